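test_that("path_length composes flank offsets, interiors and overlaps", {
  # left: 1000 bp, one cut at 900 -> tail 100; right: 1000 bp, cut at 200
  digs <- list(
    L = structure(list(contig_id = "L", length = 1000L, cut_positions = 900L,
                       fragments = c(900L, 100L)), class = "contig_digest"),
    A = structure(list(contig_id = "A", length = 5000L,
                       cut_positions = integer(0), fragments = 5000L),
                  class = "contig_digest"),
    R = structure(list(contig_id = "R", length = 1000L, cut_positions = 200L,
                       fragments = c(200L, 800L)), class = "contig_digest"))
  p <- data.frame(id = c("L", "A", "R"), strand = "+", stringsAsFactors = FALSE)
  expect_equal(path_length(p, digs), 5300)
  expect_equal(path_length(p, digs, junction_overlap = 50), 5200)
  # minus-strand flanks mirror their cut offsets
  pm <- data.frame(id = c("R", "A", "L"), strand = "-", stringsAsFactors = FALSE)
  expect_equal(path_length(pm, digs), 5300)
  # flank without any site: the gap is undefined
  digs$L$cut_positions <- integer(0)
  digs$L$fragments <- 1000L
  expect_error(path_length(p, digs), "no restriction site")
})

test_that("a direct connection and a diamond enumerate correctly", {
  g <- toy_graph(c(L = 20000, A = 7000, B = 9000, R = 20000),
                 list(c("L", "3", "R", "5")))
  gap <- toy_gap(oc("L", "+"), oc("R", "+"), 20000, 10000, 10000)
  f <- find_paths(g, oc("L", "+"), oc("R", "+"), gap, c("L", "R"))
  expect_equal(length(f$candidates), 1L)
  expect_equal(format_contig_path(f$candidates[[1]]$members), "L+:R+")
  expect_equal(f$candidates[[1]]$base_length, 20000)
  expect_equal(f$candidates[[1]]$loops, list())

  g2 <- toy_graph(c(L = 20000, A = 7000, B = 9000, R = 20000),
                  list(c("L", "3", "A", "5"), c("A", "3", "R", "5"),
                       c("L", "3", "B", "5"), c("B", "3", "R", "5")))
  gap2 <- toy_gap(oc("L", "+"), oc("R", "+"), 28000, 10000, 10000)
  f2 <- find_paths(g2, oc("L", "+"), oc("R", "+"), gap2, c("L", "R"))
  expect_setequal(vapply(f2$candidates, function(x)
    format_contig_path(x$members), ""), c("L+:A+:R+", "L+:B+:R+"))
})

test_that("length bound and unique-contig rule prune branches", {
  g <- toy_graph(c(L = 20000, A = 7000, U = 5000, R = 20000),
                 list(c("L", "3", "A", "5"), c("A", "3", "R", "5"),
                      c("L", "3", "U", "5"), c("U", "3", "R", "5")))
  gap <- toy_gap(oc("L", "+"), oc("R", "+"), 27000, 10000, 10000)
  # U is uniquely placed: the branch through it must be dropped
  f <- find_paths(g, oc("L", "+"), oc("R", "+"), gap, c("L", "R", "U"))
  expect_equal(vapply(f$candidates, function(x)
    format_contig_path(x$members), ""), "L+:A+:R+")
  # tight bound kills the long branch as well
  gap2 <- toy_gap(oc("L", "+"), oc("R", "+"), 18000, 10000, 10000)
  f2 <- find_paths(g, oc("L", "+"), oc("R", "+"), gap2, c("L", "R"))
  expect_equal(length(f2$candidates), 0L)
})

test_that("a tandem repeat registers as a loop with the spacer", {
  # genome ... L R S R S R Z: contig R 3 copies, spacer S twice
  g <- toy_graph(c(L = 30000, R = 6000, S = 3000, Z = 30000),
                 list(c("L", "3", "R", "5"), c("R", "3", "S", "5"),
                      c("S", "3", "R", "5"), c("R", "3", "Z", "5")))
  gap <- toy_gap(oc("L", "+"), oc("Z", "+"), 39000, 10000, 11000)
  f <- find_paths(g, oc("L", "+"), oc("Z", "+"), gap, c("L", "Z"))
  expect_equal(length(f$candidates), 1L)
  cand <- f$candidates[[1]]
  expect_equal(format_contig_path(cand$members), "L+:R+:Z+")
  expect_equal(length(cand$loops), 1L)
  lp <- cand$loops[[1]]
  expect_equal(format_contig_path(lp$members), "S+:R+")
  expect_equal(lp$anchor$id, "R")
  expect_equal(lp$loop_length, 9000)
})

test_that("orientation flips re-enter a contig on the other strand", {
  # inverted-repeat arrangement: X flanked by the same contig twice, once
  # reversed -- the path must visit P in both orientations
  g <- toy_graph(c(L = 20000, P = 4000, X = 6000, R = 20000),
                 list(c("L", "3", "P", "5"), c("P", "3", "X", "5"),
                      c("X", "3", "P", "3"), c("P", "5", "R", "3")))
  gap <- toy_gap(oc("L", "+"), oc("R", "-"), 34000, 10000, 10000)
  f <- find_paths(g, oc("L", "+"), oc("R", "-"), gap, c("L", "R"))
  paths <- vapply(f$candidates, function(x) format_contig_path(x$members), "")
  expect_true("L+:P+:X+:P-:R-" %in% paths)
})

test_that("mirroring the gap mirrors the candidate set", {
  inst <- random_search_instance(77)
  f <- find_paths(inst$graph, inst$left, inst$right, inst$gap, inst$unique_ids)
  mleft <- oc(inst$right$id, "-")
  mright <- oc(inst$left$id, "-")
  mgap <- toy_gap(mleft, mright, inst$gap$rescaled_size,
                  inst$gap$right_head, inst$gap$left_tail)
  fm <- find_paths(inst$graph, mleft, mright, mgap, inst$unique_ids)
  fwd <- sort(vapply(f$candidates, function(x)
    format_contig_path(x$members), ""))
  mirrored <- sort(vapply(fm$candidates, function(x) {
    m <- x$members[rev(seq_len(nrow(x$members))), ]
    m$strand <- ifelse(m$strand == "+", "-", "+")
    format_contig_path(m)
  }, ""))
  expect_identical(fwd, mirrored)
})

test_that("candidate expansions match brute-force walks on random graphs", {
  checked <- 0L
  for (seed in 1:200) {
    inst <- random_search_instance(seed)
    bound <- 1.2 * inst$gap$rescaled_size
    walks <- brute_walks(inst$graph, inst$left, inst$right,
                         inst$gap$left_tail, inst$gap$right_head, bound,
                         inst$unique_ids)
    f <- find_paths(inst$graph, inst$left, inst$right, inst$gap,
                    inst$unique_ids)
    expect_false(f$overflow)
    walk_forms <- unique(vapply(walks, function(w) {
      r <- reduce_walk(w)
      canon_form(r$base, r$loops)
    }, ""))
    cand_forms <- unique(unlist(lapply(f$candidates, candidate_forms,
                                       bound = bound)))
    if (is.null(cand_forms)) cand_forms <- character(0)
    expect_setequal(cand_forms, walk_forms)
    checked <- checked + length(walks)
  }
  expect_gt(checked, 200)   # the instances genuinely exercise the search
})

test_that("the search terminates and flags overflow instead of hanging", {
  # dense loop nest with a generous bound: candidate/step valves must trip
  g <- toy_graph(c(L = 100, a = 1, b = 1, c = 1, d = 1, R = 100),
                 list(c("L", "3", "a", "5"), c("a", "3", "b", "5"),
                      c("b", "3", "a", "5"), c("a", "3", "c", "5"),
                      c("c", "3", "d", "5"), c("d", "3", "a", "5"),
                      c("b", "3", "c", "5"), c("d", "3", "b", "5"),
                      c("c", "3", "R", "5")))
  gap <- toy_gap(oc("L", "+"), oc("R", "+"), 1e6, 50, 50)
  f <- find_paths(g, oc("L", "+"), oc("R", "+"), gap, c("L", "R"),
                  search_params(max_paths = 10000L, max_steps = 200))
  expect_true(f$overflow || length(f$candidates) > 0)
})
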