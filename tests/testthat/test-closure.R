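mk_cand <- function(path_str, base_length, loops = list()) {
  list(members = parse_contig_path(path_str), base_length = base_length,
       loops = loops)
}
mk_loop <- function(anchor_str, members_str, loop_length) {
  a <- parse_contig_path(anchor_str)
  list(anchor = list(id = a$id, strand = a$strand),
       members = parse_contig_path(members_str), loop_length = loop_length,
       key = paste0(anchor_str, "@", members_str))
}

test_that("loop copy counts minimise distance to the gap size", {
  cand <- mk_cand("L+:R+", 10000, list(mk_loop("L+", "A+:L+", 3000)))
  o <- optimize_loop_copies(cand, 19200)
  expect_equal(o$final_length, 19000)   # n = 3
  expect_equal(unname(o$copies), 3L)
  expect_equal(format_contig_path(o$members), "L+:A+:L+:A+:L+:A+:L+:R+")

  # no loops: identity
  o0 <- optimize_loop_copies(mk_cand("L+:R+", 10000), 12000)
  expect_equal(o0$final_length, 10000)

  # ties break toward fewer copies: base 10000, loop 2000, gap 11000
  cand_t <- mk_cand("L+:R+", 10000, list(mk_loop("L+", "A+:L+", 2000)))
  expect_equal(unname(optimize_loop_copies(cand_t, 11000)$copies), 0L)

  # brute-force argmin oracle on random instances
  set.seed(55)
  for (i in 1:50) {
    base <- sample(5000:50000, 1)
    ll <- sample(1000:12000, 1)
    gap <- sample(5000:80000, 1)
    cand_r <- mk_cand("L+:R+", base, list(mk_loop("L+", "A+:L+", ll)))
    n_opt <- unname(optimize_loop_copies(cand_r, gap)$copies)
    ns <- 0:ceiling(gap / ll + 1)
    err <- abs(base + ns * ll - gap)
    best <- ns[order(err, ns)][1]
    expect_identical(n_opt, as.integer(best))
  }
})

test_that("a nested loop splices only after its parent materialises", {
  parent <- mk_loop("A+", "B+:A+", 8000)
  inner <- mk_loop("B+", "C+:B+", 3000)
  cand <- mk_cand("L+:A+:R+", 20000, list(parent, inner))
  o <- optimize_loop_copies(cand, 31000)   # parent n=1 (28000), inner n=1 (23000->…)
  expect_true("B+" %in% paste0(o$members$id, o$members$strand))
  # the inner loop's copies sit after a spliced B
  expect_equal(o$final_length,
               20000 + 8000 * o$copies[[parent$key]] +
                 3000 * o$copies[[inner$key]])
})

test_that("closure selection enforces tolerance and ambiguity rules", {
  gap <- toy_gap(oc("L", "+"), oc("R", "+"), 27000, 10000, 10000)
  p <- search_params()

  # single candidate, 1 bp off: closed
  cl <- select_best(list(mk_cand("L+:A+:R+", 27001)), gap, p)
  expect_equal(cl$status, "closed")
  expect_equal(cl$length_difference, 1)

  # single candidate, 2500 bp off at tolerance 2000: out of tolerance
  cl <- select_best(list(mk_cand("L+:A+:R+", 29500)), gap, p)
  expect_equal(cl$status, "out_of_tolerance")

  # two candidates differing by 5 bp: ambiguous, both retained
  cl <- select_best(list(mk_cand("L+:A+:R+", 27000),
                         mk_cand("L+:B+:R+", 27005)), gap, p)
  expect_equal(cl$status, "ambiguous")
  expect_equal(length(cl$ranked), 2L)
  expect_equal(cl$runner_up_margin, 5)

  # equal-length substitute contig: ambiguous
  cl <- select_best(list(mk_cand("L+:X+:A+:Y+:R+", 27000),
                         mk_cand("L+:X+:B+:Y+:R+", 27000)), gap, p)
  expect_equal(cl$status, "ambiguous")

  # clearly separated runner-up: closed
  cl <- select_best(list(mk_cand("L+:A+:R+", 27100),
                         mk_cand("L+:B+:R+", 33000)), gap, p)
  expect_equal(cl$status, "closed")

  # nothing found
  expect_equal(select_best(list(), gap, p)$status, "no_path")
})

test_that("multi-loop best paths close only when they are the sole survivor", {
  gap <- toy_gap(oc("L", "+"), oc("R", "+"), 40000, 10000, 10000)
  two_loops <- list(mk_loop("A+", "B+:A+", 7000), mk_loop("A+", "C+:A+", 9000))
  best <- mk_cand("L+:A+:R+", 40000, two_loops)
  # another candidate also inside tolerance: refuse to arbitrate
  other <- mk_cand("L+:D+:R+", 41000)
  cl <- select_best(list(best, other), gap, search_params())
  expect_equal(cl$status, "ambiguous")
  # alone, it closes
  cl2 <- select_best(list(best), gap, search_params())
  expect_equal(cl2$status, "closed")
})

test_that("stitching concatenates, reverse-complements and trims overlaps", {
  seqs <- c(c1 = "AAAA", c2 = "CCCC", c3 = "AAGG")
  m <- parse_contig_path("c1+:c2+")
  expect_equal(stitch_path(m, seqs), "AAAACCCC")
  expect_equal(stitch_path(parse_contig_path("c1+:c3-"), seqs), "AAAACCTT")
  expect_equal(stitch_path(m, seqs, junction_overlap = 2), "AAAACC")
  expect_error(stitch_path(parse_contig_path("c1+:zz+"), seqs), "zz")
})

test_that("N50 follows the cumulative-half-total definition", {
  expect_equal(assembly_stats(c(2, 3, 4, 5, 6))$n50_bp, 5)
  expect_equal(assembly_stats(42)$n50_bp, 42)
  expect_equal(assembly_stats(rep(7, 9))$n50_bp, 7)
  expect_error(assembly_stats(numeric(0)))
})

test_that("the closure audit catches violated invariants", {
  gap <- toy_gap(oc("L", "+"), oc("R", "+"), 27000, 10000, 10000)
  good <- select_best(list(mk_cand("L+:A+:R+", 27001)), gap, search_params())
  expect_true(audit_closures(list(good)))
  bad <- good
  bad$length_difference <- 5000
  expect_error(audit_closures(list(bad)), "invariant")
})
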