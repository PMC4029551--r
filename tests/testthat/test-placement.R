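# a linear map with a planted window for a contig whose internal RFs are
# [10000, 20000, 15000]; end fragments are padding that must be ignored
planted_digest <- function(id = "c1") {
  # fragments: end 3000 | 10000 20000 15000 10000 12000 | end 2500
  cuts <- cumsum(c(3000, 10000, 20000, 15000, 10000, 12000))
  structure(list(contig_id = id, length = as.integer(max(cuts) + 2500),
                 cut_positions = as.integer(cuts),
                 fragments = as.integer(diff(c(0, cuts, max(cuts) + 2500)))),
            class = "contig_digest")
}

planted_map <- function(dup = FALSE) {
  window <- c(10100, 19800, 15200, 9900, 12100)
  frags <- c(40000, 35000, window, 28000, 55000)
  if (dup) frags <- c(frags, 31000, window, 26000)
  restriction_map(frags, enzyme = "AflII", circular = FALSE)
}

test_that("a planted window is found once, on the right strand", {
  d <- planted_digest()
  pl <- align_contig(d, planted_map())
  expect_equal(length(pl), 1L)
  p <- pl[[1]]
  expect_equal(p$strand, "+")
  expect_equal(c(p$map_first, p$map_last), c(3L, 7L))
  expect_equal(c(p$contig_first, p$contig_last), c(2L, 6L))
  # all five blocks are 1-vs-1
  expect_true(all(p$blocks$map_last - p$blocks$map_first == 0L))
  pl <- classify_uniqueness(pl)
  expect_true(pl[[1]]$unique)
})

test_that("a reversed contig places on the minus strand (strand symmetry)", {
  d <- planted_digest()
  rd <- digest_reverse_complement(d)
  pl <- align_contig(rd, planted_map())
  expect_equal(length(pl), 1L)
  expect_equal(pl[[1]]$strand, "-")
  expect_equal(c(pl[[1]]$map_first, pl[[1]]$map_last), c(3L, 7L))
})

test_that("a duplicated window yields two placements, both non-unique", {
  pl <- align_contig(planted_digest(), planted_map(dup = TRUE))
  expect_equal(length(pl), 2L)
  pl <- classify_uniqueness(pl)
  expect_false(any(vapply(pl, `[[`, NA, "unique")))
})

test_that("uniqueness margin arithmetic follows the 20% rule", {
  mk <- function(score) omconnect:::new_placement("c", "+", 1L, 5L, 2L, 6L,
                                                  score, NULL)
  pl <- classify_uniqueness(list(mk(1.0), mk(1.5)))
  expect_true(pl[[1]]$unique)    # 1.5 > 1.2 * 1.0
  pl <- classify_uniqueness(list(mk(1.0), mk(1.0)))
  expect_false(any(vapply(pl, `[[`, NA, "unique")))   # tie
  pl <- classify_uniqueness(list(mk(1.0), mk(1.15)))
  expect_false(pl[[1]]$unique)   # inside the margin
})

test_that("contigs with too few internal RFs are unplaceable", {
  d <- digest_sequence(paste0(strrep("A", 3000), "CTTAAG", strrep("C", 3000)),
                       "AflII", "tiny")
  expect_equal(align_contig(d, planted_map()), list())
})

test_that("placement table reader validates spans and contigs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  cs <- contig_set(c("006", "007"), c(50000L, 60000L))
  m <- restriction_map(rep(10000, 20), circular = FALSE)
  writeLines("006\t+\t10\t14\tU", f)
  pl <- read_placements(f, cs, m)
  expect_equal(pl[[1]]$map_first, 11L)   # 0-based half-open on disk
  expect_equal(pl[[1]]$map_last, 14L)
  expect_true(pl[[1]]$unique)

  writeLines("006\t+\t10\t999\tU", f)
  expect_error(read_placements(f, cs, m), "out of bounds")
  writeLines("zzz\t+\t1\t4\tU", f)
  expect_error(read_placements(f, cs, m), "unknown contig")
})

test_that("gap construction floors small RFs and counts pairs correctly", {
  # two unique placements on a linear map: fragments between them are the gap
  m <- restriction_map(c(10000, 11000, 5000, 1500, 800, 12000, 9000),
                       circular = FALSE)
  mk <- function(id, first, last) omconnect:::new_placement(
    id, "+", first, last, 2L, 3L, 0, NULL, unique = TRUE)
  digs <- list()  # tails fall back to NA without digests; supply spans only
  gaps <- build_gaps(list(mk("a", 1L, 2L), mk("b", 6L, 7L)), m, digs)
  expect_equal(length(gaps), 1L)
  expect_equal(gaps[[1]]$gap_rfs, c(5000, 1500, 800))
  expect_equal(gaps[[1]]$raw_size, 5000 + 2000 + 2000)

  # circular: wrap-around pair appears, gap count equals placement count
  mc <- restriction_map(c(10000, 11000, 5000, 1500, 800, 12000, 9000),
                        circular = TRUE)
  gaps <- build_gaps(list(mk("a", 1L, 2L), mk("b", 6L, 7L)), mc, digs)
  expect_equal(length(gaps), 2L)
  expect_equal(gaps[[2]]$gap_rfs, numeric(0))   # adjacent across the origin

  # overlapping placements: the pair is skipped with a warning
  expect_warning(
    gaps <- build_gaps(list(mk("a", 1L, 4L), mk("b", 3L, 7L)), m, digs),
    "overlapping")
  expect_equal(length(gaps), 0L)
})

test_that("noise-free planted contigs place at score ~0 at their true locus", {
  cfg <- scenario_config(genome_length = 500000, circular = FALSE,
                         n_unique_segments = 5L, map_scale = 1,
                         sizing_noise_sigma = 0, small_rf_drop_prob = 0,
                         seed = 11)
  sc <- generate_scenario(cfg)
  digs <- lapply(stats::setNames(sc$contigs$id, sc$contigs$id), function(id)
    digest_sequence(sc$contigs$sequence[sc$contigs$id == id], "AflII", id))
  placed <- 0L
  for (id in sc$contigs$id) {
    pl <- align_contig(digs[[id]], sc$map)
    if (!length(pl)) next
    placed <- placed + 1L
    pl <- classify_uniqueness(pl)
    expect_lt(pl[[1]]$score, 1e-6)
    expect_true(pl[[1]]$unique)
    expect_equal(pl[[1]]$strand, "+")
  }
  expect_gte(placed, 4L)
})
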