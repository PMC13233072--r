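test_that("window length is half the median read length, floored and bounded", {
  expect_identical(compute_window_length(c(10000, 10000, 10000)), 5000L)
  expect_identical(compute_window_length(1000), 500L)
  # even count: median = mean of the two middle values (5000), halved
  expect_identical(compute_window_length(c(2000, 4000, 6000, 8000)), 2500L)
  # bounded below by the configured minimum
  expect_identical(compute_window_length(c(300, 300, 300)), 500L)
  expect_identical(compute_window_length(c(300, 300), min_window_length = 100L), 150L)
  expect_error(compute_window_length(integer()), "no usable reads")
})

test_that("best-alignment selection keeps one record per read with tie-breaks", {
  a <- aln_tbl(
    aln_row("r1", 0, "AAAA", score = 60),
    aln_row("r1", 10, "AAAA", score = 40),
    aln_row("r2", 5, "AAAA", score = 10))
  out <- select_best_alignments(a)
  expect_identical(nrow(out), 2L)
  expect_identical(out$start[out$read_id == "r1"], 0L)

  # one record per read: unchanged
  b <- aln_tbl(aln_row("r1", 0, "AAAA"), aln_row("r2", 3, "AAAA"))
  expect_identical(nrow(select_best_alignments(b)), 2L)

  # equal scores: lexicographically smallest (contig, start) wins
  d <- aln_tbl(
    aln_row("r1", 7, "AAAA", contig = "c2", score = 50),
    aln_row("r1", 9, "AAAA", contig = "c1", score = 50))
  out <- select_best_alignments(d)
  expect_identical(out$contig, "c1")
})

test_that("binary matrix encodes reference agreement over spanning reads", {
  ref <- ref_codes("ACGT")
  w <- win_tbl(0, 4)
  a <- aln_tbl(
    aln_row("r1", 0, "ACGT"),
    aln_row("r2", 0, "ACGT"),
    aln_row("r3", 0, "ACGT"))
  bm <- build_binary_matrix(w, a, ref)
  expect_identical(dim(bm), c(3L, 4L))
  expect_true(all(bm$M == 1L))

  # one substitution and one deletion both give 0
  b <- aln_tbl(aln_row("r1", 0, "ACGT"), aln_row("r2", 0, "ATG-"))
  bm <- build_binary_matrix(w, b, ref)
  expect_identical(bm$M[2, ], c(1L, 0L, 1L, 0L))
  expect_true(all(bm$M %in% c(0L, 1L)))

  # a read missing the first window base is excluded from the rows
  d <- aln_tbl(aln_row("r1", 0, "ACGT"), aln_row("r2", 1, "CGT"))
  bm <- build_binary_matrix(w, d, ref)
  expect_identical(bm$read_ids, "r1")

  # zero spanning reads: a valid empty matrix
  bm0 <- build_binary_matrix(w, d[2, ], ref)
  expect_identical(nrow(bm0$M), 0L)
})

test_that("error bound is the inflated window divergence, clamped", {
  # 31 non-reference bases out of 336 aligned: s = 3 * 31/336 = 0.28
  em <- error_model_from_counts(31, 336)
  expect_equal(round(em$s, 2), 0.28)
  expect_equal(em$s, 3 * 31 / 336, tolerance = 1e-12)
  # divergence 0.05 -> s = 0.15
  expect_equal(error_model_from_counts(5, 100)$s, 0.15, tolerance = 1e-12)
  # clamped at the ceiling
  expect_equal(error_model_from_counts(40, 100)$s, 0.95, tolerance = 1e-12)
  # and at the floor
  expect_equal(error_model_from_counts(0, 100)$s, 0.01, tolerance = 1e-12)
  expect_error(error_model_from_counts(0, 0), "zero aligned")

  # from alignments: computed within the window only
  ref <- ref_codes("AAAA")
  w <- win_tbl(0, 4)
  a <- aln_tbl(aln_row("r1", 0, "AAAT"), aln_row("r2", 0, "AAAA"))
  em <- estimate_error_rate(a, w, ref)
  expect_equal(em$divergence, 1 / 8, tolerance = 1e-12)
  expect_equal(em$s, 3 / 8, tolerance = 1e-12)
})

test_that("candidate filter is strictly greater-than on the alt fraction", {
  fx <- block_window(len = 3, n_ref = 89,
                     groups = list(list(n = 6, pos = c(0L, 1L), alt = c("G", "G")),
                                   list(n = 5, pos = 2L, alt = "G")))
  bm <- build_binary_matrix(fx$window, fx$aln, fx$ref)
  expect_identical(nrow(bm$M), 100L)
  bm <- filter_candidate_columns(bm, 0.05)
  # 6/100 = 0.06 > 0.05 is a candidate; exactly 5/100 is not (strict >)
  expect_identical(unname(bm$candidate), c(TRUE, TRUE, FALSE))
  expect_identical(bm$m, 2L)

  # all-reference column is never a candidate
  fx0 <- block_window(len = 4, n_ref = 20)
  bm0 <- filter_candidate_columns(build_binary_matrix(fx0$window, fx0$aln, fx0$ref))
  expect_identical(bm0$m, 0L)
})

test_that("raising the candidate threshold never increases m", {
  set.seed(71)
  for (rep in 1:5) {
    fx <- block_window(len = 50, n_ref = 10,
                       groups = list(list(n = sample(1:8, 1), pos = 0:24,
                                          alt = rep("C", 25))))
    bm <- build_binary_matrix(fx$window, fx$aln, fx$ref)
    # perturb with random errors
    bm$M[sample(length(bm$M), 50)] <- 0L
    ms <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.4),
                 function(f) filter_candidate_columns(bm, f)$m, integer(1))
    expect_true(all(diff(ms) <= 0L))
  }
})

test_that("coordinate clustering requires >= 5 reads at identical coordinates", {
  w <- win_tbl(0, 100)
  mk <- function(n, start, len, prefix) {
    dplyr::bind_rows(lapply(seq_len(n), function(i)
      aln_row(sprintf("%s%02d", prefix, i), start,
              strrep("A", len))))
  }
  a <- mk(7, 10, 20, "a")
  cl <- cluster_reads_by_coordinates(w, a)
  expect_length(cl$clusters, 1L)
  expect_length(cl$clusters[[1]], 7L)

  b <- mk(4, 10, 20, "b")
  cl <- cluster_reads_by_coordinates(w, b)
  expect_length(cl$clusters, 0L)
  expect_length(cl$residual, 4L)

  # off-by-one coordinates are different clusters
  d <- dplyr::bind_rows(mk(5, 10, 20, "c"), mk(5, 11, 20, "d"))
  cl <- cluster_reads_by_coordinates(w, d)
  expect_length(cl$clusters, 2L)
  starts <- vapply(cl$clusters, function(x) attr(x, "start"), integer(1))
  expect_identical(sort(starts), c(10L, 11L))
})

test_that("pileup counts include non-spanning reads and deletion marks", {
  w <- win_tbl(0, 4)
  a <- aln_tbl(
    aln_row("r1", 0, "ACGT"),
    aln_row("r2", 1, "C-T"),     # partial read with a deletion at pos 2
    aln_row("r3", 2, "GT"))
  counts <- window_pileup_counts(w, a)
  expect_identical(dim(counts), c(5L, 4L))
  expect_identical(sum(counts), 9L)                 # 4 + 3 + 2 covered cells
  expect_identical(counts[5, 3], 1L)                # the deletion mark
  expect_equal(unname(colSums(counts)), c(1, 2, 3, 3))
})
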