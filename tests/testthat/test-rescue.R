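test_that("binomial upper tail is exact", {
  expect_identical(binomial_tail_pvalue(0, 30, 0.15), 1.0)
  expect_equal(binomial_tail_pvalue(5, 5, 0.5), 0.03125, tolerance = 1e-15)
  # frozen from exact rational summation of C(30,j) 0.15^j 0.85^(30-j)
  expect_equal(binomial_tail_pvalue(13, 30, 0.15), 1.857024475931922e-4,
               tolerance = 1e-12)
  expect_equal(binomial_tail_pvalue(10, 30, 0.15), 9.657635199554856e-3,
               tolerance = 1e-12)
  expect_error(binomial_tail_pvalue(-1, 10, 0.2), "0 <= k <= c")
  expect_error(binomial_tail_pvalue(11, 10, 0.2), "0 <= k <= c")
  expect_error(binomial_tail_pvalue(2, 10, 1), "in \\(0, 1\\)")
})

test_that("obvious SNPs need a count errors cannot explain", {
  # one position, coverage 30, s = 0.15: k = 13 called, k = 10 not, k = 0 never
  mk_counts <- function(k, c, ref_row = 1L, alt_row = 3L) {
    counts <- matrix(0L, 5, 1)
    counts[ref_row, 1] <- c - k
    counts[alt_row, 1] <- k
    counts
  }
  hit <- call_obvious_snps(mk_counts(13, 30), ref = 1L, window_start = 100L,
                           s = 0.15)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$pos0, 100L)
  expect_identical(hit$alt, "G")
  expect_identical(hit$support, 13L)
  expect_equal(hit$log10_p, log10(1.857024475931922e-4), tolerance = 1e-9)

  expect_identical(nrow(call_obvious_snps(mk_counts(10, 30), 1L, 0L, 0.15)), 0L)
  expect_identical(nrow(call_obvious_snps(mk_counts(0, 30), 1L, 0L, 0.15)), 0L)

  # the threshold is strict: p must be < alpha, not <=
  k_edge <- 13; p_edge <- binomial_tail_pvalue(k_edge, 30, 0.15)
  expect_identical(nrow(call_obvious_snps(mk_counts(k_edge, 30), 1L, 0L, 0.15,
                                          alpha = p_edge)), 0L)

  # per-allele counting: two alts of 7 each are not pooled into 14
  counts <- matrix(0L, 5, 1)
  counts[1, 1] <- 16L; counts[2, 1] <- 7L; counts[4, 1] <- 7L
  expect_identical(nrow(call_obvious_snps(counts, 1L, 0L, 0.15)), 0L)

  # deletion marks are never emitted
  counts <- matrix(0L, 5, 1)
  counts[1, 1] <- 10L; counts[5, 1] <- 20L
  expect_identical(nrow(call_obvious_snps(counts, 1L, 0L, 0.15)), 0L)
})

test_that("loci correlated with confirmed SNPs are rescued", {
  # 60 reads; column 2 identical to confirmed column 1 (30/30 split):
  # chi-square = 60, p << 1e-6. Column 3 independent.
  fx <- block_window(len = 4, n_ref = 30,
                     groups = list(list(n = 30, pos = c(0L, 1L), alt = c("G", "G"))))
  bm <- build_binary_matrix(fx$window, fx$aln, fx$ref)
  set.seed(13)
  bm$M[sample(60, 12), 3] <- 0L          # noise column, independent
  bm$obs[bm$M == 0L & col(bm$M) == 3] <- 4L
  out <- rescue_correlated_loci(bm, confirmed_cols = 1L)
  expect_identical(out$pos0, 1L)
  expect_identical(out$alt, "G")
  expect_true(10^out$log10_p < 1e-6)

  # no confirmed columns: vacuous
  expect_identical(nrow(rescue_correlated_loci(bm, integer())), 0L)

  # already-called keys are not re-emitted
  out2 <- rescue_correlated_loci(bm, 1L, called_keys = "1:G")
  expect_identical(nrow(out2), 0L)
})

test_that("masking converts called alt cells to reference-like status", {
  fx <- block_window(len = 3, n_ref = 10,
                     groups = list(list(n = 6, pos = 0L, alt = "G"),
                                   list(n = 4, pos = 0L, alt = "T")))
  bm <- build_binary_matrix(fx$window, fx$aln, fx$ref)
  expect_identical(sum(bm$M[, 1] == 0L), 10L)

  masked <- mask_called_variants(bm, tibble::tibble(pos0 = 0L, alt = "G"))
  # G cells flipped to reference; T cells untouched
  expect_identical(sum(masked$M[, 1] == 0L), 4L)
  expect_true(all(masked$obs[masked$M[, 1] == 0L, 1] == 4L))

  # masking the remaining alt empties the column
  masked2 <- mask_called_variants(masked, tibble::tibble(pos0 = 0L, alt = "T"))
  expect_true(all(masked2$M[, 1] == 1L))
  expect_identical(filter_candidate_columns(masked2)$candidate[1], FALSE)

  # empty call list: identity
  expect_identical(mask_called_variants(bm, tibble::tibble()), bm)

  # count-space masking mirrors the matrix
  counts <- window_pileup_counts(fx$window, fx$aln)
  mc <- mask_pileup_counts(counts, fx$ref, 0L, tibble::tibble(pos0 = 0L, alt = "G"))
  expect_identical(mc[3, 1], 0L)
  expect_identical(mc[1, 1], counts[1, 1] + counts[3, 1])
  expect_identical(sum(mc), sum(counts))
})

test_that("iterative calling terminates and reveals secondary alleles", {
  # all-reference window: zero calls, stops after the first round
  fx0 <- block_window(len = 100, n_ref = 20)
  out0 <- call_window(fx0$window, fx0$aln, fx0$ref)
  expect_identical(nrow(out0), 0L)

  # simulated tri-allelic sites: 3 strains diverged enough that some
  # positions carry two alternative bases; both must be called. Evaluated
  # away from contig ends, where read sampling thins the pileup for
  # reasons unrelated to the multi-allelic mechanism.
  tr <- simulate_haplotypes(20000, strain_count = 3, divergence = 0.02, seed = 37)
  multi <- tr$truth |>
    dplyr::count(pos) |>
    dplyr::filter(n >= 2)
  expect_gt(nrow(multi), 0L)
  reads <- simulate_reads(tr, coverages = c(25, 25, 25), read_length = 4000,
                          error_rate = 0.01, seed = 38)
  res <- call_alignments(reads, tr$reference, contig = tr$contig)
  ck <- paste0(res$calls$pos, ":", res$calls$alt)
  tri <- tr$truth[tr$truth$pos %in% multi$pos &
                    tr$truth$pos > 4000 & tr$truth$pos <= 16000, ]
  expect_gt(mean(paste0(tri$pos, ":", tri$alt) %in% ck), 0.85)
  # at least one site has both of its alternative alleles called
  both <- vapply(split(paste0(tri$pos, ":", tri$alt), tri$pos),
                 function(k) all(k %in% ck), logical(1))
  expect_gt(sum(both), 0L)

  # no (position, alt) pair is ever emitted twice across rounds
  expect_identical(anyDuplicated(ck), 0L)
  expect_lte(max(res$calls$round), caller_config()$max_rounds)
})
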