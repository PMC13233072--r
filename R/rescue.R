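#' Exact binomial upper-tail probability
#'
#' `P(X >= k)` for `X ~ Binomial(c, s)`: the chance that sequencing errors
#' alone, at per-base rate at most `s`, produce `k` or more copies of one
#' alternative base among `c` covering reads.
#'
#' @param k Observed count, `0 <= k <= c`.
#' @param c Coverage at the position.
#' @param s Error bound in (0, 1).
#' @return The exact upper-tail probability.
#' @examples
#' binomial_tail_pvalue(13, 30, 0.15)
#' @export
binomial_tail_pvalue <- function(k, c, s) {
  if (any(k < 0) || any(k > c) || any(c < 0)) {
    abort("need 0 <= k <= c")
  }
  if (s <= 0 || s >= 1) abort("`s` must be in (0, 1)")
  # P(X >= k) = 1 - P(X <= k - 1), exact via the regularised beta function
  pbinom(k - 1, c, s, lower.tail = FALSE)
}

#' Call obvious SNPs from per-position allele counts
#'
#' Position-specific binomial test, independent of the multi-locus
#' machinery: at each position, each alternative base whose count `k` among
#' the `c` covering reads is too large to be explained by errors at rate `s`
#' (upper-tail p-value strictly below `alpha`) is called an "obvious" SNP.
#' Each alternative base is tested on its own count — the model describes
#' one allele's recurrence; pooling across alternatives would conflate
#' multi-allelic noise. Deletion marks are never emitted (SNP caller).
#'
#' @param counts 5 x L per-position allele counts (rows A, C, G, T, del),
#'   as from [window_pileup_counts()].
#' @param ref Integer base codes of the reference over the same positions.
#' @param window_start 0-based reference coordinate of the first column.
#' @param s Error bound from the window's `error_model`.
#' @param alpha Threshold (default 0.001), strict `<`.
#' @return A tibble with `pos0`, `ref`, `alt`, `support`, `depth`,
#'   `log10_p` (one row per called position/allele).
#' @export
call_obvious_snps <- function(counts, ref, window_start, s, alpha = 0.001) {
  L <- ncol(counts)
  depth <- colSums(counts)
  out <- vector("list", 4L)
  for (base in 1:4) {
    k <- counts[base, ]
    testable <- which(base != ref & k > 0L & depth > 0L)
    if (length(testable) == 0L) next
    p <- binomial_tail_pvalue(k[testable], depth[testable], s)
    hit <- p < alpha
    if (!any(hit)) next
    j <- testable[hit]
    out[[base]] <- tibble(
      pos0 = window_start + j - 1L,
      ref = code_to_base(ref[j]),
      alt = BASE_LEVELS[base],
      support = as.integer(k[j]),
      depth = as.integer(depth[j]),
      log10_p = log10(p[hit])
    )
  }
  bind_rows(out)
}

#' Rescue loci correlated with confirmed SNPs
#'
#' High-noise loci excluded from variant groups (for instance by the
#' candidate filter) can still carry real strain signal. Every not-yet
#' -called pileup column of the matrix is chi-square-tested against each
#' confirmed column; a locus whose best p-value is strictly below
#' `threshold` is rescued. The reported alternative base is the majority
#' observed alternative among the reads sharing the confirmed column's
#' alternative state, ties broken alphabetically.
#'
#' @param matrix A `binmat` (all pileup columns, not only candidates).
#' @param confirmed_cols Column indices of already-called loci.
#' @param called_keys Character keys `"pos0:alt"` of calls already made
#'   (never re-emitted).
#' @param threshold Strict p-value threshold (default 1e-6).
#' @param min_overlap Minimum shared reads for a pair test.
#' @return A tibble like [call_obvious_snps()] (possibly empty).
#' @export
rescue_correlated_loci <- function(matrix, confirmed_cols, called_keys = character(),
                                   threshold = 1e-6, min_overlap = 10L) {
  empty <- tibble(pos0 = integer(), ref = character(), alt = character(),
                  support = integer(), depth = integer(), log10_p = double())
  if (length(confirmed_cols) == 0L || nrow(matrix$M) == 0L) return(empty)
  n <- nrow(matrix$M)
  Mall <- matrix$M
  A <- 1L - Mall
  Ac <- A[, confirmed_cols, drop = FALSE]
  # 2x2 cells for (every column) x (confirmed column); scalar margins
  # collapse the statistic to rank-1 products (see pairwise_chi2_pvalues)
  both <- crossprod(A, Ac)                       # alt at j and at conf
  altj <- colSums(A); altc <- colSums(Ac)
  det <- n * both - tcrossprod(altj, altc)
  denom <- tcrossprod(altj * (n - altj), altc * (n - altc))
  ok <- denom > 0
  stat <- matrix(0, nrow(both), ncol(both))
  stat[ok] <- n * det[ok]^2 / denom[ok]
  crit <- stats::qchisq(threshold, df = 1L, lower.tail = FALSE)
  p <- matrix(1.0, nrow(both), ncol(both))
  idx <- which(ok & stat >= crit)
  p[idx] <- pchisq(stat[idx], df = 1L, lower.tail = FALSE)
  if (n < min_overlap) p[] <- 1.0
  p[confirmed_cols, ] <- 1.0                     # never rescue a confirmed column
  best <- p[, 1L]
  for (j in seq_len(ncol(p))[-1L]) best <- pmin(best, p[, j])
  cand <- which(best < threshold)
  rows <- vector("list", length(cand))
  for (ii in seq_along(cand)) {
    j <- cand[ii]
    conf <- confirmed_cols[which.min(p[j, ])]
    carriers <- which(A[, conf] == 1L)
    obs <- matrix$obs[carriers, j]
    obs <- obs[obs != 0L & obs != matrix$ref[j] & obs != 5L]
    if (length(obs) == 0L) next
    tab <- tabulate(obs, nbins = 4L)
    alt <- which(tab == max(tab))[1L]            # ties: lowest code = alphabetical
    key <- paste0(matrix$positions[j], ":", BASE_LEVELS[alt])
    if (key %in% called_keys) next
    rows[[ii]] <- tibble(
      pos0 = matrix$positions[j],
      ref = code_to_base(matrix$ref[j]),
      alt = BASE_LEVELS[alt],
      support = sum(matrix$obs[, j] == alt),
      depth = sum(matrix$obs[, j] != 0L),
      log10_p = log10(best[j])
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0L) empty else distinct(out, .data$pos0, .data$alt, .keep_all = TRUE)
}

#' Mask called variants in a binary matrix
#'
#' Cells whose observed base equals a call's alternative base are converted
#' to reference-like status (`M = 1`, observed base set to the reference
#' code). Other alternative bases at the same position are untouched, so
#' re-running the caller on the masked matrix reveals secondary alleles at
#' multi-allelic sites.
#'
#' @param matrix A `binmat`.
#' @param calls A tibble with `pos0` and `alt` columns.
#' @return The masked `binmat`.
#' @export
mask_called_variants <- function(matrix, calls) {
  if (is.null(calls) || nrow(calls) == 0L) return(matrix)
  for (i in seq_len(nrow(calls))) {
    j <- match(calls$pos0[i], matrix$positions)
    if (is.na(j)) next
    code <- base_to_code(calls$alt[i])
    hit <- matrix$obs[, j] == code
    if (any(hit)) {
      matrix$obs[hit, j] <- matrix$ref[j]
      matrix$M[hit, j] <- 1L
    }
  }
  matrix
}

#' Mask called variants in a pileup count matrix
#'
#' Moves each called alternative base's count onto the reference row, the
#' count-space equivalent of [mask_called_variants()].
#'
#' @param counts 5 x L count matrix.
#' @param ref Integer reference codes.
#' @param window_start 0-based coordinate of column 1.
#' @param calls A tibble with `pos0` and `alt`.
#' @return The masked count matrix.
#' @export
mask_pileup_counts <- function(counts, ref, window_start, calls) {
  if (is.null(calls) || nrow(calls) == 0L) return(counts)
  for (i in seq_len(nrow(calls))) {
    j <- calls$pos0[i] - window_start + 1L
    if (j < 1L || j > ncol(counts)) next
    code <- base_to_code(calls$alt[i])
    counts[ref[j], j] <- counts[ref[j], j] + counts[code, j]
    counts[code, j] <- 0L
  }
  counts
}
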