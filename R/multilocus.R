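#' Chi-square p-value for a pair of pileup columns
#'
#' Pearson chi-square (1 d.f., no continuity correction) on the 2x2 table of
#' reference/alternative states at two columns, restricted to the reads
#' covering both. Degenerate tables — any zero marginal, or fewer than
#' `min_overlap` shared reads — return 1.0: the p-value is used as a
#' permissive dissimilarity for grouping, and the final decision rests on
#' the union-bound test, not on these pairwise values.
#'
#' @param col_u,col_v Binary vectors (1 = reference) with `NA` where the
#'   read does not cover the column.
#' @param min_overlap Minimum shared reads (default 10).
#' @return A p-value in `[0, 1]`.
#' @examples
#' chi2_pair_pvalue(rep(c(1, 0), each = 10), rep(c(1, 0), each = 10))
#' @export
chi2_pair_pvalue <- function(col_u, col_v, min_overlap = 10L) {
  shared <- !is.na(col_u) & !is.na(col_v)
  if (sum(shared) < min_overlap) return(1.0)
  u <- col_u[shared]; v <- col_v[shared]
  n11 <- sum(u == 1 & v == 1); n10 <- sum(u == 1 & v == 0)
  n01 <- sum(u == 0 & v == 1); n00 <- sum(u == 0 & v == 0)
  chi2_2x2_pvalue(n11, n10, n01, n00)
}

# Closed-form 2x2 Pearson chi-square: N(ad - bc)^2 / (r1 r2 c1 c2), 1 d.f.
chi2_2x2_pvalue <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1.0)
  n <- r1 + r2
  stat <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  pchisq(stat, df = 1L, lower.tail = FALSE)
}

#' All-pairs chi-square p-values over selected columns
#'
#' Vectorised version of [chi2_pair_pvalue()] for a spanning-read matrix
#' (every read covers every column): the four cell counts of all pairs come
#' from one cross-product of the alternative-state indicator.
#'
#' @param M Binary matrix (reads x columns, 1 = reference).
#' @param cols Column indices to test.
#' @param min_overlap Minimum shared reads (default 10).
#' @param max_p_exact When set, pairs whose p-value exceeds this threshold
#'   are reported as 1.0 without evaluating the chi-square tail. Grouping
#'   cuts the complete-linkage tree at the cutoff, so any value above it is
#'   interchangeable with 1.0; the partition is unchanged while the tail
#'   evaluation shrinks to the pairs that matter.
#' @return A symmetric matrix of p-values over `cols` (diagonal 1).
#' @export
pairwise_chi2_pvalues <- function(M, cols, min_overlap = 10L,
                                  max_p_exact = NULL) {
  k <- length(cols)
  out <- matrix(1.0, k, k)
  n <- nrow(M)
  if (k < 2L || n < min_overlap) return(out)
  A <- 1L - M[, cols, drop = FALSE]          # alternative indicator
  n00 <- crossprod(A)                        # both alternative
  ca <- colSums(A)
  # With scalar margins per column the 2x2 statistic collapses:
  # ad - bc = n*n00 - ca_u*ca_v and denom = ca_u(n-ca_u) * ca_v(n-ca_v),
  # so the whole matrix needs two rank-1 products.
  w <- ca * (n - ca)
  det <- n * n00 - tcrossprod(ca)
  denom <- tcrossprod(w)
  ok <- denom > 0
  stat <- matrix(0, k, k)
  stat[ok] <- n * det[ok]^2 / denom[ok]
  if (!is.null(max_p_exact)) {
    crit <- stats::qchisq(max_p_exact, df = 1L, lower.tail = FALSE)
    idx <- which(ok & stat >= crit)
    p <- matrix(1.0, k, k)
    p[idx] <- pchisq(stat[idx], df = 1L, lower.tail = FALSE)
  } else {
    p <- matrix(1.0, k, k)
    p[ok] <- pchisq(stat[ok], df = 1L, lower.tail = FALSE)
  }
  diag(p) <- 1.0
  p
}

#' Group correlated columns by complete-linkage clustering
#'
#' Agglomerative clustering with the pairwise p-value as distance and
#' complete linkage, cut at `cutoff`: every returned group of two or more
#' columns is guaranteed to have all intra-group pairs at p <= cutoff, so
#' all member loci correlate well with each other. Singleton columns fall
#' through to the isolated-SNP path.
#'
#' @param pvals Symmetric p-value matrix (as from [pairwise_chi2_pvalues()]).
#' @param cutoff Complete-linkage height cutoff (default 0.05).
#' @return A list of integer index vectors, each of length >= 2.
#' @export
complete_linkage_groups <- function(pvals, cutoff = 0.05) {
  k <- ncol(pvals)
  if (k < 2L) return(list())
  hc <- hclust(as.dist(pvals), method = "complete")
  grp <- cutree(hc, h = cutoff)
  groups <- split(seq_len(k), grp)
  groups <- groups[lengths(groups) >= 2L]
  groups <- unname(map(groups, as.integer))
  # order deterministically by lowest member index
  groups[order(map_int(groups, min))]
}

#' Extract the all-non-reference pattern of a column group
#'
#' The pattern's reads are those showing a non-reference state at every
#' member locus; with `a` such reads and `b` loci, the pattern is the
#' `a x b` all-error submatrix whose probability the union bound tests.
#'
#' @param group Integer vector of column indices (length >= 2).
#' @param matrix A `binmat`.
#' @return A list with `read_idx`, `loci`, `a`, `b`, or `NULL` when no read
#'   is non-reference across the whole group.
#' @export
extract_variant_pattern <- function(group, matrix) {
  sub <- matrix$M[, group, drop = FALSE]
  rows <- which(rowSums(sub == 0L) == length(group))
  if (length(rows) == 0L) return(NULL)
  list(read_idx = rows, loci = as.integer(group),
       a = length(rows), b = length(group))
}

#' Log10 union bound on an all-error submatrix
#'
#' In an `n x m` binary matrix there are `C(n,a) * C(m,b)` submatrices of
#' size `a x b`; under independent per-base errors at rate at most `s`, each
#' is all-error with probability at most `s^(ab)`. The union bound therefore
#' caps the probability of observing any such pattern at
#' `s^(ab) * C(n,a) * C(m,b)`. Computed in log space via `lchoose`, so no
#' overflow for any realistic matrix size.
#'
#' @param n,m Matrix dimensions (reads, candidate columns).
#' @param a,b Pattern dimensions, `1 <= a <= n`, `1 <= b <= m`.
#' @param s Error bound in (0, 1).
#' @return `log10` of the bound (may exceed 0; the bound is not a
#'   probability when it exceeds 1).
#' @examples
#' log10_pattern_bound(100, 500, 5, 10, 0.15)
#' @export
log10_pattern_bound <- function(n, m, a, b, s) {
  if (a < 1 || b < 1 || a > n || b > m) {
    abort("pattern dimensions must satisfy 1 <= a <= n and 1 <= b <= m")
  }
  if (s <= 0 || s >= 1) abort("`s` must be in (0, 1)")
  a * b * log10(s) + (lchoose(n, a) + lchoose(m, b)) / log(10)
}

#' Test a variant pattern against the union bound
#'
#' The null hypothesis is that the pattern's `a x b` all-non-reference
#' submatrix arose from independent sequencing errors; it is rejected when
#' the union bound is at most `alpha`.
#'
#' @param pattern A pattern from [extract_variant_pattern()].
#' @param n,m Host matrix dimensions (reads, candidate columns).
#' @param s Error bound from the window's `error_model`.
#' @param alpha Rejection threshold (default 0.001); significant when
#'   `bound <= alpha`.
#' @return A list with `log10_bound`, `alpha`, `significant`.
#' @export
test_pattern <- function(pattern, n, m, s, alpha = 0.001) {
  lb <- log10_pattern_bound(n, m, pattern$a, pattern$b, s)
  list(log10_bound = lb, alpha = alpha, significant = lb <= log10(alpha))
}
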