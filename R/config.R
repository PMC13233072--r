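#' Caller configuration
#'
#' Collects every tunable constant of the caller in one validated object.
#' The defaults are the published operating point of the method: the
#' per-base error bound is three times the measured read-reference
#' divergence, candidate loci must show alternative alleles in more than 5%
#' of covering reads, column pairs are grouped below a chi-square p-value of
#' 0.05, multi-locus patterns and obvious SNPs are accepted at alpha = 0.001,
#' high-noise loci are rescued below 1e-6, and coordinate clusters need at
#' least five reads.
#'
#' @param window_length Reference window length in bp, or `NULL` to derive
#'   it as half the median read length (floored, bounded below by
#'   `min_window_length`).
#' @param min_window_length Lower bound for the window length in bp.
#' @param min_alt_frac Candidate-locus filter: a pileup column is a candidate
#'   when alternative alleles appear in strictly more than this fraction of
#'   the reads covering it.
#' @param pair_pvalue_cutoff Complete-linkage cutoff on pairwise chi-square
#'   p-values used to group correlated columns.
#' @param alpha Rejection threshold for the union-bound pattern test
#'   (significant when bound <= alpha) and for the obvious-SNP binomial test
#'   (called when p < alpha).
#' @param rescue_pvalue Chi-square p-value threshold (strict `<`) for rescuing
#'   loci correlated with confirmed SNPs.
#' @param error_multiplier Inflation factor applied to the measured
#'   divergence to obtain the error bound `s`.
#' @param s_floor,s_cap Clamp applied to `s` so it stays inside (0, 1).
#' @param min_cluster_size Minimum number of reads sharing exact mapping
#'   coordinates to form a coordinate cluster.
#' @param min_pair_overlap Minimum number of reads covering both columns for
#'   a pairwise chi-square test; below it the pair's p-value is 1.
#' @param max_rounds Maximum number of mask-and-recall rounds per window.
#' @param thread_count Accepted for interface compatibility; windows are
#'   independent work units and are processed sequentially, so results do
#'   not depend on this value.
#' @param random_seed Seed forwarded to the simulator; ignored by the caller.
#'
#' @return An object of class `caller_config` (a named list).
#' @examples
#' cfg <- caller_config(min_alt_frac = 0.1)
#' cfg$alpha
#' @export
caller_config <- function(window_length = NULL,
                          min_window_length = 500L,
                          min_alt_frac = 0.05,
                          pair_pvalue_cutoff = 0.05,
                          alpha = 0.001,
                          rescue_pvalue = 1e-6,
                          error_multiplier = 3,
                          s_floor = 0.01,
                          s_cap = 0.95,
                          min_cluster_size = 5L,
                          min_pair_overlap = 10L,
                          max_rounds = 5L,
                          thread_count = 1L,
                          random_seed = NULL) {
  probs <- list(min_alt_frac = min_alt_frac,
                pair_pvalue_cutoff = pair_pvalue_cutoff,
                alpha = alpha,
                rescue_pvalue = rescue_pvalue,
                s_floor = s_floor,
                s_cap = s_cap)
  for (nm in names(probs)) {
    p <- probs[[nm]]
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1) {
      abort(sprintf("`%s` must be a single number in (0, 1), got %s",
                    nm, deparse(p)))
    }
  }
  if (s_floor > s_cap) abort("`s_floor` must not exceed `s_cap`")
  if (!is.numeric(error_multiplier) || error_multiplier <= 0) {
    abort("`error_multiplier` must be > 0")
  }
  if (!is.null(window_length) &&
      (!is.numeric(window_length) || window_length < 1)) {
    abort("`window_length` must be NULL or a positive integer")
  }
  structure(list(
    window_length = if (is.null(window_length)) NULL else as.integer(window_length),
    min_window_length = as.integer(min_window_length),
    min_alt_frac = min_alt_frac,
    pair_pvalue_cutoff = pair_pvalue_cutoff,
    alpha = alpha,
    rescue_pvalue = rescue_pvalue,
    error_multiplier = error_multiplier,
    s_floor = s_floor,
    s_cap = s_cap,
    min_cluster_size = as.integer(min_cluster_size),
    min_pair_overlap = as.integer(min_pair_overlap),
    max_rounds = as.integer(max_rounds),
    thread_count = as.integer(thread_count),
    random_seed = random_seed
  ), class = "caller_config")
}

#' @export
print.caller_config <- function(x, ...) {
  cat("<caller_config>\n")
  flds <- x[!vapply(x, is.null, logical(1))]
  for (nm in names(flds)) cat(sprintf("  %-20s %s\n", nm, format(flds[[nm]])))
  invisible(x)
}
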