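#' Simulate strain haplotypes from a common ancestor
#'
#' A random ancestor sequence over A/C/G/T is mutated independently per
#' strain: each base changes, with probability `divergence`, to a uniformly
#' chosen different base. Strain 1 is designated the reference; the truth
#' set contains every (position, alternative base) at which at least one
#' other strain differs from the reference, with its carrier strains.
#'
#' @param ancestor_length Length of the simulated contig in bp.
#' @param strain_count Number of strains `k` (>= 1).
#' @param divergence Per-base substitution probability per strain.
#' @param seed Optional RNG seed for reproducibility.
#' @param contig Contig name used downstream.
#' @return An object of class `sim_truth`: reference and per-strain
#'   haplotypes (integer base codes) plus a `truth` tibble with 1-based
#'   `pos`, `ref`, `alt` and a `strains` list-column.
#' @examples
#' tr <- simulate_haplotypes(1000, strain_count = 2, divergence = 0.01, seed = 1)
#' nrow(tr$truth)
#' @export
simulate_haplotypes <- function(ancestor_length, strain_count = 2L,
                                divergence = 0.01, seed = NULL,
                                contig = "sim_contig") {
  stopifnot(ancestor_length >= 1, strain_count >= 1)
  if (divergence < 0 || divergence >= 1) abort("`divergence` must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  anc <- sample.int(4L, ancestor_length, replace = TRUE)
  haps <- matrix(anc, nrow = strain_count, ncol = ancestor_length, byrow = TRUE)
  if (divergence > 0) {
    for (k in seq_len(strain_count)) {
      mut <- which(stats::runif(ancestor_length) < divergence)
      if (length(mut) > 0L) {
        # uniform among the three other bases
        shift <- sample.int(3L, length(mut), replace = TRUE)
        haps[k, mut] <- ((haps[k, mut] - 1L + shift) %% 4L) + 1L
      }
    }
  }
  ref <- haps[1L, ]
  truth_rows <- list()
  if (strain_count > 1L) {
    diffs <- which(colSums(haps != matrix(ref, strain_count, ancestor_length,
                                          byrow = TRUE)) > 0L)
    for (p in diffs) {
      alts <- haps[-1L, p]
      alts <- alts[alts != ref[p]]
      for (ab in unique(alts)) {
        carriers <- which(haps[, p] == ab & seq_len(strain_count) != 1L)
        truth_rows[[length(truth_rows) + 1L]] <- tibble(
          pos = p, ref = code_to_base(ref[p]), alt = code_to_base(ab),
          strains = list(carriers))
      }
    }
  }
  truth <- if (length(truth_rows) == 0L) {
    tibble(pos = integer(), ref = character(), alt = character(),
           strains = list())
  } else {
    arrange(bind_rows(truth_rows), .data$pos, .data$alt)
  }
  structure(list(contig = contig, reference = ref, haplotypes = haps,
                 ancestor = anc, divergence = divergence, truth = truth),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %s: %d bp, %d strains, %d truth variants\n",
              x$contig, length(x$reference), nrow(x$haplotypes), nrow(x$truth)))
  invisible(x)
}

#' Simulate aligned long reads from strain haplotypes
#'
#' Per strain, reads of fixed length are sampled uniformly along the
#' haplotype to the target mean depth; each base is flipped to a uniformly
#' chosen different base with probability `error_rate`. Substitution-only
#' simulation means every read aligns exactly at its true coordinates, so
#' reads are emitted pre-aligned and tests stay hermetic. An optional
#' partial-read mode adds groups of reads clipped to a shared sub-interval
#' with identical coordinates, exercising coordinate clustering.
#'
#' @param truth A `sim_truth` from [simulate_haplotypes()].
#' @param coverages Per-strain mean depth (recycled to the strain count).
#' @param read_length Read length in bp (capped at the contig length).
#' @param error_rate Per-base i.i.d. substitution error probability.
#' @param seed Optional RNG seed.
#' @param partial_groups Number of identical-coordinate partial read groups
#'   to add (default 0).
#' @param partial_group_size Reads per partial group (default 6).
#' @param partial_length Length of partial reads (default `read_length %/% 4`).
#' @return An alignment tibble (`read_id`, `strain`, `contig`, `start`,
#'   `end`, `score`, `nm`, `bases` list-column of integer codes).
#' @export
simulate_reads <- function(truth, coverages = 20, read_length = 10000L,
                           error_rate = 0.05, seed = NULL,
                           partial_groups = 0L, partial_group_size = 6L,
                           partial_length = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  if (error_rate < 0 || error_rate >= 1) abort("`error_rate` must be in [0, 1)")
  if (any(coverages <= 0)) abort("`coverages` must be positive")
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(truth$haplotypes)
  L <- length(truth$reference)
  read_length <- as.integer(min(read_length, L))
  coverages <- rep_len(coverages, k)

  sample_read <- function(strain, start, len, id) {
    b <- truth$haplotypes[strain, (start + 1L):(start + len)]
    if (error_rate > 0) {
      errs <- which(stats::runif(len) < error_rate)
      if (length(errs) > 0L) {
        shift <- sample.int(3L, length(errs), replace = TRUE)
        b[errs] <- ((b[errs] - 1L + shift) %% 4L) + 1L
      }
    }
    nm <- sum(b != truth$reference[(start + 1L):(start + len)])
    tibble(read_id = id, strain = strain, contig = truth$contig,
           start = as.integer(start), end = as.integer(start + len),
           score = len - 2L * nm, nm = nm, bases = list(b))
  }

  reads <- list()
  for (strain in seq_len(k)) {
    n_reads <- max(1L, as.integer(round(coverages[strain] * L / read_length)))
    starts <- if (read_length >= L) rep(0L, n_reads) else
      sample.int(L - read_length + 1L, n_reads, replace = TRUE) - 1L
    for (i in seq_len(n_reads)) {
      reads[[length(reads) + 1L]] <- sample_read(
        strain, starts[i], read_length,
        sprintf("s%02d_r%05d", strain, i))
    }
  }
  if (partial_groups > 0L) {
    if (is.null(partial_length)) partial_length <- max(read_length %/% 4L, 100L)
    partial_length <- as.integer(min(partial_length, L))
    for (g in seq_len(partial_groups)) {
      strain <- ((g - 1L) %% k) + 1L
      start <- if (partial_length >= L) 0L else
        sample.int(L - partial_length + 1L, 1L) - 1L
      for (i in seq_len(partial_group_size)) {
        reads[[length(reads) + 1L]] <- sample_read(
          strain, start, partial_length,
          sprintf("s%02d_p%02d_%02d", strain, g, i))
      }
    }
  }
  bind_rows(reads)
}

#' Score calls against the simulated truth
#'
#' Matches on exact 1-based (position, alternative base), SNPs only.
#' Recall is matched truth variants over all truth variants; precision is
#' matched calls over all calls. With zero calls the precision is reported
#' as 1.0 and flagged undefined.
#'
#' @param calls A `snp_calls` object or a call tibble with `pos` (1-based)
#'   and `alt`.
#' @param truth A `sim_truth` or its `truth` tibble.
#' @return A one-row tibble: `recall`, `precision`, `n_truth`, `n_calls`,
#'   `n_matched`, `precision_defined`.
#' @export
evaluate_calls <- function(calls, truth) {
  if (inherits(calls, "snp_calls")) calls <- calls$calls
  if (inherits(truth, "sim_truth")) truth <- truth$truth
  key <- function(pos, alt) {
    if (length(pos) == 0L) character(0) else unique(paste0(pos, ":", alt))
  }
  ck <- key(calls$pos, calls$alt)
  tk <- key(truth$pos, truth$alt)
  matched <- sum(tk %in% ck)
  n_calls <- length(ck)
  tibble(
    recall = if (length(tk) == 0L) 1.0 else matched / length(tk),
    precision = if (n_calls == 0L) 1.0 else sum(ck %in% tk) / n_calls,
    n_truth = length(tk), n_calls = n_calls, n_matched = matched,
    precision_defined = n_calls > 0L
  )
}
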