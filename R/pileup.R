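#' Window length from read lengths
#'
#' The reference is tiled with fixed-length windows of half the median read
#' length: long enough to span several loci, short enough that many reads
#' cover a window end to end. An even-count median is the mean of the two
#' middle values; the result is floored and bounded below by
#' `min_window_length`.
#'
#' @param read_lengths Positive integer vector of read lengths.
#' @param min_window_length Lower bound in bp (default 500).
#' @return A single integer window length.
#' @examples
#' compute_window_length(c(10000, 10000, 10000))
#' compute_window_length(c(2000, 4000, 6000, 8000))
#' @export
compute_window_length <- function(read_lengths, min_window_length = 500L) {
  if (length(read_lengths) == 0L) {
    abort("no usable reads: cannot derive a window length")
  }
  if (any(!is.finite(read_lengths)) || any(read_lengths <= 0)) {
    abort("`read_lengths` must be positive and finite")
  }
  wl <- floor(median(as.numeric(read_lengths)) / 2)
  max(as.integer(wl), as.integer(min_window_length))
}

#' Tile a contig with windows
#'
#' Non-overlapping, ordered windows covering `[0, contig_length)`; the last
#' window may be shorter. Coordinates are 0-based half-open.
#'
#' @param contig Contig name.
#' @param contig_length Contig length in bp.
#' @param window_length Window length in bp.
#' @return A tibble with columns `contig`, `start`, `end`, `index`.
#' @export
make_windows <- function(contig, contig_length, window_length) {
  starts <- seq(0L, contig_length - 1L, by = window_length)
  tibble(
    contig = contig,
    start = as.integer(starts),
    end = as.integer(pmin(starts + window_length, contig_length)),
    index = seq_along(starts)
  )
}

#' Keep the best alignment of each read
#'
#' Exactly one alignment per `read_id` survives: the one with maximal
#' `score`; ties are broken by the lexicographically smallest
#' `(contig, start)`.
#'
#' @param alignments Alignment tibble with at least `read_id`, `contig`,
#'   `start`, `score`.
#' @return The filtered alignment tibble.
#' @export
select_best_alignments <- function(alignments) {
  if (nrow(alignments) == 0L) return(alignments)
  alignments |>
    arrange(.data$read_id, desc(.data$score), .data$contig, .data$start) |>
    distinct(.data$read_id, .keep_all = TRUE)
}

new_binmat <- function(window, read_ids, positions, ref, obs, M,
                       candidate = NULL, m = NA_integer_) {
  structure(list(
    window = window, read_ids = read_ids, positions = positions,
    ref = ref, obs = obs, M = M, candidate = candidate, m = m
  ), class = "binmat")
}

#' Build the binary read-by-locus matrix of a window
#'
#' Rows are the reads whose alignment spans the whole window
#' (`start <= window.start` and `end >= window.end`); columns are the
#' window's reference positions. `M[i, j] = 1` when read `i` shows the
#' reference base at position `j`; substitutions and deletion marks give 0.
#' The observed base codes are retained for allele reporting.
#'
#' @param window One-row window tibble (`contig`, `start`, `end`, `index`).
#' @param alignments Best-selected alignment tibble with a `bases`
#'   list-column of integer base codes over `[start, end)`.
#' @param ref Integer base codes of the reference over the window.
#' @return A `binmat` object; zero spanning reads give a 0-row matrix.
#' @export
build_binary_matrix <- function(window, alignments, ref) {
  ws <- window$start[1]; we <- window$end[1]
  len <- we - ws
  stopifnot(length(ref) == len)
  span <- alignments$start <= ws & alignments$end >= we
  rows <- alignments[span, , drop = FALSE]
  n <- nrow(rows)
  obs <- matrix(0L, nrow = n, ncol = len)
  if (n > 0L) {
    for (i in seq_len(n)) {
      b <- rows$bases[[i]]
      off <- ws - rows$start[i]
      obs[i, ] <- b[(off + 1L):(off + len)]
    }
  }
  M <- matrix(0L, nrow = n, ncol = len)
  if (n > 0L) {
    M[] <- as.integer(obs == matrix(ref, nrow = n, ncol = len, byrow = TRUE))
  }
  new_binmat(window, rows$read_id, ws:(we - 1L), ref, obs, M)
}

#' @export
print.binmat <- function(x, ...) {
  cat(sprintf("<binmat> %s:[%d,%d) %d reads x %d positions; candidates: %s\n",
              x$window$contig[1], x$window$start[1], x$window$end[1],
              nrow(x$M), ncol(x$M),
              if (is.na(x$m)) "unfiltered" else as.character(x$m)))
  invisible(x)
}

#' @export
dim.binmat <- function(x) dim(x$M)

#' Estimate the per-window error bound
#'
#' The error rate is measured as the divergence of the reads to the
#' reference inside the window — non-reference bases (substitutions and
#' deletion marks) over aligned bases — and deliberately over-estimated as
#' `error_multiplier` times that divergence, clamped to
#' `[s_floor, s_cap]`. The inflation keeps the bound above the true local
#' error rate in error-prone regions such as homopolymers.
#'
#' @param alignments Alignment tibble overlapping the window (all reads, not
#'   only spanning ones).
#' @param window One-row window tibble.
#' @param ref Integer base codes of the reference over the window.
#' @param config A [caller_config()].
#' @return An `error_model` object with fields `divergence`, `multiplier`,
#'   `s`, `floor`, `cap`, `mismatch`, `aligned`.
#' @export
estimate_error_rate <- function(alignments, window, ref, config = caller_config()) {
  ws <- window$start[1]; we <- window$end[1]
  mm <- 0; al <- 0
  for (i in seq_len(nrow(alignments))) {
    s <- max(alignments$start[i], ws); e <- min(alignments$end[i], we)
    if (e <= s) next
    b <- alignments$bases[[i]][(s - alignments$start[i] + 1L):(e - alignments$start[i])]
    r <- ref[(s - ws + 1L):(e - ws)]
    cov <- b != 0L
    al <- al + sum(cov)
    mm <- mm + sum(cov & b != r)
  }
  error_model_from_counts(mm, al, config)
}

#' Error bound from mismatch counts
#'
#' @param mismatch Number of non-reference bases.
#' @param aligned Number of aligned bases (> 0).
#' @param config A [caller_config()].
#' @return An `error_model` object.
#' @examples
#' # 31 non-reference bases out of 336 aligned: s = 3 * 31/336 = 0.28
#' error_model_from_counts(31, 336)$s
#' @export
error_model_from_counts <- function(mismatch, aligned, config = caller_config()) {
  if (aligned <= 0) abort("zero aligned bases: cannot estimate divergence")
  div <- mismatch / aligned
  s <- min(max(config$error_multiplier * div, config$s_floor), config$s_cap)
  structure(list(divergence = div, multiplier = config$error_multiplier,
                 s = s, floor = config$s_floor, cap = config$s_cap,
                 mismatch = mismatch, aligned = aligned),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("<error_model> divergence %.4f (%d/%d), s = %.4f\n",
              x$divergence, x$mismatch, x$aligned, x$s))
  invisible(x)
}

#' Mark candidate columns
#'
#' A pileup column is a candidate locus when alternative alleles appear in
#' strictly more than `min_alt_frac` of the reads covering it. Filtering
#' shrinks the matrix dimension `m` that enters the union bound, which both
#' speeds up the all-pairs correlation step and strengthens the test.
#'
#' @param matrix A `binmat`.
#' @param min_alt_frac Fraction in (0, 1); default 0.05.
#' @return The `binmat` with `candidate` mask and `m` filled in.
#' @export
filter_candidate_columns <- function(matrix, min_alt_frac = 0.05) {
  stopifnot(inherits(matrix, "binmat"))
  if (min_alt_frac <= 0 || min_alt_frac >= 1) {
    abort("`min_alt_frac` must be in (0, 1)")
  }
  n <- nrow(matrix$M)
  if (n == 0L) {
    matrix$candidate <- logical(ncol(matrix$M))
    matrix$m <- 0L
    return(matrix)
  }
  alt <- colSums(matrix$M == 0L)
  matrix$candidate <- (alt / n) > min_alt_frac
  matrix$m <- sum(matrix$candidate)
  matrix
}

#' Cluster reads by exact mapping coordinates
#'
#' Reads that map to only part of a window often come from strains with
#' structural differences to the reference; groups of at least
#' `min_size` reads sharing exactly the same `(start, end)` coordinates are
#' analysed as their own matrices, while the remaining partial reads go to
#' the residual (they still count toward per-position coverage).
#'
#' @param window One-row window tibble.
#' @param alignments Alignment tibble overlapping the window.
#' @param min_size Minimum cluster size (default 5).
#' @return A list with `clusters` (list of read-id character vectors, each
#'   with attributes `start`/`end`) and `residual` (read ids in no cluster).
#' @export
cluster_reads_by_coordinates <- function(window, alignments, min_size = 5L) {
  if (nrow(alignments) == 0L) {
    return(list(clusters = list(), residual = character()))
  }
  key <- paste(alignments$start, alignments$end, sep = ":")
  groups <- split(seq_len(nrow(alignments)), key)
  clusters <- list()
  residual <- character()
  for (g in groups) {
    if (length(g) >= min_size) {
      ids <- alignments$read_id[g]
      attr(ids, "start") <- alignments$start[g[1]]
      attr(ids, "end") <- alignments$end[g[1]]
      clusters[[length(clusters) + 1L]] <- ids
    } else {
      residual <- c(residual, alignments$read_id[g])
    }
  }
  ord <- order(map_int(clusters, function(x) attr(x, "start")),
               map_int(clusters, function(x) attr(x, "end")))
  list(clusters = clusters[ord], residual = residual)
}

#' Per-position allele counts over all reads in a window
#'
#' Counts every covering best alignment, spanning or not, so the coverage
#' `c` of the binomial obvious-SNP test reflects the full pileup.
#'
#' @param window One-row window tibble.
#' @param alignments Alignment tibble overlapping the window.
#' @return A 5 x window-length integer matrix; rows follow the base codes
#'   A, C, G, T, deletion.
#' @export
window_pileup_counts <- function(window, alignments) {
  ws <- window$start[1]; we <- window$end[1]
  len <- we - ws
  idx <- vector("list", nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    s <- max(alignments$start[i], ws); e <- min(alignments$end[i], we)
    if (e <= s) next
    b <- alignments$bases[[i]][(s - alignments$start[i] + 1L):(e - alignments$start[i])]
    pos <- (s - ws):(e - ws - 1L)
    covered <- b != 0L
    idx[[i]] <- b[covered] + 5L * pos[covered]
  }
  tb <- tabulate(unlist(idx), nbins = 5L * len)
  matrix(tb, nrow = 5L)
}
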