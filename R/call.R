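STATUS_LEVELS <- c("MULTILOCUS", "OBVIOUS", "RESCUED")

call_keys <- function(df) {
  if (nrow(df) == 0L) character(0) else paste0(df$pos0, ":", df$alt)
}

empty_calls <- function() {
  tibble(contig = character(), pos0 = integer(), ref = character(),
         alt = character(), support = integer(), depth = integer(),
         status = character(), log10_p = double(), round = integer())
}

# Majority non-reference, non-gap base among given rows at matrix column j;
# ties broken alphabetically. NA when only deletion marks are present.
majority_alt_base <- function(matrix, rows, j) {
  obs <- matrix$obs[rows, j]
  obs <- obs[obs != 0L & obs != matrix$ref[j] & obs != 5L]
  if (length(obs) == 0L) return(NA_character_)
  tab <- tabulate(obs, nbins = 4L)
  BASE_LEVELS[which(tab == max(tab))[1L]]
}

# Multi-locus path on one (possibly cluster-restricted) matrix.
multilocus_calls <- function(bm, s, config, called_keys) {
  out <- list()
  n <- nrow(bm$M)
  if (n == 0L || ncol(bm$M) == 0L) return(empty_calls())
  bm <- filter_candidate_columns(bm, config$min_alt_frac)
  if (bm$m < 2L) return(empty_calls())
  cand <- which(bm$candidate)
  pmat <- pairwise_chi2_pvalues(bm$M, cand, config$min_pair_overlap,
                                max_p_exact = config$pair_pvalue_cutoff)
  groups <- complete_linkage_groups(pmat, config$pair_pvalue_cutoff)
  for (g in groups) {
    cols <- cand[g]
    pat <- extract_variant_pattern(cols, bm)
    if (is.null(pat)) next
    res <- test_pattern(pat, n = n, m = bm$m, s = s, alpha = config$alpha)
    if (!res$significant) next
    for (j in cols) {
      alt <- majority_alt_base(bm, pat$read_idx, j)
      if (is.na(alt)) next
      key <- paste0(bm$positions[j], ":", alt)
      if (key %in% called_keys) next
      called_keys <- c(called_keys, key)
      out[[length(out) + 1L]] <- tibble(
        contig = bm$window$contig[1], pos0 = bm$positions[j],
        ref = code_to_base(bm$ref[j]), alt = alt,
        support = pat$a, depth = sum(bm$obs[, j] != 0L),
        status = "MULTILOCUS", log10_p = res$log10_bound,
        round = NA_integer_)
    }
  }
  if (length(out) == 0L) empty_calls() else bind_rows(out)
}

#' Call SNPs in one window
#'
#' Runs the full per-window pipeline: estimate the error bound, build the
#' spanning-read binary matrix and any coordinate-cluster matrices, then
#' iterate (candidate filter, pairwise chi-square grouping, union-bound
#' pattern test, binomial obvious-SNP scan, correlated-locus rescue),
#' masking each round's calls and re-running until a round adds nothing or
#' `max_rounds` is reached, so secondary alleles at multi-allelic sites
#' surface once the dominant variant is masked.
#'
#' @param window One-row window tibble.
#' @param alignments Best-selected alignments overlapping the window.
#' @param ref Integer base codes of the reference over the window.
#' @param config A [caller_config()].
#' @return A call tibble (`contig`, `pos0`, `ref`, `alt`, `support`,
#'   `depth`, `status`, `log10_p`, `round`).
#' @export
call_window <- function(window, alignments, ref, config = caller_config()) {
  if (nrow(alignments) == 0L) return(empty_calls())
  err <- tryCatch(estimate_error_rate(alignments, window, ref, config),
                  error = function(e) NULL)
  if (is.null(err)) return(empty_calls())
  s <- err$s
  counts <- window_pileup_counts(window, alignments)

  matrices <- list(build_binary_matrix(window, alignments, ref))
  cl <- cluster_reads_by_coordinates(window, alignments, config$min_cluster_size)
  ws <- window$start[1]; we <- window$end[1]
  for (ids in cl$clusters) {
    cs <- max(attr(ids, "start"), ws); ce <- min(attr(ids, "end"), we)
    if (cs <= ws && ce >= we) next      # spanning cluster: already in the main matrix
    if (ce - cs < 1L) next
    sub <- alignments[alignments$read_id %in% ids, , drop = FALSE]
    cw <- tibble(contig = window$contig[1], start = cs, end = ce,
                 index = window$index[1])
    matrices[[length(matrices) + 1L]] <-
      build_binary_matrix(cw, sub, ref[(cs - ws + 1L):(ce - ws)])
  }

  all_calls <- empty_calls()
  for (rnd in seq_len(config$max_rounds)) {
    called_keys <- call_keys(all_calls)
    round_calls <- empty_calls()

    for (bm in matrices) {
      keys <- c(called_keys, call_keys(round_calls))
      round_calls <- bind_rows(round_calls, multilocus_calls(bm, s, config, keys))
    }

    obv <- call_obvious_snps(counts, ref, ws, s, config$alpha)
    if (nrow(obv) > 0L) {
      keys <- c(called_keys, call_keys(round_calls))
      obv <- obv[!(paste0(obv$pos0, ":", obv$alt) %in% keys), , drop = FALSE]
      if (nrow(obv) > 0L) {
        round_calls <- bind_rows(round_calls, tibble(
          contig = window$contig[1], pos0 = obv$pos0, ref = obv$ref,
          alt = obv$alt, support = as.integer(obv$support),
          depth = obv$depth, status = "OBVIOUS", log10_p = obv$log10_p,
          round = NA_integer_))
      }
    }

    # rescue against this round's confirmed loci, before masking erases them
    for (bm in matrices) {
      conf <- match(unique(round_calls$pos0), bm$positions)
      conf <- conf[!is.na(conf)]
      if (length(conf) == 0L) next
      keys <- c(called_keys, call_keys(round_calls))
      res <- rescue_correlated_loci(bm, conf, keys,
                                    threshold = config$rescue_pvalue,
                                    min_overlap = config$min_pair_overlap)
      if (nrow(res) > 0L) {
        round_calls <- bind_rows(round_calls, tibble(
          contig = window$contig[1], pos0 = res$pos0, ref = res$ref,
          alt = res$alt, support = as.integer(res$support),
          depth = res$depth, status = "RESCUED", log10_p = res$log10_p,
          round = NA_integer_))
      }
    }

    if (nrow(round_calls) == 0L) break
    round_calls <- round_calls |>
      mutate(round = rnd,
             prio = match(.data$status, STATUS_LEVELS)) |>
      arrange(.data$pos0, .data$alt, .data$prio) |>
      distinct(.data$pos0, .data$alt, .keep_all = TRUE) |>
      dplyr::select(-"prio")
    all_calls <- bind_rows(all_calls, round_calls)

    matrices <- map(matrices, mask_called_variants, calls = round_calls)
    counts <- mask_pileup_counts(counts, ref, ws, round_calls)
  }
  all_calls
}

#' Call SNPs from in-memory alignments
#'
#' Windowed driver over one contig: selects best alignments, derives the
#' window length (half the median read length unless overridden), tiles the
#' contig and calls each window. This is the hermetic entry point the
#' simulator-based tests use; [snp_call()] wraps it for BAM/FASTA input.
#'
#' @param alignments Alignment tibble (`read_id`, `contig`, `start`, `end`,
#'   `score`, `bases` list-column of integer base codes).
#' @param ref_codes Integer base codes of the whole contig.
#' @param contig Contig name.
#' @param config A [caller_config()].
#' @return An object of class `snp_calls`.
#' @export
call_alignments <- function(alignments, ref_codes, contig = "contig_1",
                            config = caller_config()) {
  best <- select_best_alignments(alignments)
  wl <- config$window_length
  if (is.null(wl)) {
    wl <- compute_window_length(best$end - best$start, config$min_window_length)
  }
  windows <- make_windows(contig, length(ref_codes), wl)
  calls <- vector("list", nrow(windows))
  summaries <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    win <- windows[w, ]
    keep <- best$contig == contig & best$start < win$end & best$end > win$start
    aln <- best[keep, , drop = FALSE]
    ref <- ref_codes[(win$start + 1L):win$end]
    wcalls <- call_window(win, aln, ref, config)
    calls[[w]] <- wcalls
    summaries[[w]] <- tibble(
      contig = contig, index = win$index, start = win$start, end = win$end,
      n_reads = nrow(aln),
      n_spanning = sum(aln$start <= win$start & aln$end >= win$end),
      n_calls = nrow(wcalls))
  }
  new_snp_calls(bind_rows(calls), bind_rows(summaries), config,
                setNames(length(ref_codes), contig))
}

new_snp_calls <- function(calls, windows, config, contig_lengths) {
  calls <- calls |>
    mutate(pos = .data$pos0 + 1L) |>
    arrange(.data$contig, .data$pos, .data$alt)
  structure(list(calls = calls, windows = windows, config = config,
                 contig_lengths = contig_lengths),
            class = "snp_calls")
}

#' @export
print.snp_calls <- function(x, ...) {
  cat(sprintf("<snp_calls> %d calls over %d windows (%s)\n",
              nrow(x$calls), nrow(x$windows),
              paste(names(x$contig_lengths), collapse = ", ")))
  st <- table(factor(x$calls$status, levels = STATUS_LEVELS))
  cat("  ", paste(sprintf("%s: %d", names(st), st), collapse = "  "), "\n")
  invisible(x)
}

#' Run the caller on a BAM/FASTA pair
#'
#' Orchestrates the whole pipeline: stream windows from a coordinate-sorted,
#' indexed BAM against an indexed reference FASTA, call each window, merge
#' the per-window results in genomic order, and (optionally) write VCF.
#'
#' @param bam_path Path to a coordinate-sorted BAM with a `.bai` index.
#' @param fasta_path Path to the reference FASTA (a `.fai` index is created
#'   if absent).
#' @param config A [caller_config()].
#' @param vcf_path Optional output VCF path; written when not `NULL`.
#' @param verbose Emit one summary line per window.
#' @return An object of class `snp_calls`.
#' @export
snp_call <- function(bam_path, fasta_path, config = caller_config(),
                     vcf_path = NULL, verbose = FALSE) {
  streamed <- stream_windows(bam_path, fasta_path, config)
  calls <- vector("list", length(streamed$windows_list))
  summaries <- vector("list", length(streamed$windows_list))
  for (w in seq_along(streamed$windows_list)) {
    item <- streamed$windows_list[[w]]
    wcalls <- call_window(item$window, item$alignments, item$ref, config)
    calls[[w]] <- wcalls
    summaries[[w]] <- tibble(
      contig = item$window$contig[1], index = item$window$index[1],
      start = item$window$start[1], end = item$window$end[1],
      n_reads = nrow(item$alignments),
      n_spanning = sum(item$alignments$start <= item$window$start[1] &
                         item$alignments$end >= item$window$end[1]),
      n_calls = nrow(wcalls))
    if (verbose) {
      inform(sprintf("window %s:%d-%d reads=%d calls=%d",
                     item$window$contig[1], item$window$start[1],
                     item$window$end[1], nrow(item$alignments), nrow(wcalls)))
    }
  }
  res <- new_snp_calls(bind_rows(calls), bind_rows(summaries), config,
                       streamed$contig_lengths)
  if (!is.null(vcf_path)) write_vcf(res, vcf_path)
  res
}
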