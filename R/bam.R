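# Expand one alignment's query sequence onto reference space.
# Returns integer base codes over [pos0, pos0 + ref_width): A/C/G/T = 1..4,
# deletion = 5 (covers the reference), skipped region (N) = 0 (no coverage).
cigar_ref_bases <- function(cigar, seq_codes) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  kinds <- sub("^\\d+", "", ops)
  out <- integer(sum(lens[kinds %in% c("M", "=", "X", "D", "N")]))
  qpos <- 0L; rpos <- 0L
  for (i in seq_along(ops)) {
    len <- lens[i]
    switch(kinds[i],
      "M" = , "=" = , "X" = {
        out[(rpos + 1L):(rpos + len)] <- seq_codes[(qpos + 1L):(qpos + len)]
        qpos <- qpos + len; rpos <- rpos + len
      },
      "I" = { qpos <- qpos + len },
      "D" = { out[(rpos + 1L):(rpos + len)] <- 5L; rpos <- rpos + len },
      "N" = { out[(rpos + 1L):(rpos + len)] <- 0L; rpos <- rpos + len },
      "S" = { qpos <- qpos + len },
      NULL  # H, P consume nothing
    )
  }
  out
}

#' Read alignments from a BAM file
#'
#' Loads primary alignments (secondary, supplementary and unmapped records
#' are excluded) and expands each CIGAR into per-reference-position base
#' codes, the representation every downstream step works on. The alignment
#' score is the `AS` tag when present, otherwise aligned length minus twice
#' the `NM` edit distance.
#'
#' @param bam_path Path to a coordinate-sorted, indexed BAM.
#' @param contig Restrict to one contig (`NULL` = all).
#' @return An alignment tibble (`read_id`, `contig`, `start`, `end`,
#'   `score`, `nm`, `qwidth`, `bases`).
#' @export
read_alignments <- function(bam_path, contig = NULL) {
  if (!file.exists(bam_path)) abort(sprintf("BAM not found: %s", bam_path))
  if (!file.exists(paste0(bam_path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_path))) {
    abort(sprintf(
      "BAM index (.bai) not found for %s; run samtools index or Rsamtools::indexBam",
      bam_path))
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  what <- c("qname", "flag", "rname", "pos", "qwidth", "cigar", "seq")
  param <- Rsamtools::ScanBamParam(flag = flags, what = what,
                                   tag = c("NM", "AS"))
  res <- Rsamtools::scanBam(bam_path, param = param)
  parts <- vector("list", length(res))
  for (ch in seq_along(res)) {
    x <- res[[ch]]
    if (length(x$qname) == 0L) next
    keep <- if (is.null(contig)) rep(TRUE, length(x$qname)) else
      as.character(x$rname) == contig
    if (!any(keep)) next
    idx <- which(keep)
    seqs <- strsplit(as.character(x$seq[idx]), "")
    nm <- x$tag$NM[idx]
    as_tag <- x$tag$AS[idx]
    bases <- vector("list", length(idx))
    starts <- integer(length(idx)); ends <- integer(length(idx))
    for (i in seq_along(idx)) {
      codes <- base_to_code(seqs[[i]])
      codes[is.na(codes)] <- 0L           # ambiguity codes: no coverage
      b <- cigar_ref_bases(x$cigar[idx[i]], codes)
      starts[i] <- x$pos[idx[i]] - 1L     # 0-based half-open internally
      ends[i] <- starts[i] + length(b)
      bases[[i]] <- b
    }
    alen <- ends - starts
    score <- ifelse(!is.na(as_tag), as_tag,
                    alen - 2L * ifelse(is.na(nm), 0L, nm))
    parts[[ch]] <- tibble(
      read_id = x$qname[idx], contig = as.character(x$rname[idx]),
      start = starts, end = ends, score = as.numeric(score),
      nm = ifelse(is.na(nm), NA_integer_, as.integer(nm)),
      qwidth = as.integer(x$qwidth[idx]), bases = bases)
  }
  out <- bind_rows(parts)
  if (nrow(out) == 0L) {
    out <- tibble(read_id = character(), contig = character(),
                  start = integer(), end = integer(), score = double(),
                  nm = integer(), qwidth = integer(), bases = list())
  }
  out
}

read_fasta_codes <- function(fasta_path) {
  if (!file.exists(fasta_path)) abort(sprintf("FASTA not found: %s", fasta_path))
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  lapply(setNames(as.character(seqs), names(seqs)), function(s) {
    codes <- base_to_code(strsplit(s, "")[[1]])
    codes[is.na(codes)] <- 0L
    codes
  })
}

#' Stream a BAM as per-window work units
#'
#' Tiles every FASTA contig with windows of half the median read length
#' (or the configured override) and attaches to each window the best
#' alignment of every read overlapping it, plus the window's reference
#' codes. Contig names present in the BAM but absent from the FASTA are an
#' error; an empty BAM yields zero windows with a warning.
#'
#' @param bam_path Coordinate-sorted, indexed BAM.
#' @param fasta_path Reference FASTA.
#' @param config A [caller_config()].
#' @return A list with `windows_list` (each element: `window`, `alignments`,
#'   `ref`) and `contig_lengths`.
#' @export
stream_windows <- function(bam_path, fasta_path, config = caller_config()) {
  ref_codes <- read_fasta_codes(fasta_path)
  contig_lengths <- setNames(lengths(ref_codes), names(ref_codes))
  aln <- read_alignments(bam_path)
  if (nrow(aln) == 0L) {
    warn("BAM contains no usable alignments; zero windows to process")
    return(list(windows_list = list(), contig_lengths = contig_lengths))
  }
  missing <- setdiff(unique(aln$contig), names(ref_codes))
  if (length(missing) > 0L) {
    abort(sprintf(
      "contigs in BAM but not in FASTA: %s (check that reads were mapped to this reference)",
      paste(missing, collapse = ", ")))
  }
  best <- select_best_alignments(aln)
  wl <- config$window_length
  if (is.null(wl)) {
    wl <- compute_window_length(best$qwidth, config$min_window_length)
  }
  out <- list()
  for (ctg in names(ref_codes)) {
    caln <- best[best$contig == ctg, , drop = FALSE]
    if (nrow(caln) == 0L) next
    windows <- make_windows(ctg, contig_lengths[[ctg]], wl)
    for (w in seq_len(nrow(windows))) {
      win <- windows[w, ]
      keep <- caln$start < win$end & caln$end > win$start
      out[[length(out) + 1L]] <- list(
        window = win,
        alignments = caln[keep, , drop = FALSE],
        ref = ref_codes[[ctg]][(win$start + 1L):win$end])
    }
  }
  list(windows_list = out, contig_lengths = contig_lengths)
}

#' Write simulated reads as FASTA + sorted, indexed BAM
#'
#' Serialises a [simulate_reads()] result: the reference goes to
#' `<prefix>.fasta` (with `.fai`), the reads to `<prefix>.bam` (sorted,
#' with `.bai`), and the ground truth to `<prefix>.truth.vcf`. Reads are
#' substitution-only, so every CIGAR is a single match run and the `NM`
#' and `AS` tags carry the edit distance and score.
#'
#' @param reads Alignment tibble from [simulate_reads()].
#' @param truth The `sim_truth` the reads were drawn from.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default `"sim"`).
#' @return Named character vector of the written paths.
#' @export
write_sim_bam <- function(reads, truth, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, paste0(prefix, ".fasta"))
  seq <- Biostrings::DNAStringSet(paste(code_to_base(truth$reference),
                                        collapse = ""))
  names(seq) <- truth$contig
  Biostrings::writeXStringSet(seq, fasta)
  Rsamtools::indexFa(fasta)

  sam <- file.path(dir, paste0(prefix, ".sam"))
  con <- file(sam, "w")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", truth$contig,
                       length(truth$reference))), con)
  if (nrow(reads) > 0L) {
    recs <- character(nrow(reads))
    for (i in seq_len(nrow(reads))) {
      b <- reads$bases[[i]]
      recs[i] <- paste(
        reads$read_id[i], 0L, reads$contig[i], reads$start[i] + 1L, 60L,
        sprintf("%dM", length(b)), "*", 0L, 0L,
        paste(code_to_base(b), collapse = ""), "*",
        sprintf("NM:i:%d", reads$nm[i]),
        sprintf("AS:i:%d", reads$score[i]),
        sep = "\t")
    }
    writeLines(recs, con)
  }
  close(con)
  bam <- Rsamtools::asBam(sam, file.path(dir, prefix), overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  truth_vcf <- file.path(dir, paste0(prefix, ".truth.vcf"))
  write_truth_vcf(truth, truth_vcf)
  c(fasta = fasta, bam = bam, truth_vcf = truth_vcf)
}
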