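vcf_info_header <- c(
  '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth at the site">',
  '##INFO=<ID=SR,Number=A,Type=Integer,Description="Reads supporting the alternative allele">',
  '##INFO=<ID=LP,Number=A,Type=Float,Description="log10 of the evidence bound or p-value behind the call">',
  '##INFO=<ID=ST,Number=A,Type=String,Description="Call status: MULTILOCUS, OBVIOUS or RESCUED">',
  '##INFO=<ID=IT,Number=A,Type=Integer,Description="Mask-and-recall round that produced the call">'
)

#' Write calls as VCF v4.2
#'
#' Site-only records (no sample columns), 1-based positions, contig header
#' lines from the reference, and the caller's evidence in INFO fields
#' (`DP`, `SR`, `LP`, `ST`, `IT`). Co-located alternative alleles are
#' merged into one record with a comma-separated ALT in alphabetical
#' order. The body is deterministic for identical calls.
#'
#' @param calls A `snp_calls` object, or a call tibble plus
#'   `contig_lengths`.
#' @param path Output path.
#' @param contig_lengths Named vector of contig lengths (taken from a
#'   `snp_calls` object when given).
#' @return The path, invisibly.
#' @export
write_vcf <- function(calls, path, contig_lengths = NULL) {
  if (inherits(calls, "snp_calls")) {
    contig_lengths <- calls$contig_lengths
    calls <- calls$calls
  }
  if (is.null(contig_lengths)) abort("`contig_lengths` required")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=strainsnp",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            as.integer(contig_lengths)),
    vcf_info_header,
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(calls) == 0L) return(invisible(path))
  calls <- calls |>
    filter(.data$alt %in% c("A", "C", "G", "T"), .data$alt != .data$ref) |>
    arrange(.data$contig, .data$pos, .data$alt) |>
    distinct(.data$contig, .data$pos, .data$alt, .keep_all = TRUE)
  if (nrow(calls) == 0L) return(invisible(path))
  site <- paste(calls$contig, calls$pos, sep = ":")
  recs <- vapply(split(seq_len(nrow(calls)), factor(site, levels = unique(site))),
                 function(idx) {
    x <- calls[idx, ]
    info <- sprintf("DP=%d;SR=%s;LP=%s;ST=%s;IT=%s",
                    max(x$depth),
                    paste(x$support, collapse = ","),
                    paste(sprintf("%.4g", x$log10_p), collapse = ","),
                    paste(x$status, collapse = ","),
                    paste(x$round, collapse = ","))
    paste(x$contig[1], x$pos[1], ".", x$ref[1],
          paste(x$alt, collapse = ","), ".", ".", info, sep = "\t")
  }, character(1))
  writeLines(unname(recs), con)
  invisible(path)
}

#' Write a simulated truth set as VCF
#'
#' @param truth A `sim_truth`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_truth_vcf <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  tr <- truth$truth
  calls <- tibble(
    contig = truth$contig, pos = tr$pos, ref = tr$ref, alt = tr$alt,
    support = map_int(tr$strains, length), depth = map_int(tr$strains, length),
    status = "TRUTH", log10_p = 0, round = 0L)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=strainsnp-simulator",
    sprintf("##contig=<ID=%s,length=%d>", truth$contig,
            length(truth$reference)),
    '##INFO=<ID=CS,Number=1,Type=String,Description="Carrier strain indices (reference = strain 1)">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(tr) > 0L) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tCS=%s",
                       truth$contig, tr$pos, tr$ref, tr$alt,
                       map_chr(tr$strains, paste, collapse = "|")), con)
  }
  invisible(path)
}

#' Read a VCF body back as a call-like tibble
#'
#' Minimal reader used for round-trip checks and by the CLI's evaluation
#' path; splits merged ALT records back into one row per allele.
#'
#' @param path VCF path.
#' @return A tibble with `contig`, `pos`, `ref`, `alt`.
#' @export
read_vcf_sites <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    return(tibble(contig = character(), pos = integer(),
                  ref = character(), alt = character()))
  }
  f <- strsplit(body, "\t")
  bind_rows(map(f, function(x) {
    alts <- strsplit(x[5], ",")[[1]]
    tibble(contig = x[1], pos = as.integer(x[2]), ref = x[4], alt = alts)
  }))
}
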