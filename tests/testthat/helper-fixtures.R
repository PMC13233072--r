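# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# Alignment tibble row from a base string ("ACGT-" alphabet); start is the
# 0-based mapped start.
aln_row <- function(read_id, start, bases, contig = "ctg", score = NULL,
                    strain = 1L) {
  codes <- match(strsplit(bases, "")[[1]], c("A", "C", "G", "T", "-"))
  if (is.null(score)) score <- length(codes)
  tibble::tibble(read_id = read_id, strain = strain, contig = contig,
                 start = as.integer(start),
                 end = as.integer(start + length(codes)),
                 score = as.numeric(score),
                 nm = NA_integer_, bases = list(codes))
}

aln_tbl <- function(...) dplyr::bind_rows(...)

ref_codes <- function(bases) match(strsplit(bases, "")[[1]], c("A", "C", "G", "T"))

win_tbl <- function(start, end, contig = "ctg", index = 1L) {
  tibble::tibble(contig = contig, start = as.integer(start),
                 end = as.integer(end), index = index)
}

# A window fixture with block structure: `n_ref` all-reference reads and
# groups of reads carrying given alt bases at given 0-based positions.
# groups: list of list(n =, pos =, alt =) where pos/alt are parallel.
block_window <- function(len = 200, n_ref = 30, groups = list(),
                         ref_base = "A") {
  ref <- rep(match(ref_base, c("A", "C", "G", "T")), len)
  reads <- list()
  id <- 0L
  add_read <- function(codes) {
    id <<- id + 1L
    tibble::tibble(read_id = sprintf("r%03d", id), strain = 1L,
                   contig = "ctg", start = 0L, end = as.integer(len),
                   score = as.numeric(len), nm = NA_integer_,
                   bases = list(codes))
  }
  for (i in seq_len(n_ref)) reads[[length(reads) + 1L]] <- add_read(ref)
  for (g in groups) {
    for (i in seq_len(g$n)) {
      codes <- ref
      codes[g$pos + 1L] <- match(g$alt, c("A", "C", "G", "T", "-"))
      reads[[length(reads) + 1L]] <- add_read(codes)
    }
  }
  list(window = win_tbl(0, len), aln = dplyr::bind_rows(reads), ref = ref)
}

# Independent exact oracle for the 2x2 chi-square used throughout:
# N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) against the 1-d.f. survival function.
oracle_chi2_p <- function(a, b, c, d) {
  n <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  if (den == 0) return(1.0)
  stats::pchisq(n * (a * d - b * c)^2 / den, df = 1, lower.tail = FALSE)
}

# Independent exact binomial upper tail by log-space term summation.
oracle_binom_tail <- function(k, c, s) {
  if (k <= 0) return(1.0)
  j <- k:c
  sum(exp(lchoose(c, j) + j * log(s) + (c - j) * log1p(-s)))
}
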