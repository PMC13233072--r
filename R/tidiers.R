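#' Tidy a call set
#'
#' One row per called (position, alternative allele), in genomic order.
#'
#' @param x A `snp_calls` object.
#' @param ... Unused.
#' @return A tibble with `contig`, `pos` (1-based), `ref`, `alt`,
#'   `support`, `depth`, `status`, `log10_p`, `round`.
#' @method tidy snp_calls
#' @export
tidy.snp_calls <- function(x, ...) {
  x$calls |>
    dplyr::select("contig", "pos", "ref", "alt", "support", "depth",
                  "status", "log10_p", "round")
}

#' One-row summary of a caller run
#'
#' @param x A `snp_calls` object.
#' @param ... Unused.
#' @return A one-row tibble: windows processed, calls in total and by
#'   status, and the deepest mask-and-recall round used.
#' @method glance snp_calls
#' @export
glance.snp_calls <- function(x, ...) {
  st <- table(factor(x$calls$status, levels = STATUS_LEVELS))
  tibble(
    n_windows = nrow(x$windows),
    n_calls = nrow(x$calls),
    n_multilocus = as.integer(st[["MULTILOCUS"]]),
    n_obvious = as.integer(st[["OBVIOUS"]]),
    n_rescued = as.integer(st[["RESCUED"]]),
    max_round = if (nrow(x$calls) == 0L) 0L else max(x$calls$round)
  )
}

#' Plot called SNPs along the genome
#'
#' Each call is a point at its reference position, height the strength of
#' its evidence (`-log10` of the bound or p-value), coloured by the path
#' that produced it.
#'
#' @param object A `snp_calls` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot snp_calls
#' @export
autoplot.snp_calls <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$pos, y = pmax(-.data$log10_p, 0),
                colour = .data$status)) +
    geom_point(alpha = 0.7, size = 1) +
    facet_wrap(~contig, ncol = 1, scales = "free_x") +
    labs(x = "reference position (bp)",
         y = expression(-log[10] ~ "evidence bound"),
         colour = NULL,
         title = "Called SNPs") +
    theme_minimal()
}

#' Plot a window's binary matrix
#'
#' Reads by loci; reference-agreeing cells are light, alternative cells
#' dark — variant patterns appear as dark rectangles once rows and columns
#' carrying the same strain signal line up.
#'
#' @param object A `binmat`.
#' @param candidates_only Show only candidate columns (requires a prior
#'   [filter_candidate_columns()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot binmat
#' @export
autoplot.binmat <- function(object, candidates_only = FALSE, ...) {
  cols <- if (candidates_only && !is.null(object$candidate)) {
    which(object$candidate)
  } else {
    seq_len(ncol(object$M))
  }
  d <- tibble(
    read = rep(seq_len(nrow(object$M)), times = length(cols)),
    pos = rep(object$positions[cols] + 1L, each = nrow(object$M)),
    state = factor(as.vector(object$M[, cols, drop = FALSE]),
                   levels = c(1L, 0L),
                   labels = c("reference", "alternative")))
  ggplot(d, aes(x = factor(.data$pos), y = .data$read, fill = .data$state)) +
    geom_raster() +
    scale_fill_manual(values = c(reference = "grey85",
                                 alternative = "grey15")) +
    labs(x = "reference position (bp)", y = "read", fill = NULL) +
    theme_minimal()
}
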