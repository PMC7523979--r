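#' Manhattan-style plot of per-SNP Fst
#'
#' Fst by genomic position, faceted/colored by chromosome, with the
#' directional-selection threshold drawn as a horizontal line.
#'
#' @param fst An `fst_table` from [wc_fst()].
#' @param threshold Threshold line to draw (defaults to the scan's).
#' @return A ggplot object.
#' @export
plot_fst_manhattan <- function(fst, threshold = attr(fst, "threshold") %||% 0.2) {
  dat <- dplyr::filter(tibble::as_tibble(fst), !is.na(.data$fst))
  dat$chrom <- factor(dat$chrom, levels = unique(dat$chrom))
  # cumulative position across chromosomes for a single genome axis
  offs <- dat |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$pos), .groups = "drop") |>
    dplyr::mutate(offset = dplyr::lag(cumsum(as.numeric(.data$len)),
                                      default = 0))
  dat <- dplyr::left_join(dat, offs, by = "chrom")
  dat$gpos <- dat$pos + dat$offset
  centers <- dat |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(center = mean(range(.data$gpos)), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(.data$gpos, .data$fst,
                                    color = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = centers$center,
                                labels = centers$chrom) +
    ggplot2::labs(x = "chromosome", y = expression(F[ST]),
                  title = "Per-SNP differentiation between phenotypic groups") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.fst_table <- function(object, ...) plot_fst_manhattan(object, ...)

#' Scatter of the first two principal coordinates
#'
#' @param x A `pcoa_result` from [pcoa()].
#' @param groups Optional tibble `line`, `group` to color points by.
#' @return A ggplot object.
#' @export
plot_pcoa <- function(x, groups = NULL) {
  dat <- x$coordinates
  if (ncol(dat) < 3) stop("need at least two axes to plot", call. = FALSE)
  if (!is.null(groups)) {
    dat <- dplyr::left_join(dat, as_group_tbl(groups), by = "line")
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$Axis1, .data$Axis2)) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * x$prop_variance[1]),
      y = sprintf("PCo2 (%.1f%%)", 100 * x$prop_variance[2]),
      title = "Principal coordinates of 1 - IBS distances"
    ) +
    ggplot2::theme_minimal()
  if (is.null(groups)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$group))
  }
}

#' @exportS3Method ggplot2::autoplot
autoplot.pcoa_result <- function(object, ...) plot_pcoa(object, ...)

#' LNAE against number of favorable alleles
#'
#' Scatter of per-line LNAE against NFA with the fitted regression line and
#' the correlation annotated.
#'
#' @param assoc An `nfa_assoc` from [nfa_lnae_association()].
#' @return A ggplot object.
#' @export
plot_nfa_lnae <- function(assoc) {
  ggplot2::ggplot(assoc$data, ggplot2::aes(.data$nfa, .data$lnae)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_abline(intercept = assoc$intercept, slope = assoc$slope,
                         color = "steelblue") +
    ggplot2::annotate(
      "text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
      label = sprintf("r = %.2f, R² = %.2f", assoc$r, assoc$r_squared)
    ) +
    ggplot2::labs(x = "number of favorable alleles (NFA)",
                  y = expression(LNAE ~ (kg ~ ha^-1)),
                  title = "Low-N efficiency vs favorable-allele count") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.nfa_assoc <- function(object, ...) plot_nfa_lnae(object, ...)
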