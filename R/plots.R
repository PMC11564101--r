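# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a 96-channel substitution spectrum
#'
#' Barplot of channel counts, faceted by any grouping columns present
#' (e.g. arm x origin from [build_spectrum()]), coloured by substitution
#' type.
#'
#' @param spectrum output of [build_spectrum()].
#' @return a ggplot.
#' @export
plot_spectrum <- function(spectrum) {
  assert_cols(spectrum, c("channel", "count"), "spectrum")
  df <- spectrum %>%
    mutate(substitution = sub(".*\\[(.*)\\].*", "\\1", .data$channel),
           channel = factor(.data$channel, levels = sbs_channels()))
  gp <- ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$count,
                                         fill = .data$substitution)) +
    ggplot2::geom_col() +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "trinucleotide channel", y = "mutations",
                  fill = "substitution")
  extra <- setdiff(names(spectrum), c("channel", "count"))
  if (length(extra) > 0) {
    gp <- gp + ggplot2::facet_grid(
      stats::as.formula(paste(extra[1], "~", if (length(extra) > 1) extra[2] else "."))
    )
  }
  gp
}

#' Plot clonality ratios by alteration status
#'
#' Box-and-jitter display of EoT VAF/maxVAF ratios for acquired versus
#' maintained alterations, with the subclonality threshold marked.
#'
#' @param clonality output of [compute_clonality()].
#' @param threshold subclonality line (default 0.3).
#' @return a ggplot.
#' @export
plot_clonality <- function(clonality, threshold = 0.3) {
  assert_cols(clonality, c("status", "ratio"), "clonality")
  df <- clonality %>% filter(.data$status %in% c("acquired", "maintained"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$status, y = .data$ratio)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "EoT VAF / maxVAF")
}

#' Plot the fitted rate mixture
#'
#' Histogram of per-patient display rates (log10 axis; zero rates shown at
#' half the smallest nonzero value) coloured by assigned mixture component.
#'
#' @param object a `poisson_mixture` fit.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.poisson_mixture <- function(object, ...) {
  df <- augment(object) %>%
    mutate(component = factor(.data$component))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$display_rate,
                                   fill = .data$component)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::scale_x_log10() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "acquired mutations per month", y = "patients",
                  fill = "rate subgroup")
}

#' Kaplan-Meier plot
#'
#' Step plot of the product-limit estimate per group.
#'
#' @param object a `km_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.km_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$estimate,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "months", y = "survival probability", colour = NULL)
}

#' Enrichment dot plot
#'
#' Genesets by normalised enrichment score, point size encoding the
#' BH-adjusted permutation p-value.
#'
#' @param enrichment output of [preranked_gsea()].
#' @return a ggplot.
#' @export
plot_enrichment <- function(enrichment) {
  assert_cols(enrichment, c("geneset", "nes", "p_adjust"), "enrichment")
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = .data$nes,
                               y = stats::reorder(.data$geneset, .data$nes),
                               size = -log10(.data$p_adjust))) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "NES", y = NULL, size = "-log10 adj. p")
}
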