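#' Plot position weight matrix nucleotide weights
#'
#' Bar chart of log2(observed/expected) weights per codon position and
#' nucleotide; `NaN` weights (zero observed or expected frequency) are
#' dropped from the chart.
#'
#' @param pwm A `codon_pwm` or its tidied tibble (columns `position`,
#'   `nucleotide`, `weight`).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_pwm <- function(pwm, title = NULL) {
  dat <- if (is.data.frame(pwm)) pwm else generics::tidy(pwm)
  dat <- dat[is.finite(dat$weight), ]
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$nucleotide, y = .data$weight, fill = .data$nucleotide
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~position, nrow = 1,
                        labeller = ggplot2::labeller(position = function(p) paste("position", p))) +
    ggplot2::labs(
      x = NULL, y = expression(log[2](f[obs] / f[exp])), title = title
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.codon_pwm <- function(object, ...) {
  plot_pwm(object, title = object$selector_description)
}

#' Plot per-codon densities with versus without +1 GNN
#'
#' Paired bars of mean normalized A-site density for each codon type,
#' labelled by the first two codon nucleotides, faceted by footprint
#' class. Significant types (p below `alpha`) are marked with an asterisk.
#'
#' @param comparisons A `context_comparison` tibble.
#' @param alpha Significance mark threshold.
#' @return A ggplot object.
#' @export
plot_context_comparison <- function(comparisons, alpha = 0.01) {
  long <- comparisons %>%
    tidyr::pivot_longer(
      c("mean_with", "mean_without"),
      names_to = "context", values_to = "mean_density"
    ) %>%
    dplyr::mutate(
      context = ifelse(.data$context == "mean_with", "w +1 GNN", "wo +1 GNN"),
      sig = ifelse(.data$p_two_tailed < alpha & !.data$degenerate, "*", "")
    )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$asite_codon, y = .data$mean_density, fill = .data$context
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_text(
      data = dplyr::distinct(long, .data$asite_codon, .data$rfp_class, .data$sig),
      ggplot2::aes(x = .data$asite_codon, label = .data$sig, y = 0),
      vjust = -0.2, inherit.aes = FALSE
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", linewidth = 0.3) +
    ggplot2::facet_wrap(~rfp_class, ncol = 1) +
    ggplot2::labs(x = "A-site codon", y = "mean normalized density", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 7))
}

#' @export
autoplot.context_comparison <- function(object, ...) {
  plot_context_comparison(object, ...)
}

#' Plot percent density elevation grouped by codon class
#'
#' Box plot of per-codon-type percent elevation (with vs without +1 GNN)
#' grouped into NNU(G34), NNU(I34), NNC, NNA and NNG classes, one box per
#' footprint class.
#'
#' @param comparisons A `context_comparison` tibble.
#' @return A ggplot object.
#' @export
plot_class_summary <- function(comparisons) {
  cls <- classify_codon(comparisons$asite_codon)
  dat <- comparisons %>%
    dplyr::mutate(group = dplyr::case_when(
      cls$wobble == "U" ~ paste0("NNU(", cls$t34, ")"),
      cls$wobble == "C" ~ "NNC",
      cls$wobble == "A" ~ "NNA",
      cls$wobble == "G" ~ "NNG"
    )) %>%
    dplyr::filter(is.finite(.data$percent_elevation))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$group, y = .data$percent_elevation, fill = .data$rfp_class
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(
      x = "A-site codon class", y = "% density elevation with +1 GNN",
      fill = "RFP class"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rfp_class_summary <- function(object, ...) {
  ggplot2::ggplot(object$groups, ggplot2::aes(
    x = .data$group, y = .data$mean, fill = .data$rfp_class
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3
    ) +
    ggplot2::labs(
      x = "A-site codon class", y = "% density elevation with +1 GNN",
      fill = "RFP class"
    ) +
    ggplot2::theme_minimal()
}
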