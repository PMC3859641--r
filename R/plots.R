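# ggplot2 views of the result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_boxplot
#'   geom_tile facet_wrap labs theme_minimal scale_fill_gradient2
#' @export
ggplot2::autoplot

#' ROC curve plot
#'
#' @param object A `ubi_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ubi_roc
#' @export
autoplot.ubi_roc <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line(colour = "#2166ac") +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    theme_minimal()
}

#' ROC curves of all indicators of an analysis
#'
#' @param object A `ubi_analysis` from [analyze_sites()].
#' @param ... Unused.
#' @return A ggplot overlaying one ROC curve per indicator.
#' @method autoplot ubi_analysis
#' @export
autoplot.ubi_analysis <- function(object, ...) {
  curves <- purrr::imap(object$rocs, function(r, nm) {
    dplyr::mutate(r$curve, indicator = sprintf("%s (%.3f)", nm, r$auc))
  }) |> purrr::list_rbind()
  ggplot(curves, aes(x = .data$fpr, y = .data$tpr, colour = .data$indicator)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line() +
    labs(x = "False positive rate", y = "True positive rate",
         colour = "Indicator (AUC)") +
    theme_minimal()
}

#' Descriptor distributions by site label
#'
#' Boxplots of each descriptor for Ub vs NonUb sites.
#'
#' @param analysis A `ubi_analysis`.
#' @param descriptors Descriptor columns to show.
#' @return A ggplot.
#' @export
plot_descriptor_panel <- function(analysis,
                                  descriptors = intersect(DESCRIPTOR_PANEL,
                                                          names(analysis$site_descriptors))) {
  long <- analysis$site_descriptors |>
    select("site_id", "label", all_of(descriptors)) |>
    tidyr::pivot_longer(all_of(descriptors), names_to = "descriptor",
                        values_to = "value")
  ggplot(long, aes(x = .data$label, y = .data$value, fill = .data$label)) +
    geom_boxplot(outlier.size = 0.4) +
    facet_wrap(~descriptor, scales = "free_y") +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Positional enrichment heat map
#'
#' Tabular replacement for a two-sample logo: enrichment (red) and
#' depletion (blue) of symbols by context offset, with non-significant
#' cells blank.
#'
#' @param enrichment Table from [two_sample_enrichment()].
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrichment) {
  sig <- dplyr::filter(enrichment, .data$direction != "none") |>
    dplyr::mutate(delta = .data$freq_pos - .data$freq_neg)
  ggplot(sig, aes(x = .data$offset, y = .data$symbol, fill = .data$delta)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    labs(x = "Offset from central lysine", y = NULL,
         fill = "freq(Ub) - freq(NonUb)") +
    theme_minimal()
}
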