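#' Plot a ROC curve
#'
#' @param object a `ribocall_roc` from [roc_curve()].
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ribocall_roc <- function(object, ...) {
  auc <- attr(object, "auc")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", auc)) +
    ggplot2::theme_minimal()
}

#' Plot a metagene profile
#'
#' A-site read density around start or stop codons, coloured by codon
#' position so the 3-nt periodicity is visible.
#'
#' @param metagene tibble from [metagene_profile()].
#' @param anchor label for the x axis.
#' @return A ggplot.
#' @export
plot_metagene <- function(metagene, anchor = "start codon") {
  d <- mutate(metagene,
              frame = factor(((.data$position %% 3) + 3) %% 3,
                             labels = c("codon nt 1", "codon nt 2",
                                        "codon nt 3")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$rpm,
                                  fill = .data$frame)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(x = paste0("Position relative to ", anchor, " (nt)"),
                  y = "Mean RPM", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the classifier feature space
#'
#' Scatter of the periodicity feature `f1` against `pme`, optionally
#' coloured by a grouping column (label, ORF type or call).
#'
#' @param features feature tibble.
#' @param colour_by column name to colour points by.
#' @return A ggplot.
#' @export
plot_feature_space <- function(features, colour_by = "orf_type") {
  ggplot2::ggplot(features,
                  ggplot2::aes(x = .data$f1, y = .data$pme,
                               colour = .data[[colour_by]])) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "Fraction of reads at codon nt 1 (f1)",
                  y = "PME") +
    ggplot2::theme_minimal()
}
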