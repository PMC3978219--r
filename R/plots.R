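#' Plot an ROC curve
#'
#' Standard ROC plot (1 - specificity against sensitivity) with the
#' Youden-optimal operating point marked.
#'
#' @param object A `suvr_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.suvr_roc <- function(object, ...) {
  curve <- object$curve
  at_cut <- curve[which(curve$threshold == object$optimal_cutoff), ]
  ggplot2::ggplot(curve, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(data = at_cut, colour = "red", size = 2) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC (AUC %.2f, cut-off %.2f)",
                                  object$auc, object$optimal_cutoff)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot regional effect sizes
#'
#' Dot plot of Cohen's d per report region for one or more comparisons
#' (e.g. the patient-vs-control contrast under each route).
#'
#' @param ... Named `suvr_comparison` objects; the names label the series.
#' @return A ggplot.
#' @export
plot_effect_sizes <- function(...) {
  cmps <- list(...)
  if (is.null(names(cmps)) || any(names(cmps) == ""))
    names(cmps) <- paste0("comparison", seq_along(cmps))
  df <- dplyr::bind_rows(lapply(names(cmps), function(nm) {
    d <- tidy(cmps[[nm]])
    d$series <- nm
    d[, c("region", "cohens_d", "series")]
  }))
  df$region <- factor(df$region, levels = rev(unique(df$region)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cohens_d, y = .data$region,
                                   colour = .data$series)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(size = 2, position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "Cohen's d", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an SUVr table
#'
#' Bar chart of regional SUVr for one subject, with the cerebellar reference
#' line at 1.
#'
#' @param object A `suvr_table`.
#' @param ... Unused.
#' @export
autoplot.suvr_table <- function(object, ...) {
  df <- as_tibble(object)
  df$region <- factor(df$region, levels = df$region)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$suvr)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "SUVr (cerebellar reference)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
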