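#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a region comparison
#'
#' Returns the comparison as a plain tibble (one row per region); `glance()`
#' summarises it (number of regions, Holm-significant count at `alpha`,
#' largest absolute effect size).
#'
#' @param x A `suvr_comparison`.
#' @param ... Unused.
#' @export
tidy.suvr_comparison <- function(x, ...) {
  out <- x
  attr(out, "comparison") <- NULL
  class(out) <- setdiff(class(out), "suvr_comparison")
  as_tibble(out)
}

#' @rdname tidy.suvr_comparison
#' @param alpha Significance level applied to the adjusted p values.
#' @export
glance.suvr_comparison <- function(x, alpha = 0.05, ...) {
  meta <- attr(x, "comparison")
  tibble(comparison = meta$type,
         n_regions = nrow(x),
         n_significant = sum(x$p_adjusted < alpha),
         max_abs_d = max(abs(x$cohens_d), na.rm = TRUE))
}

#' @rdname tidy.suvr_comparison
#' @export
tidy.suvr_roc <- function(x, ...) x$curve

#' @rdname tidy.suvr_comparison
#' @export
glance.suvr_roc <- function(x, ...) {
  tibble(auc = x$auc, optimal_cutoff = x$optimal_cutoff,
         sensitivity = x$sens_at_cut, specificity = x$spec_at_cut,
         n_positive = x$n_positive, n_negative = x$n_negative)
}
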