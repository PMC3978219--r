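#' Pooled-SD Cohen's d for unequal group sizes
#'
#' Standardised mean difference `(mean_a - mean_b) / s_pooled`, with the
#' pooled standard deviation weighted by sample size. The default weights
#' are the usual `n - 1` degrees of freedom,
#' `s_pooled^2 = ((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a + n_b - 2)`;
#' `weighting = "n"` uses raw-n weights instead.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries.
#' @param weighting `"n-1"` (default) or `"n"`.
#' @return Scalar effect size.
#' @examples
#' cohens_d(1.47, 0.24, 22, 1.25, 0.13, 17)
#' @export
cohens_d <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b, weighting = c("n-1", "n")) {
  weighting <- match.arg(weighting)
  if (n_a < 2 || n_b < 2)
    stop_petsuvr("Cohen's d needs at least two observations per group", "sample_size")
  if (sd_a == 0 && sd_b == 0)
    stop_petsuvr("effect size undefined: both group standard deviations are zero", "undefined_effect")
  s2 <- if (weighting == "n-1") {
    ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
  } else {
    (n_a * sd_a^2 + n_b * sd_b^2) / (n_a + n_b)
  }
  (mean_a - mean_b) / sqrt(s2)
}

#' Holm step-down adjustment
#'
#' Step-down multiplicity control across a family of p values (the package
#' default family is the ten report regions of one comparison).
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values, clipped at 1, in the input order.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_petsuvr("p values must lie in [0, 1]", "usage")
  p.adjust(p, method = "holm")
}

region_columns <- function(cohort) {
  setdiff(names(cohort), c("subject_id", "group", "route"))
}

check_cohort <- function(cohort) {
  need <- c("subject_id", "group", "route")
  if (!all(need %in% names(cohort)))
    stop_petsuvr("cohort table needs columns subject_id, group, route plus one column per region",
                 "usage")
  if (anyDuplicated(cohort[, c("subject_id", "route")]))
    stop_petsuvr("duplicate (subject_id, route) rows in cohort table", "usage")
  invisible(cohort)
}

degenerate_spread <- function(x) {
  # t.test refuses "essentially constant" data; mirror that cut-off
  sd(x) < 10 * .Machine$double.eps * max(abs(mean(x)), 1e-300)
}

paired_t_row <- function(d) {
  m <- mean(d)
  if (degenerate_spread(d)) {
    if (m == 0) return(list(t = 0, p = 1, degenerate = FALSE))
    return(list(t = sign(m) * Inf, p = .Machine$double.xmin, degenerate = TRUE))
  }
  tt <- t.test(d)
  list(t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
}

#' Paired route-1 vs route-2 comparison within a group
#'
#' For one clinical group, compares SUVr between the two quantification
#' routes region by region with a paired two-sided t test on the
#' route1 - route2 differences, Holm-adjusted across the regions.
#'
#' @param cohort Tibble with columns `subject_id`, `group`, `route` and one
#'   numeric column per region; every subject of the group must appear under
#'   both routes.
#' @param group Group to analyse (`"patient"` or `"control"`).
#' @return A `suvr_comparison` tibble: one row per region with `mean_route1`,
#'   `sd_route1`, `mean_route2`, `sd_route2`, `n`, `t_statistic`, `p_raw`,
#'   `p_adjusted`, `cohens_d` (paired routes share n, so d uses the pooled
#'   cross-route SD).
#' @export
paired_route_comparison <- function(cohort, group) {
  check_cohort(cohort)
  sub <- cohort[cohort$group == group, , drop = FALSE]
  regions <- region_columns(cohort)
  r1 <- sub[sub$route == "route1", , drop = FALSE]
  r2 <- sub[sub$route == "route2", , drop = FALSE]
  miss <- union(setdiff(r1$subject_id, r2$subject_id), setdiff(r2$subject_id, r1$subject_id))
  if (length(miss))
    stop_petsuvr(sprintf("subject(s) without both routes: %s", paste(miss, collapse = ", ")),
                 "pairing")
  if (nrow(r1) < 3)
    stop_petsuvr("paired comparison needs at least 3 subjects", "sample_size")
  r2 <- r2[match(r1$subject_id, r2$subject_id), , drop = FALSE]
  rows <- purrr::map(regions, function(rg) {
    a <- r1[[rg]]; b <- r2[[rg]]
    res <- paired_t_row(a - b)
    if (res$degenerate)
      warn(sprintf("region '%s': zero-variance nonzero paired difference; p floored", rg))
    tibble(region = rg,
           mean_route1 = mean(a), sd_route1 = sd(a),
           mean_route2 = mean(b), sd_route2 = sd(b),
           n = length(a), t_statistic = res$t, p_raw = res$p,
           cohens_d = if (sd(a) == 0 && sd(b) == 0) NA_real_ else
             cohens_d(mean(a), sd(a), length(a), mean(b), sd(b), length(b)))
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- holm_adjust(out$p_raw)
  out <- out[, c(setdiff(names(out), c("p_adjusted", "cohens_d")), "p_adjusted", "cohens_d")]
  new_comparison(out, type = "paired_routes", group = group)
}

#' Patients vs controls comparison for one route
#'
#' Region-by-region two-sample comparison of the two clinical groups for one
#' quantification route. The default is Welch's unequal-variance t test
#' (`var_equal = TRUE` gives the pooled-variance Student test); p values are
#' Holm-adjusted across the regions, and the pooled-SD Cohen's d quantifies
#' each effect.
#'
#' @param cohort Cohort tibble (see [paired_route_comparison()]).
#' @param route Route to analyse (`"route1"` or `"route2"`).
#' @param var_equal Use pooled-variance Student t instead of Welch.
#' @param d_weighting Passed to [cohens_d()].
#' @return A `suvr_comparison` tibble: one row per region with group means,
#'   SDs, ns, `t_statistic`, `p_raw`, `p_adjusted` and `cohens_d`
#'   (patient minus control).
#' @export
group_comparison <- function(cohort, route, var_equal = FALSE, d_weighting = "n-1") {
  check_cohort(cohort)
  sub <- cohort[cohort$route == route, , drop = FALSE]
  regions <- region_columns(cohort)
  pa <- sub[sub$group == "patient", , drop = FALSE]
  co <- sub[sub$group == "control", , drop = FALSE]
  if (nrow(pa) < 2 || nrow(co) < 2)
    stop_petsuvr("group comparison needs at least 2 subjects per group", "sample_size")
  rows <- purrr::map(regions, function(rg) {
    a <- pa[[rg]]; b <- co[[rg]]
    if (degenerate_spread(a) && degenerate_spread(b)) {
      tt <- list(statistic = c(t = if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf),
                 p.value = if (mean(a) == mean(b)) 1 else .Machine$double.xmin)
      d <- NA_real_
    } else {
      tt <- t.test(a, b, var.equal = var_equal)
      d <- cohens_d(mean(a), sd(a), length(a), mean(b), sd(b), length(b),
                    weighting = d_weighting)
    }
    tibble(region = rg,
           mean_patient = mean(a), sd_patient = sd(a), n_patient = length(a),
           mean_control = mean(b), sd_control = sd(b), n_control = length(b),
           t_statistic = unname(tt$statistic), p_raw = tt$p.value, cohens_d = d)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- holm_adjust(out$p_raw)
  out <- out[, c(setdiff(names(out), c("p_adjusted", "cohens_d")), "p_adjusted", "cohens_d")]
  new_comparison(out, type = "groups", route = route,
                 test = if (var_equal) "student" else "welch")
}

new_comparison <- function(tbl, ...) {
  attr(tbl, "comparison") <- list(...)
  class(tbl) <- c("suvr_comparison", class(tbl))
  tbl
}

#' Empirical ROC analysis of a diagnostic score
#'
#' Builds the empirical ROC of a score (here: mean global SUVr) against the
#' clinical group, treating `score >= threshold` as a positive call. The
#' AUC is the trapezoidal area, identical to the proportion of concordant
#' patient/control pairs with ties counted half. The optimal cut-off
#' maximises Youden's J = sensitivity + specificity - 1; ties are broken
#' toward the lower cut-off (higher sensitivity).
#'
#' @param data Data frame / tibble with the score and class columns, or
#'   `NULL` if `scores` and `labels` are given directly.
#' @param score,class Column names in `data` (tidyselect not required;
#'   strings).
#' @param scores,labels Alternative direct vectors; `labels` is logical or
#'   a factor/character where `positive` names the diseased class.
#' @param positive Value of the class column counted as signal (default
#'   `"patient"`).
#' @return A `suvr_roc` object: list with `curve` (tibble of `threshold`,
#'   `sensitivity`, `specificity`), `auc`, `optimal_cutoff`, `sens_at_cut`,
#'   `spec_at_cut`, `n_positive`, `n_negative`.
#' @export
roc_analysis <- function(data = NULL, score = "suvr", class = "group",
                         scores = NULL, labels = NULL, positive = "patient") {
  if (!is.null(data)) {
    scores <- data[[score]]
    labels <- data[[class]]
  }
  pos <- if (is.logical(labels)) labels else labels == positive
  if (!any(pos) || !any(!pos))
    stop_petsuvr("ROC needs both classes present", "class")
  if (sum(pos) < 2 || sum(!pos) < 2)
    stop_petsuvr("ROC needs at least 2 subjects per class", "class")
  sp <- scores[pos]; sn <- scores[!pos]
  thresholds <- sort(unique(scores))
  sens <- vapply(thresholds, function(t) mean(sp >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(sn < t), numeric(1))
  curve <- tibble(threshold = c(-Inf, thresholds, Inf),
                  sensitivity = c(1, sens, 0),
                  specificity = c(0, spec, 1))
  fpr <- 1 - curve$specificity
  ord <- order(fpr, curve$sensitivity)
  auc <- -sum(diff(fpr[ord]) * (head(curve$sensitivity[ord], -1) +
                                tail(curve$sensitivity[ord], -1)) / 2)
  auc <- abs(auc)
  j <- sens + spec - 1
  best <- which(j == max(j))
  cut <- thresholds[min(best)]  # lower cut-off on ties
  structure(list(curve = curve, auc = auc, optimal_cutoff = cut,
                 sens_at_cut = sens[min(best)], spec_at_cut = spec[min(best)],
                 n_positive = sum(pos), n_negative = sum(!pos)),
            class = "suvr_roc")
}

#' @export
print.suvr_roc <- function(x, ...) {
  cat(sprintf("<suvr_roc> AUC %.3f | optimal cut-off %.4g (Youden): sensitivity %.1f%%, specificity %.1f%% (n = %d/%d)\n",
              x$auc, x$optimal_cutoff, 100 * x$sens_at_cut, 100 * x$spec_at_cut,
              x$n_positive, x$n_negative))
  invisible(x)
}

#' Signal-detection sensitivity d' and bias C
#'
#' `d' = z(H) - z(F)` and `C = -(z(H) + z(F)) / 2`, with `z` the standard
#' normal quantile, `H` the hit rate (sensitivity) and `F` the false-alarm
#' rate (1 - specificity). Rates of exactly 0 or 1 make `z` infinite; with
#' `correction = "count_correction"` such rates are replaced by `1/(2n)` and
#' `1 - 1/(2n)` using the supplied class counts, otherwise they raise a
#' boundary error.
#'
#' @param hit_rate,false_alarm_rate Proportions.
#' @param correction `"none"` or `"count_correction"`.
#' @param n_signal,n_noise Class sizes, required for the count correction.
#' @return A tibble with columns `hit_rate`, `false_alarm_rate`, `d_prime`,
#'   `bias_c`.
#' @examples
#' dprime(0.864, 1 - 0.706)
#' @export
dprime <- function(hit_rate, false_alarm_rate,
                   correction = c("none", "count_correction"),
                   n_signal = NULL, n_noise = NULL) {
  correction <- match.arg(correction)
  fix <- function(r, n) {
    if (r <= 0 || r >= 1) {
      if (correction == "none")
        stop_petsuvr("hit/false-alarm rate of exactly 0 or 1 needs correction = 'count_correction'",
                     "boundary")
      if (is.null(n))
        stop_petsuvr("count_correction needs n_signal and n_noise", "usage")
      r <- min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
    }
    r
  }
  h <- fix(hit_rate, n_signal)
  f <- fix(false_alarm_rate, n_noise)
  tibble(hit_rate = h, false_alarm_rate = f,
         d_prime = qnorm(h) - qnorm(f),
         bias_c = -(qnorm(h) + qnorm(f)) / 2)
}

#' Sensitivity and specificity from confusion counts
#'
#' @param true_positive,positives,true_negative,negatives Non-negative
#'   counts; `true_positive <= positives`, `true_negative <= negatives`.
#' @return Tibble with `sensitivity` and `specificity` as proportions plus
#'   `sensitivity_pct` / `specificity_pct` rounded to 0.1%.
#' @examples
#' confusion_rates(18, 22, 15, 17)
#' @export
confusion_rates <- function(true_positive, positives, true_negative, negatives) {
  counts <- c(true_positive, positives, true_negative, negatives)
  if (any(counts < 0) || positives < 1 || negatives < 1 ||
      true_positive > positives || true_negative > negatives)
    stop_petsuvr("invalid confusion counts", "count")
  sens <- true_positive / positives
  spec <- true_negative / negatives
  tibble(sensitivity = sens, specificity = spec,
         sensitivity_pct = round(100 * sens, 1),
         specificity_pct = round(100 * spec, 1))
}

#' Write a cohort SUVr table to CSV / read it back
#'
#' Columns: `subject_id`, `group`, `route`, then one numeric column per
#' region.
#'
#' @param cohort Cohort tibble.
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  check_cohort(as_tibble(read.csv(path, stringsAsFactors = FALSE)))
}
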