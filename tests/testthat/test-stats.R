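# independent oracles used throughout this file
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}
paired_oracle <- function(d) {
  t <- mean(d) / (sd(d) / sqrt(length(d)))
  list(t = t, p = 2 * pt(-abs(t), length(d) - 1))
}
holm_oracle <- function(p) {
  m <- length(p); o <- order(p); adj <- numeric(m); run <- 0
  for (i in seq_len(m)) {
    run <- max(run, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, run)
  }
  adj
}
auc_pairs_oracle <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

make_cohort_table <- function(vals_by_region, group, route, ids = NULL) {
  n <- length(vals_by_region[[1]])
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(n))
  tibble::as_tibble(c(list(subject_id = ids, group = group, route = route),
                      vals_by_region))
}

test_that("pooled-SD Cohen's d matches direct formula evaluation", {
  expect_equal(cohens_d(1.3, 0.2, 10, 1.3, 0.3, 12), 0)
  # published global route-1 summaries as inputs
  d <- cohens_d(1.47, 0.24, 22, 1.25, 0.13, 17)
  oracle <- (1.47 - 1.25) / sqrt((21 * 0.24^2 + 16 * 0.13^2) / 37)
  expect_equal(d, oracle, tolerance = 1e-12)
  expect_equal(round(d, 2), 1.10)
  expect_equal(cohens_d(1.25, 0.13, 17, 1.47, 0.24, 22), -d)
  # n-weighted variant
  dn <- cohens_d(1.47, 0.24, 22, 1.25, 0.13, 17, weighting = "n")
  expect_equal(dn, (1.47 - 1.25) / sqrt((22 * 0.24^2 + 17 * 0.13^2) / 39))
  expect_error(cohens_d(1, 0, 5, 2, 0, 5), class = "petsuvr_error_undefined_effect")
  expect_error(cohens_d(1, 0.1, 1, 2, 0.1, 5), class = "petsuvr_error_sample_size")
})

test_that("Holm adjustment is the step-down procedure", {
  expect_equal(holm_adjust(0.04), 0.04)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  set.seed(20)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    h <- holm_adjust(p)
    expect_equal(h, holm_oracle(p))
    expect_true(all(h >= p))
    expect_true(all(h <= pmin(1, length(p) * p) + 1e-12))
  }
  expect_error(holm_adjust(c(0.5, 1.2)), class = "petsuvr_error_usage")
})

test_that("paired route comparison handles identical and degenerate data", {
  set.seed(21)
  vals <- list(global = rnorm(6, 1.4, 0.2), precuneus = rnorm(6, 1.3, 0.2))
  r1 <- make_cohort_table(vals, "patient", "route1")
  r2 <- make_cohort_table(vals, "patient", "route2")
  res <- paired_route_comparison(rbind(r1, r2), "patient")
  expect_equal(res$t_statistic, c(0, 0))
  expect_equal(res$p_raw, c(1, 1))

  shifted <- lapply(vals, function(v) v - 0.1)  # constant offset: zero variance
  r2c <- make_cohort_table(shifted, "patient", "route2")
  expect_warning(res2 <- paired_route_comparison(rbind(r1, r2c), "patient"),
                 "zero-variance")
  expect_lte(res2$p_raw[1], .Machine$double.xmin)

  expect_error(paired_route_comparison(rbind(r1, r2[-1, ]), "patient"),
               class = "petsuvr_error_pairing")
})

test_that("paired route comparison matches the t-distribution oracle", {
  set.seed(22)
  n <- 22
  base <- rnorm(n, 1.4, 0.2)
  regions <- list(global = base, frontal = base + rnorm(n, 0, 0.03),
                  precuneus = base + rnorm(n, 0, 0.03))
  shifted <- lapply(regions, function(v) v + rnorm(n, 0.07, 0.05))
  r1 <- make_cohort_table(shifted, "patient", "route1")
  r2 <- make_cohort_table(regions, "patient", "route2")
  res <- paired_route_comparison(rbind(r1, r2), "patient")
  for (rg in names(regions)) {
    o <- paired_oracle(shifted[[rg]] - regions[[rg]])
    row <- res[res$region == rg, ]
    expect_equal(row$t_statistic, o$t, tolerance = 1e-6)
    expect_equal(row$p_raw, o$p, tolerance = 1e-6)
  }
  expect_true(all(res$p_adjusted < 0.05))
  expect_equal(res$p_adjusted, holm_oracle(res$p_raw))
})

test_that("group comparison uses Welch's test and matches a closed-form oracle", {
  tbl <- rbind(make_cohort_table(list(global = c(1, 2, 3)), "patient", "route1"),
               make_cohort_table(list(global = c(4, 5, 6)), "control", "route1",
                                 ids = c("C1", "C2", "C3")))
  res <- group_comparison(tbl, "route1")
  o <- welch_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t_statistic, o$t, tolerance = 1e-9)
  expect_equal(res$p_raw, o$p, tolerance = 1e-9)
  expect_equal(res$cohens_d, cohens_d(2, 1, 3, 5, 1, 3))

  same <- rbind(make_cohort_table(list(global = c(1, 2, 3)), "patient", "route1"),
                make_cohort_table(list(global = c(1, 2, 3)), "control", "route1",
                                  ids = c("C1", "C2", "C3")))
  res0 <- group_comparison(same, "route1")
  expect_equal(res0$cohens_d, 0)
  expect_equal(res0$p_raw, 1)

  one <- rbind(make_cohort_table(list(global = 1.4), "patient", "route1"),
               make_cohort_table(list(global = c(1, 2)), "control", "route1",
                                 ids = c("C1", "C2")))
  expect_error(group_comparison(one, "route1"), class = "petsuvr_error_sample_size")
})

test_that("empirical ROC matches exhaustive pair counting and pROC", {
  r <- roc_analysis(scores = c(1.5, 1.3, 1.2, 1.4),
                    labels = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.75)

  perfect <- roc_analysis(scores = c(5, 6, 7, 1, 2, 3),
                          labels = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sens_at_cut, 1)
  expect_equal(perfect$spec_at_cut, 1)

  tied <- roc_analysis(scores = rep(c(1, 2), 4),
                       labels = rep(c(TRUE, FALSE), each = 4))
  expect_equal(tied$auc, 0.5)

  set.seed(23)
  for (i in 1:20) {
    np <- sample(2:10, 1); nn <- sample(2:10, 1)
    pos <- round(rnorm(np, 1.5, 0.3), 2); neg <- round(rnorm(nn, 1.2, 0.2), 2)
    r <- roc_analysis(scores = c(pos, neg), labels = rep(c(TRUE, FALSE), c(np, nn)))
    expect_equal(r$auc, auc_pairs_oracle(pos, neg), tolerance = 1e-12)
    pr <- suppressMessages(pROC::roc(rep(c(1, 0), c(np, nn)), c(pos, neg),
                                     quiet = TRUE, direction = "<",
                                     levels = c(0, 1)))
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    # sensitivity is non-increasing along rising thresholds
    expect_true(all(diff(r$curve$sensitivity) <= 0))
    # the reported cut-off attains the maximal Youden J
    j <- r$sens_at_cut + r$spec_at_cut - 1
    sens <- vapply(r$curve$threshold, function(t) mean(pos >= t), numeric(1))
    spec <- vapply(r$curve$threshold, function(t) mean(neg < t), numeric(1))
    expect_equal(j, max(sens + spec - 1), tolerance = 1e-12)
  }
  expect_error(roc_analysis(scores = 1:4, labels = rep(TRUE, 4)),
               class = "petsuvr_error_class")
})

test_that("ROC cut-off ties break toward the lower threshold", {
  # thresholds 2 and 4 both attain J = 0.5; the lower (more sensitive) wins
  r <- roc_analysis(scores = c(2, 4, 1, 3), labels = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$optimal_cutoff, 2)
  expect_equal(r$sens_at_cut, 1)
})

test_that("d-prime and bias C follow the normal-quantile definitions", {
  r <- dprime(0.6, 0.2)
  expect_equal(r$d_prime, qnorm(0.6) - qnorm(0.2))
  expect_equal(r$bias_c, -(qnorm(0.6) + qnorm(0.2)) / 2)
  expect_equal(dprime(0.37, 0.37)$d_prime, 0)
  # round-trip through the normal CDF
  expect_equal(pnorm(qnorm(r$hit_rate)), 0.6, tolerance = 1e-9)
  # monotone in H, antitone in F
  hs <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(vapply(hs, function(h) dprime(h, 0.2)$d_prime, numeric(1))) > 0))
  expect_true(all(diff(vapply(hs, function(f) dprime(0.9, f)$d_prime, numeric(1))) < 0))
  expect_error(dprime(1, 0.2), class = "petsuvr_error_boundary")
  corr <- dprime(1, 0.2, correction = "count_correction", n_signal = 22, n_noise = 17)
  expect_equal(corr$hit_rate, 1 - 1 / 44)
})

test_that("confusion counts give the published visual-rating rates", {
  r <- confusion_rates(18, 22, 15, 17)
  expect_equal(r$sensitivity_pct, 81.8)
  expect_equal(r$specificity_pct, 88.2)
  expect_equal(confusion_rates(22, 22, 17, 17)$sensitivity, 1)
  expect_equal(confusion_rates(0, 22, 17, 17)$sensitivity, 0)
  expect_equal(confusion_rates(0, 22, 17, 17)$specificity, 1)
  expect_error(confusion_rates(23, 22, 17, 17), class = "petsuvr_error_count")
})

test_that("simulated cohorts recover their generating effect size", {
  set.seed(24)
  ds <- replicate(200, {
    ch <- make_cohort(22, 17, seed = sample.int(1e6, 1), build_volumes = FALSE)
    g <- group_comparison(ch$cohort, "route2")
    g$cohens_d[g$region == "global"]
  })
  gen_d <- cohens_d(1.50, 0.32, 22, 1.18, 0.09, 17)
  expect_lt(abs(mean(ds) - gen_d), 0.15)
})

test_that("tidy and glance summarise comparison and ROC objects", {
  tbl <- rbind(make_cohort_table(list(global = c(1.5, 1.6, 1.7)), "patient", "route1"),
               make_cohort_table(list(global = c(1.1, 1.2, 1.3)), "control", "route1",
                                 ids = c("C1", "C2", "C3")))
  cmp <- group_comparison(tbl, "route1")
  expect_s3_class(tidy(cmp), "tbl_df")
  expect_false(inherits(tidy(cmp), "suvr_comparison"))
  g <- glance(cmp)
  expect_equal(g$n_regions, 1)
  r <- roc_analysis(scores = c(1.5, 1.6, 1.1, 1.2),
                    labels = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(glance(r)$auc, 1)
  expect_named(tidy(r), c("threshold", "sensitivity", "specificity"))
})
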