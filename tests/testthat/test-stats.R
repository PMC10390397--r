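test_that("regression reproduces exact linear relations", {
  x <- 1:10
  fit <- linear_regression_ci(x = x, y = 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$pearson_r, 1)
  expect_equal(diff(fit$ci_slope), 0, tolerance = 1e-12)
  expect_equal(linear_regression_ci(x = x, y = -x)$pearson_r, -1)
  expect_error(linear_regression_ci(x = rep(1, 5), y = 1:5), "constant")
  expect_error(linear_regression_ci(x = 1:2, y = 1:2), "3")
})

test_that("regression matches a normal-equations oracle and tidies", {
  withr::with_seed(14, {
    x <- runif(40, 0, 2)
    y <- 150 * x + rnorm(40, 0, 10)
  })
  fit <- linear_regression_ci(x = x, y = y)
  ref <- oracle_ols(x, y)
  expect_equal(fit$slope, ref$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, ref$intercept, tolerance = 1e-10)
  expect_equal(fit$slope_stderr, ref$se_slope, tolerance = 1e-10)
  tq <- qt(0.975, 38)
  expect_equal(fit$ci_slope, ref$slope + c(-1, 1) * tq * ref$se_slope,
               tolerance = 1e-10)
  td <- tidy(fit)
  expect_equal(td$estimate, c(fit$intercept, fit$slope))
  expect_equal(glance(fit)$r, fit$pearson_r)
  # data-frame-first interface pipes through
  df <- tibble::tibble(a = x, b = y)
  fit2 <- linear_regression_ci(df, a, b)
  expect_equal(fit2$slope, fit$slope)
})

test_that("confidence intervals cover at their nominal level", {
  hits <- withr::with_seed(99, {
    vapply(1:500, function(i) {
      x <- runif(30, 0, 2)
      y <- 150 * x + rnorm(30, 0, 20)
      ci <- linear_regression_ci(x = x, y = y)$ci_slope
      ci[1] <= 150 && 150 <= ci[2]
    }, logical(1))
  })
  expect_gt(mean(hits), 0.95 - 3 * sqrt(0.05 * 0.95 / 500))
  expect_lt(mean(hits), 0.95 + 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("two-sample t-test behaves at both extremes", {
  a <- c(1.2, 3.4, 2.2, 5.0)
  res <- two_sample_ttest(a, a)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  withr::with_seed(3, {
    x <- rnorm(50); y <- rnorm(50, 5)
  })
  expect_lt(two_sample_ttest(x, y)$p_value, 1e-6)
  expect_error(two_sample_ttest(1, 1:3), "at least 2")
  expect_error(two_sample_ttest(c(1, 1), c(2, 2)), "variance")
  # degenerate equal constants agree trivially
  expect_equal(two_sample_ttest(c(2, 2), c(2, 2))$p_value, 1)
})

test_that("ROC analysis matches hand-computed and oracle values", {
  # perfectly separated low-BMD-positive scores
  r <- roc_curve(c(0.2, 0.3, 0.8, 0.9), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  expect_equal(r$operating_point$tpr, 1)
  expect_equal(r$operating_point$fpr, 0)

  # worked example with higher-is-positive orientation: AUC = 3/4
  r2 <- roc_curve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1),
                  positive_is_low = FALSE)
  expect_equal(r2$auc, 0.75)
  expect_equal(r2$auc, oracle_auc_concordance(c(0.1, 0.4, 0.35, 0.8),
                                              c(0, 0, 1, 1),
                                              positive_is_low = FALSE))
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "classes")
})

test_that("AUC equals the pairwise-concordance estimator on random input", {
  withr::with_seed(17, {
    for (i in 1:25) {
      n <- sample(8:40, 1)
      scores <- round(runif(n), sample(1:3, 1))   # ties likely
      labels <- runif(n) < 0.4
      if (!any(labels) || all(labels)) next
      lo <- runif(1) < 0.5
      r <- roc_curve(scores, labels, positive_is_low = lo)
      expect_equal(r$auc, oracle_auc_concordance(scores, labels, lo),
                   tolerance = 1e-12)
      # invariance under strictly monotone transform
      r2 <- roc_curve(exp(2 * scores), labels, positive_is_low = lo)
      expect_equal(r2$auc, r$auc, tolerance = 1e-12)
      expect_true(all(diff(r$curve$tpr) >= 0))
      expect_true(all(diff(r$curve$fpr) >= 0))
    }
  })
})

test_that("uninformative scores give chance-level AUC", {
  withr::with_seed(23, {
    scores <- rnorm(2000)
    labels <- runif(2000) < 0.5
  })
  r <- roc_curve(scores, labels)
  expect_lt(abs(r$auc - 0.5), 0.03)
})

test_that("ROI metrics recover known generative parameters", {
  withr::with_seed(41, a <- matrix(rnorm(80 * 80, 8, 2), 80, 80))
  met <- roi_metrics(a, roi = c(1, 80, 1, 80))
  expect_equal(met$snr, 8 / 2, tolerance = 0.1)
  b <- -a + 20
  expect_equal(roi_metrics(a, b, c(1, 80, 1, 80))$anticorrelation_r, -1)
  withr::with_seed(42, ind <- matrix(rnorm(80 * 80), 80, 80))
  expect_lt(abs(roi_metrics(a, ind, c(1, 80, 1, 80))$anticorrelation_r),
            3 / sqrt(80 * 80))
  expect_error(roi_metrics(matrix(1, 8, 8), roi = c(1, 8, 1, 8)),
               "constant")
  expect_error(roi_metrics(a, roi = c(1, 2, 1, 2)), "16")
})

test_that("cohort analysis emits three regressions and ROCs", {
  withr::with_seed(7, {
    n <- 30
    vb <- runif(n, 40, 200)
    tb <- tibble::tibble(
      patient_id = sprintf("P%02d", 1:n), vertebra = "mean",
      vbmd_true = vb, vbmd = vb,
      abmd_measured_ap = vb / 300 + rnorm(n, 0, 0.05),
      abmd_projected_ap = vb / 300 + rnorm(n, 0, 0.02),
      abmd_projected_lateral = vb / 300,
      mask_pixel_count = 100L, qc_negative = FALSE,
      status = classify_status(vb)
    )
  })
  an <- run_cohort_analysis(tb)
  expect_named(an$regressions, c("measured_ap", "projected_ap",
                                 "projected_lateral"))
  expect_equal(an$regressions$projected_lateral$pearson_r, 1)
  expect_equal(an$rocs$projected_lateral$auc, 1)
  # exact linear arm: slope is the vBMD/aBMD scale (300 mg/mL per g/cm^2)
  expect_equal(an$regressions$projected_lateral$slope, 300, tolerance = 1e-8)
  expect_true(all(c("arm", "min_distance") %in%
                    names(an$operating_points)))
  expect_error(run_cohort_analysis(dplyr::select(tb, -vbmd)), "vbmd")

  # single-class cohorts keep regressions but drop the ROC stage
  tb2 <- dplyr::mutate(tb, vbmd = vbmd * 0 + 150, vbmd_true = vbmd)
  ws <- capture_warnings(an2 <- run_cohort_analysis(tb2))
  expect_length(ws, 3)
  expect_match(ws, "single-class", all = TRUE)
  expect_length(an2$rocs, 0)
  expect_length(an2$regressions, 3)
})

test_that("ROC results agree with an independent reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(55, {
    scores <- c(rnorm(40, 1), rnorm(25, 0))
    labels <- rep(c(FALSE, TRUE), c(40, 25))   # low scores = positive
  })
  r <- roc_curve(scores, labels, positive_is_low = TRUE)
  ref <- pROC::auc(pROC::roc(response = labels, predictor = scores,
                             direction = ">", quiet = TRUE))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
})
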