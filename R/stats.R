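#' Least-squares regression with t-based confidence intervals
#'
#' Ordinary least squares of `y` on `x` with standard errors, the two-sided
#' p-value for the null hypothesis of zero slope, and confidence intervals
#' for slope and intercept from the two-sided inverse Student
#' t-distribution with `n - 2` degrees of freedom.
#'
#' @param data optional data frame containing `x` and `y` (tidyverse-style
#'   first argument); may be omitted by passing vectors.
#' @param x,y column names (when `data` given) or numeric vectors.
#' @param level confidence level, default 0.95.
#' @return object of class `sdexa_regression` with slope, intercept,
#'   pearson_r, p_value, slope_stderr, intercept_stderr, ci_slope,
#'   ci_intercept, n, and the data. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' fit <- linear_regression_ci(y = 2 * (1:10) + 1, x = 1:10)
#' glance(fit)
#' @export
linear_regression_ci <- function(data = NULL, x, y, level = 0.95) {
  if (is.data.frame(data)) {
    xv <- rlang::eval_tidy(rlang::enquo(x), data)
    yv <- rlang::eval_tidy(rlang::enquo(y), data)
  } else {
    xv <- x; yv <- y
  }
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3) stop_sdexa("need at least 3 complete observations")
  if (sd(xv) == 0) stop_sdexa("x is constant; regression undefined")
  fit <- lm(yv ~ xv)
  slope <- unname(coef(fit)[2]); icpt <- unname(coef(fit)[1])
  # standard errors computed directly so exact fits stay warning-free
  s2 <- sum(fit$residuals^2) / (n - 2)
  sxx <- sum((xv - mean(xv))^2)
  se_s <- sqrt(s2 / sxx)
  se_i <- sqrt(s2 * (1 / n + mean(xv)^2 / sxx))
  alpha <- 1 - level
  tq <- qt(1 - alpha / 2, df = n - 2)
  p_slope <- if (se_s == 0) as.numeric(slope == 0) else
    2 * pt(-abs(slope / se_s), df = n - 2)
  r_xy <- if (sd(yv) == 0) NA_real_ else cor(xv, yv)
  structure(
    list(slope = slope, intercept = icpt,
         pearson_r = r_xy,
         p_value = p_slope,
         slope_stderr = se_s, intercept_stderr = se_i,
         ci_slope = slope + c(-1, 1) * tq * se_s,
         ci_intercept = icpt + c(-1, 1) * tq * se_i,
         level = level, n = n, data = tibble::tibble(x = xv, y = yv)),
    class = "sdexa_regression"
  )
}

#' @export
print.sdexa_regression <- function(x, ...) {
  cat("<sdexa_regression> n =", x$n, "\n")
  cat(sprintf("  slope %.4g [%.4g, %.4g], intercept %.4g [%.4g, %.4g]\n",
              x$slope, x$ci_slope[1], x$ci_slope[2], x$intercept,
              x$ci_intercept[1], x$ci_intercept[2]))
  cat(sprintf("  Pearson r = %.3f, p = %.3g\n", x$pearson_r, x$p_value))
  invisible(x)
}

#' Two-sample t-test for identical means
#'
#' Two-sided test; the equal-variance (pooled) statistic is the default,
#' with Welch's unequal-variance correction available.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param var_equal pooled (TRUE, default) or Welch (FALSE).
#' @return list with `statistic`, `p_value`, `df`.
#' @export
two_sample_ttest <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) {
    stop_sdexa("each sample needs at least 2 values")
  }
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) return(list(statistic = 0, p_value = 1,
                                        df = length(a) + length(b) - 2))
    stop_sdexa("zero pooled variance with unequal means")
  }
  tt <- t.test(a, b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' ROC curve, trapezoidal AUC and minimum-distance operating point
#'
#' Sweeps the unique score values as thresholds, computes the true/false
#' positive rates, integrates the curve with the trapezoidal rule and picks
#' the operating point with minimum Euclidean distance to (FPR 0, TPR 1);
#' distance ties resolve toward the higher TPR. BMD-like scores classify
#' disease at LOW values; set `positive_is_low = TRUE` so the reported
#' thresholds stay in physical units.
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector: TRUE = positive (diseased).
#' @param positive_is_low when TRUE, predict positive for
#'   `score <= threshold`; when FALSE, for `score >= threshold`.
#' @return object of class `sdexa_roc`: tibble of (threshold, tpr, fpr)
#'   along the sweep, `auc`, and `operating_point`. Supports `tidy()`,
#'   `glance()` and `autoplot()`.
#' @export
roc_curve <- function(scores, labels, positive_is_low = TRUE) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop_sdexa("length mismatch")
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels)) {
    stop_sdexa("both classes must be present for ROC analysis")
  }
  thr <- sort(unique(scores))
  if (positive_is_low) {
    # predict positive when score <= t; sweep upward widens the positive set
    tpr <- vapply(thr, function(t) mean(scores[labels] <= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(scores[!labels] <= t), numeric(1))
  } else {
    thr <- rev(thr)
    tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  }
  curve <- tibble::tibble(threshold = thr, tpr = tpr, fpr = fpr)
  # trapezoidal integration over the curve closed at (0,0) and (1,1)
  fx <- c(0, fpr, 1); fy <- c(0, tpr, 1)
  auc <- sum(diff(fx) * (head(fy, -1) + tail(fy, -1)) / 2)
  d2 <- fpr^2 + (1 - tpr)^2
  cand <- which(d2 == min(d2))
  op <- cand[which.max(tpr[cand])]
  structure(
    list(curve = curve, auc = auc,
         operating_point = list(threshold = thr[op], tpr = tpr[op],
                                fpr = fpr[op]),
         positive_is_low = positive_is_low,
         n_positive = sum(labels), n_negative = sum(!labels)),
    class = "sdexa_roc"
  )
}

#' @export
print.sdexa_roc <- function(x, ...) {
  op <- x$operating_point
  cat(sprintf("<sdexa_roc> AUC = %.3f (%d pos / %d neg)\n", x$auc,
              x$n_positive, x$n_negative))
  cat(sprintf("  operating point: threshold %.4g, TPR %.2f, FPR %.2f\n",
              op$threshold, op$tpr, op$fpr))
  invisible(x)
}

#' ROI summary metrics of projection maps
#'
#' Mean, standard deviation and SNR (mean/sd) of `map_a` inside the ROI;
#' when `map_b` is given, also the Pearson correlation between the two maps
#' in the ROI (the anticorrelation diagnostic of spectral basis maps).
#'
#' @param map_a matrix.
#' @param map_b optional matrix of the same shape.
#' @param roi `c(row0, row1, col0, col1)`, at least 16 pixels.
#' @return list with `roi`, `mean`, `sd`, `snr`, and `anticorrelation_r`
#'   (NA when `map_b` missing).
#' @export
roi_metrics <- function(map_a, map_b = NULL, roi) {
  a <- roi_pixels(unclass(as.matrix(map_a)), roi)
  if (length(a) < 16) stop_sdexa("ROI must contain at least 16 pixels")
  s <- sd(a)
  if (s == 0) stop_sdexa("constant ROI: SNR undefined")
  r <- NA_real_
  if (!is.null(map_b)) {
    b <- roi_pixels(unclass(as.matrix(map_b)), roi)
    r <- cor(a, b)
  }
  list(roi = as.integer(roi), mean = mean(a), sd = s, snr = mean(a) / s,
       anticorrelation_r = r)
}

#' Cohort regression and ROC analysis
#'
#' Reproduces the study-level analysis on a cohort table: regressions of
#' volumetric BMD on each areal BMD arm (measured AP scout, projected AP,
#' projected lateral), and an ROC analysis per arm with vBMD-derived ground
#' truth (osteoporotic, < 80 mg/mL, for the projected arms; osteoporotic or
#' osteopenic, < 120 mg/mL, for the measured scout arm, where counting
#' statistics are poorest). Scores classify disease at low aBMD.
#'
#' @param cohort a `cohort_table` (or tibble with the same columns); the
#'   per-patient aggregate rows (`vertebra == "mean"`) are the analysis
#'   input, falling back to all rows if no aggregates are present.
#' @param projected_threshold,measured_threshold vBMD ground-truth cuts in
#'   mg/mL.
#' @param regress direction of the regressions: `"vbmd_on_abmd"` (default;
#'   slope in mg/mL per g/cm^2) or `"abmd_on_vbmd"`.
#' @return object of class `cohort_analysis`: named lists `regressions` and
#'   `rocs` (arms measured_ap / projected_ap / projected_lateral), plus an
#'   operating-point summary table. ROC arms with a single class are
#'   dropped with a warning; regressions are always emitted.
#' @export
run_cohort_analysis <- function(cohort, projected_threshold = 80,
                                measured_threshold = 120,
                                regress = c("vbmd_on_abmd",
                                            "abmd_on_vbmd")) {
  regress <- match.arg(regress)
  need <- c("patient_id", "vbmd", "abmd_measured_ap", "abmd_projected_ap",
            "abmd_projected_lateral")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop_sdexa("cohort table lacks columns: ",
               paste(missing_cols, collapse = ", "))
  }
  tb <- tibble::as_tibble(cohort)
  if ("vertebra" %in% names(tb) && any(tb$vertebra == "mean")) {
    tb <- dplyr::filter(tb, .data$vertebra == "mean")
  }

  arms <- c(measured_ap = "abmd_measured_ap",
            projected_ap = "abmd_projected_ap",
            projected_lateral = "abmd_projected_lateral")
  regressions <- purrr::imap(arms, function(col, nm) {
    if (regress == "vbmd_on_abmd") {
      linear_regression_ci(x = tb[[col]], y = tb$vbmd)
    } else {
      linear_regression_ci(x = tb$vbmd, y = tb[[col]])
    }
  })

  truth <- list(measured_ap = tb$vbmd < measured_threshold,
                projected_ap = tb$vbmd < projected_threshold,
                projected_lateral = tb$vbmd < projected_threshold)
  rocs <- purrr::imap(arms, function(col, nm) {
    lab <- truth[[nm]]
    if (!any(lab) || all(lab)) {
      warning("single-class ground truth for arm ", nm, "; ROC skipped")
      return(NULL)
    }
    roc_curve(tb[[col]], lab, positive_is_low = TRUE)
  })
  rocs <- purrr::compact(rocs)

  op_table <- purrr::imap_dfr(rocs, function(r, nm) {
    dplyr::mutate(r$curve, arm = nm,
                  min_distance = .data$threshold ==
                    r$operating_point$threshold)
  })

  structure(list(regressions = regressions, rocs = rocs,
                 operating_points = op_table, n = nrow(tb),
                 thresholds = c(projected = projected_threshold,
                                measured = measured_threshold)),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("<cohort_analysis> n =", x$n, "patients\n")
  for (nm in names(x$regressions)) {
    r <- x$regressions[[nm]]
    cat(sprintf("  %-18s r = %.3f, slope %.4g [%.4g, %.4g]\n", nm,
                r$pearson_r, r$slope, r$ci_slope[1], r$ci_slope[2]))
  }
  for (nm in names(x$rocs)) {
    cat(sprintf("  %-18s AUC = %.3f\n", nm, x$rocs[[nm]]$auc))
  }
  invisible(x)
}
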