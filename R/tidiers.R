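#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a regression result
#'
#' @param x an `sdexa_regression`.
#' @param ... unused.
#' @return one row per model term with estimate, std.error, statistic,
#'   p.value, conf.low, conf.high.
#' @method tidy sdexa_regression
#' @export
tidy.sdexa_regression <- function(x, ...) {
  tstat <- c(x$intercept / x$intercept_stderr, x$slope / x$slope_stderr)
  p_int <- 2 * pt(-abs(tstat[1]), df = x$n - 2)
  tibble::tibble(
    term = c("(Intercept)", "x"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_stderr, x$slope_stderr),
    statistic = tstat,
    p.value = c(p_int, x$p_value),
    conf.low = c(x$ci_intercept[1], x$ci_slope[1]),
    conf.high = c(x$ci_intercept[2], x$ci_slope[2])
  )
}

#' @rdname tidy.sdexa_regression
#' @method glance sdexa_regression
#' @export
glance.sdexa_regression <- function(x, ...) {
  tibble::tibble(r = x$pearson_r, r.squared = x$pearson_r^2,
                 slope = x$slope, intercept = x$intercept,
                 p.value = x$p_value, n = x$n)
}

#' Tidy an ROC result
#'
#' @param x an `sdexa_roc`.
#' @param ... unused.
#' @method tidy sdexa_roc
#' @export
tidy.sdexa_roc <- function(x, ...) x$curve

#' @rdname tidy.sdexa_roc
#' @method glance sdexa_roc
#' @export
glance.sdexa_roc <- function(x, ...) {
  op <- x$operating_point
  tibble::tibble(auc = x$auc, threshold = op$threshold, tpr = op$tpr,
                 fpr = op$fpr, n_positive = x$n_positive,
                 n_negative = x$n_negative)
}

#' Plot an ROC curve with its operating point
#' @param object an `sdexa_roc`.
#' @param ... unused.
#' @method autoplot sdexa_roc
#' @export
autoplot.sdexa_roc <- function(object, ...) {
  op <- object$operating_point
  df <- dplyr::bind_rows(tibble::tibble(fpr = 0, tpr = 0),
                         object$curve[c("fpr", "tpr")],
                         tibble::tibble(fpr = 1, tpr = 1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::annotate("point", x = op$fpr, y = op$tpr, colour = "red") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::coord_equal()
}

#' Plot a regression result
#' @param object an `sdexa_regression`.
#' @param ... unused.
#' @method autoplot sdexa_regression
#' @export
autoplot.sdexa_regression <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept, colour = "red") +
    ggplot2::labs(title = sprintf("r = %.3f, slope = %.4g [%.4g, %.4g]",
                                  object$pearson_r, object$slope,
                                  object$ci_slope[1], object$ci_slope[2]))
}

#' Plot an areal BMD (or any projection) map
#' @param object an `abmd_map` or `projected_map`.
#' @param ... unused.
#' @method autoplot abmd_map
#' @export
autoplot.abmd_map <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object)),
                           col = seq_len(ncol(object)))
  df$value <- as.vector(t(unclass(object)))  # expand_grid: col varies fastest
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "g/cm²") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "detector column", y = "table position")
}

#' @method autoplot projected_map
#' @export
autoplot.projected_map <- autoplot.abmd_map
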