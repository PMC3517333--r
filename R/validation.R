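# Method-comparison statistics for validating an instrument against a
# criterion measure: Pearson and partial correlation, Bland-Altman
# limits of agreement with a trend test, compliance accounting, and
# one-sided k-SD outlier screening for sensitivity reanalysis.

check_paired <- function(x, y, n_min = 3) {
  if (length(x) != length(y))
    stop("paired vectors must have equal length", call. = FALSE)
  if (length(x) < n_min)
    stop("need at least ", n_min, " pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("paired values must be finite", call. = FALSE)
}

cor_p_value <- function(r, df) {
  if (df <= 0) return(NA_real_)
  tstat <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(tstat), df)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value comes from
#' `t = r sqrt((n-2) / (1-r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3), non-degenerate.
#' @return An object of class `correlation_result`: `r`, `p`, `n`,
#'   `kind`.
#' @examples
#' pearson(c(1, 2, 3), c(1, 3, 2))$r  # 0.5
#' @export
pearson <- function(x, y) {
  check_paired(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  r <- stats::cor(x, y)
  structure(list(r = r, p = cor_p_value(r, length(x) - 2),
                 n = length(x), kind = "zero_order"),
            class = "correlation_result")
}

#' Partial Pearson correlation
#'
#' Correlation of the residuals of `x` and `y` after ordinary
#' least-squares adjustment for the covariates; degrees of freedom are
#' reduced by the number of covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates data frame (or matrix) of numeric covariates; an
#'   empty covariate set reduces to [pearson()].
#' @return A `correlation_result` with `kind = "partial"`.
#' @export
partial_pearson <- function(x, y, covariates) {
  covariates <- as.data.frame(covariates)
  k <- ncol(covariates)
  if (k == 0) {
    out <- pearson(x, y)
    out$kind <- "partial"
    return(out)
  }
  check_paired(x, y, n_min = k + 3)
  if (nrow(covariates) != length(x))
    stop("covariates must have one row per pair", call. = FALSE)
  mm <- stats::model.matrix(~ ., data = covariates)
  if (qr(mm)$rank < ncol(mm))
    stop("covariates are collinear (rank-deficient design)", call. = FALSE)
  rx <- stats::residuals(stats::lm.fit(mm, x))
  ry <- stats::residuals(stats::lm.fit(mm, y))
  if (stats::sd(rx) < 1e-12 * max(1, stats::sd(x)) ||
      stats::sd(ry) < 1e-12 * max(1, stats::sd(y)))
    stop("residual variance collapses after adjustment; ",
         "partial correlation undefined", call. = FALSE)
  r <- stats::cor(rx, ry)
  structure(list(r = r, p = cor_p_value(r, length(x) - 2 - k),
                 n = length(x), kind = "partial"),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s Pearson r = %.3f (n = %d, P = %.3g)\n",
              if (x$kind == "partial") "Partial" else "Zero-order",
              x$r, x$n, x$p))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' For paired measurements of the same quantity by two methods, computes
#' the differences `a - b` and their mean and sample SD, the limits of
#' agreement `mean_diff +/- 1.96 SD`, and a test for trend: the OLS
#' regression of the difference on the pair mean `(a + b) / 2`, reported
#' as slope, intercept, correlation and p-value (the slope's t-test and
#' the correlation's t-test coincide).
#'
#' @param a,b paired measurements, same units (n >= 3); `a` is
#'   conventionally the instrument under test and `b` the criterion.
#' @param constants see [ee_constants()] (`loa_multiplier`).
#' @return An object of class `bland_altman_result`: `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `trend_slope`, `trend_intercept`,
#'   `trend_r`, `trend_p`, `n`, plus the raw `differences` and `means`.
#' @export
bland_altman <- function(a, b, constants = ee_constants()) {
  check_paired(a, b)
  d <- a - b
  m <- (a + b) / 2
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  half <- constants$loa_multiplier * sd_diff
  if (stats::sd(m) == 0 || sd_diff == 0) {
    trend <- list(slope = 0, intercept = mean_diff, r = 0, p = NA_real_)
  } else {
    fit <- stats::lm(d ~ m)
    r <- stats::cor(d, m)
    trend <- list(slope = unname(stats::coef(fit)[2]),
                  intercept = unname(stats::coef(fit)[1]),
                  r = r, p = cor_p_value(r, length(d) - 2))
  }
  structure(list(mean_diff = mean_diff, sd_diff = sd_diff,
                 loa_low = mean_diff - half, loa_high = mean_diff + half,
                 trend_slope = trend$slope,
                 trend_intercept = trend$intercept,
                 trend_r = trend$r, trend_p = trend$p,
                 n = length(d), differences = d, means = m),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean difference %.2f, SD %.2f\n",
              x$n, x$mean_diff, x$sd_diff))
  cat(sprintf("  limits of agreement: %.2f to %.2f\n", x$loa_low, x$loa_high))
  cat(sprintf("  trend: slope %.3f, r = %.3f, P = %.3g\n",
              x$trend_slope, x$trend_r, x$trend_p))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Difference-versus-mean scatter with the bias line and the limits of
#' agreement.  Requires ggplot2.
#'
#' @param result a [bland_altman()] result.
#' @param xlab,ylab axis labels.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(result, xlab = "Mean of methods",
                              ylab = "Difference between methods") {
  stopifnot(inherits(result, "bland_altman_result"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- data.frame(m = result$means, d = result$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$d)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = result$mean_diff, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(result$loa_low, result$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_classic()
}

#' Compliance accounting
#'
#' Fraction of participant-days with completed input, as a percentage to
#' one decimal place.
#'
#' @param completed either an integer count or a logical vector of
#'   per-day completion flags.
#' @param total total participant-days; defaults to `length(completed)`
#'   when `completed` is a flag vector.
#' @return A list: `completed`, `total`, `pct` (one decimal).
#' @examples
#' compliance(122, 140)$pct  # 87.1
#' @export
compliance <- function(completed, total = NULL) {
  if (is.logical(completed)) {
    if (is.null(total)) total <- length(completed)
    completed <- sum(completed)
  }
  if (is.null(total) || total <= 0)
    stop("total participant-days must be positive", call. = FALSE)
  list(completed = as.integer(completed), total = as.integer(total),
       pct = round(100 * completed / total, 1))
}

#' One-sided high outlier screen
#'
#' Flags indices whose value exceeds `mean + k_sd x SD` (one-sided high:
#' gross over-reporting is the failure mode of self-report instruments).
#' Recomputing statistics on the retained set is the caller's second
#' pass.
#'
#' @param values numeric vector (n >= 3).
#' @param k_sd SD multiplier; default 3.
#' @return Integer vector of flagged indices (possibly empty).
#' @export
flag_outliers <- function(values, k_sd = ee_constants()$outlier_k_sd) {
  if (length(values) < 3)
    stop("need at least 3 values to screen for outliers", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) return(integer(0))
  which(values > mean(values) + k_sd * s)
}
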