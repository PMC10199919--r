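# Method-agreement statistics between an estimated and a reference series:
# bias +/- SD, median absolute difference, error CDF, ICC, linear fit.

#' Method-agreement report
#'
#' Summarizes agreement between paired measurement series the way clinical
#' method-comparison studies report it: mean difference (bias) and its
#' standard deviation, median absolute difference, the empirical CDF of
#' absolute differences, the intraclass correlation coefficient (two-way
#' single-measure absolute agreement, ICC(2,1), the standard choice for
#' method agreement; ICC(3,1) consistency is available via \code{icc_type}),
#' and the ordinary-least-squares fit of est on ref.
#'
#' @param est estimated series.
#' @param ref reference series (same length, >= 3).
#' @param icc_type "ICC2" (absolute agreement, default) or "ICC3"
#'   (consistency).
#' @return object of class \code{"agreement"}: list(bias, sd, median_abs,
#'   cdf (data.frame abs_diff, q), icc, fit (intercept, slope), n).
#' @export
agreement <- function(est, ref, icc_type = c("ICC2", "ICC3")) {
  icc_type <- match.arg(icc_type)
  stop_if_not(length(est) == length(ref), "length mismatch")
  stop_if_not(length(est) >= 3, "need at least 3 pairs")
  d <- est - ref
  ad <- sort(abs(d))
  fit <- stats::lm.fit(cbind(1, ref), est)$coefficients
  structure(list(bias = mean(d), sd = stats::sd(d),
                 median_abs = stats::median(abs(d)),
                 cdf = data.frame(abs_diff = ad,
                                  q = seq_along(ad) / length(ad)),
                 icc = icc_pairs(est, ref, icc_type),
                 fit = c(intercept = unname(fit[1]), slope = unname(fit[2])),
                 n = length(d)),
            class = "agreement")
}

# ICC for two raters (methods) x n subjects from the two-way ANOVA mean
# squares. ICC(2,1): (MSR - MSE) / (MSR + MSE + 2 (MSC - MSE) / n).
icc_pairs <- function(est, ref, type = "ICC2") {
  x <- cbind(est, ref)
  n <- nrow(x); k <- 2
  mean_all <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssr <- k * sum((row_m - mean_all)^2)
  ssc <- n * sum((col_m - mean_all)^2)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + mean_all)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (type == "ICC3") {
    (msr - mse) / (msr + (k - 1) * mse)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
}

#' @export
print.agreement <- function(x, ...) {
  cat(sprintf("Agreement over %d pairs: bias %.3f +/- %.3f, median |diff| %.3f\n",
              x$n, x$bias, x$sd, x$median_abs))
  cat(sprintf("ICC %.4f; fit est = %.3f + %.3f ref\n",
              x$icc, x$fit["intercept"], x$fit["slope"]))
  invisible(x)
}

#' @export
plot.agreement <- function(x, ...) {
  graphics::plot(x$cdf$abs_diff, x$cdf$q, type = "s",
                 xlab = "absolute difference", ylab = "cumulative fraction",
                 main = sprintf("bias %.2f +/- %.2f, ICC %.3f",
                                x$bias, x$sd, x$icc), ...)
  invisible(x)
}
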