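#' Pearson correlation with two-sided significance
#'
#' Sample Pearson correlation between two vectors with the classical
#' two-sided t-test, \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees
#' of freedom (via [stats::cor.test()]). A perfect correlation has a
#' degenerate test statistic and is reported with `p_value = 0`.
#'
#' @param x,y Paired numeric vectors, `n >= 3`, each with non-zero
#'   variance.
#' @return List with `r`, `p_value`, `n`.
#' @examples
#' pearson_with_p(1:5, c(2, 1, 4, 3, 5))   # r = 0.8, p ~ 0.104
#' @export
pearson_with_p <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must be paired")
  if (length(x) < 3L) stop("need at least three pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: zero variance")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "pearson"))
  r <- unname(ct$estimate)
  p <- if (abs(r) >= 1) 0 else ct$p.value
  list(r = r, p_value = p, n = length(x))
}

#' Fraction of predictions within a factor of two
#'
#' Share of paired positive values whose ratio (either way) is at most 2 —
#' the conventional "factor-2" agreement band drawn as dashed guide lines
#' on predicted-vs-observed plots.
#'
#' @param pred,obs Paired positive values.
#' @return Fraction in `[0, 1]`.
#' @export
factor2_fraction <- function(pred, obs) {
  pred <- as.numeric(pred); obs <- as.numeric(obs)
  if (length(pred) != length(obs)) stop("'pred' and 'obs' must be paired")
  if (length(pred) == 0L) stop("no pairs supplied")
  if (any(!is.finite(pred)) || any(!is.finite(obs)) ||
      any(pred <= 0) || any(obs <= 0))
    stop("factor-2 agreement needs positive values")
  mean(pmax(pred / obs, obs / pred) <= 2)
}

#' Evaluate predicted versus observed absorption ratios
#'
#' Bundles the predicted-vs-observed comparison metrics: Pearson r with
#' its two-sided p-value, the regression slope, and the factor-2 agreement
#' fraction. The slope is by default from an origin-constrained least
#' squares fit of observed on predicted (absorption ratios live on a
#' common `[0, 1]` scale where a 1:1 line through the origin is the
#' null expectation); set `intercept = TRUE` for an ordinary regression
#' slope instead.
#'
#' @param predicted,observed Paired ratios, `n >= 3`.
#' @param chemical Optional labels, carried into the result.
#' @param intercept Logical; fit the slope with a free intercept?
#' @return An object of class `absorption_comparison`: list with `n`, `r`,
#'   `p_value`, `slope`, `factor2_fraction` and the paired `data`.
#' @examples
#' study <- simulate_study(seed = 42)
#' evaluate_predictions(study$comparison$predicted,
#'                      study$comparison$observed,
#'                      chemical = study$comparison$chemical)
#' @export
evaluate_predictions <- function(predicted, observed, chemical = NULL,
                                 intercept = FALSE) {
  predicted <- as.numeric(predicted); observed <- as.numeric(observed)
  if (length(predicted) != length(observed))
    stop("'predicted' and 'observed' must be paired")
  if (length(predicted) < 3L) stop("need at least three pairs")
  pr <- pearson_with_p(predicted, observed)
  slope <- if (intercept)
    unname(coef(lm(observed ~ predicted))[2L])
  else
    unname(coef(lm(observed ~ predicted + 0))[1L])
  dat <- data.frame(
    chemical = if (is.null(chemical)) seq_along(predicted) else chemical,
    predicted = predicted, observed = observed)
  structure(list(n = pr$n, r = pr$r, p_value = pr$p_value, slope = slope,
                 factor2_fraction = factor2_fraction(predicted, observed),
                 intercept_fitted = intercept, data = dat),
            class = "absorption_comparison")
}

#' @export
print.absorption_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("Predicted vs observed absorption ratios (n = %d)\n", x$n))
  cat(sprintf("  Pearson r          %s (two-sided p = %s)\n",
              signif(x$r, digits), signif(x$p_value, digits)))
  cat(sprintf("  slope (%s) %s\n",
              if (x$intercept_fitted) "with intercept" else "through origin",
              signif(x$slope, digits)))
  cat(sprintf("  within factor 2    %s\n",
              signif(x$factor2_fraction, digits)))
  invisible(x)
}

#' Scatter plot of predicted versus observed ratios
#'
#' Identity line (solid) and factor-2 band (dashed), the standard display
#' for absorption-ratio agreement.
#'
#' @param x An `absorption_comparison`.
#' @param ... Passed to [plot()].
#' @export
plot.absorption_comparison <- function(x, ...) {
  d <- x$data
  lim <- range(0, d$predicted, d$observed)
  plot(d$predicted, d$observed, xlim = lim, ylim = lim,
       xlab = "predicted absorption ratio",
       ylab = "observed absorption ratio", pch = 19, ...)
  abline(0, 1)
  abline(0, 2, lty = 2)
  abline(0, 0.5, lty = 2)
  legend("topleft", bty = "n",
         legend = c(sprintf("r = %.3f", x$r),
                    sprintf("slope = %.3f", x$slope),
                    sprintf("factor-2 = %.2f", x$factor2_fraction)))
  invisible(x)
}
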