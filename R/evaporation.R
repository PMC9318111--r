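#' Applied-solution weight series
#'
#' Weight of the applied solution measured at a regular cadence (typically
#' every 0.25 h) until no further change is observed; the raw material for
#' estimating the complete-evaporation time.
#'
#' @param times Measurement times in h, strictly increasing.
#' @param weights Solution weights in mg, non-negative, same length.
#' @return An object of class `evaporation_series`.
#' @export
evaporation_series <- function(times, weights) {
  times <- as.numeric(times)
  weights <- as.numeric(weights)
  if (length(times) != length(weights))
    stop("'times' and 'weights' must have the same length")
  if (length(times) < 3L)
    stop("an evaporation series needs at least three points")
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  if (any(is.na(weights)) || any(weights < 0))
    stop("'weights' must be non-negative")
  structure(list(times = times, weights = weights),
            class = "evaporation_series")
}

#' Estimate the complete-evaporation time of the vehicle
#'
#' Scans consecutive weight changes for a sustained plateau. A pair of
#' successive measurements "qualifies" when the absolute change is at most
#' `rel_threshold` times the initial weight. `Teva` is the earliest time
#' after which every consecutive change qualifies, i.e. the end of the last
#' non-qualifying change — the first measurement at which evaporation is
#' complete. The plateau must hold to the end of the series (at minimum its
#' final pair); otherwise evaporation is judged incomplete and an error is
#' raised. For a series that is flat from the start, `Teva` is the second
#' time point, the first at which stability has actually been observed.
#'
#' The relative-change criterion makes the estimate invariant to rescaling
#' all weights, and a looser threshold can only move `Teva` earlier.
#'
#' @param series An [evaporation_series()], or a numeric vector of times
#'   when `weights` is supplied.
#' @param rel_threshold Plateau criterion as a fraction of the initial
#'   weight (default 0.01, i.e. consecutive changes within 1\%).
#' @param weights Optional numeric weights when `series` is a time vector.
#' @return An object of class `teva_estimate`: list with `Teva` (h),
#'   `plateau_weight` (mean weight from `Teva` on, mg), `criterion` and
#'   `rel_threshold`.
#' @examples
#' s <- evaporation_series(seq(0.25, 1.5, by = 0.25),
#'                         c(10.0, 6.7, 3.4, 0.1, 0.1, 0.1))
#' estimate_teva(s)
#' @export
estimate_teva <- function(series, rel_threshold = 0.01, weights = NULL) {
  if (!inherits(series, "evaporation_series"))
    series <- evaporation_series(series, weights)
  if (!is.numeric(rel_threshold) || length(rel_threshold) != 1L ||
      rel_threshold < 0)
    stop("'rel_threshold' must be a non-negative number")
  t <- series$times
  w <- series$weights
  thr <- rel_threshold * w[1L]
  ok <- abs(diff(w)) <= thr            # ok[j]: pair (j, j+1) qualifies
  if (!ok[length(ok)])
    stop("evaporation incomplete: weight still changing at the end of the series")
  bad <- which(!ok)
  idx <- if (length(bad) == 0L) 2L else max(bad) + 1L
  structure(list(Teva = t[idx],
                 plateau_weight = mean(w[idx:length(w)]),
                 criterion = "consecutive_change_rel_initial",
                 rel_threshold = rel_threshold),
            class = "teva_estimate")
}

#' @export
print.teva_estimate <- function(x, ...) {
  cat(sprintf("Teva = %g h (plateau weight %g mg; consecutive changes <= %g%% of initial)\n",
              x$Teva, signif(x$plateau_weight, 4), 100 * x$rel_threshold))
  invisible(x)
}
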