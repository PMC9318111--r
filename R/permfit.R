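#' Steady-state (lag-time) fit of a permeation profile
#'
#' Fits an ordinary least-squares line \eqn{Q = a t + b} to the selected
#' window of a cumulative permeation profile. The slope is the steady-state
#' flux and the x-intercept the lag time
#' \eqn{T_{lag} = -b/a}, i.e. the intersection of the steady-state tangent
#' with the time axis.
#'
#' The default window keeps all points at `t >= 2` h for skin-like
#' membranes, and `t >= 4` h for Strat-M (membrane names containing
#' `"strat"`), where the 2-h point typically still lies off the straight
#' line. Override with an explicit index vector when visual inspection
#' suggests a different linear region.
#'
#' @param profile A [permeation_profile()].
#' @param window Integer indices of the profile points to fit, or `NULL`
#'   for the membrane-dependent default. At least two points.
#' @return A list with `Flux` (ug/cm^2/h), `Tlag` (h), `r2`, `intercept`,
#'   `n_points`, `window` and logical `negative_tlag`.
#' @seealso [fit_permeation()] which composes this with the parameter
#'   relations into a full fit.
#' @examples
#' p <- permeation_profile(c(2, 4, 6, 8), c(5, 15, 25, 35),
#'                         Cv = 1e4, membrane = membrane_spec("skin", 0.1))
#' fit_steady_state(p)   # Flux = 5, Tlag = 1
#' @export
fit_steady_state <- function(profile, window = NULL) {
  stopifnot(inherits(profile, "permeation_profile"))
  window <- resolve_window(profile, window)
  t <- profile$times[window]
  Q <- profile$cumulative[window]
  fit <- lm(Q ~ t)
  a <- unname(coef(fit)[2L])
  b <- unname(coef(fit)[1L])
  # slope indistinguishable from zero at the data's scale is no flux
  eps_slope <- 1e-10 * (max(abs(Q)) + 1) / diff(range(t))
  if (!is.finite(a) || a <= eps_slope)
    stop("no positive steady-state flux in the selected window")
  Tlag <- -b / a
  neg <- Tlag < 0
  if (neg)
    warning("negative lag time (", signif(Tlag, 4),
            " h): steady-state window may be invalid", call. = FALSE)
  # direct R^2 (avoids summary.lm's perfect-fit warning on noiseless data)
  ss_tot <- sum((Q - mean(Q))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(residuals(fit)^2) / ss_tot
  list(Flux = a, Tlag = Tlag, r2 = r2, intercept = b,
       n_points = length(t), window = window, negative_tlag = neg,
       lm = fit)
}

resolve_window <- function(profile, window) {
  if (is.null(window)) {
    tmin <- if (grepl("strat", profile$membrane$name, ignore.case = TRUE))
      4 else 2
    window <- which(profile$times >= tmin)
    if (length(window) < 2L)           # short profile: fall back to all points
      window <- seq_along(profile$times)
  } else {
    window <- as.integer(window)
    if (length(window) < 2L)
      stop("'window' must select at least two points")
    if (any(is.na(window)) || any(window < 1L) ||
        any(window > length(profile$times)))
      stop("'window' indices out of range")
  }
  sort(unique(window))
}

#' Permeability coefficient from flux
#'
#' \eqn{K_p = Flux / C_v}: the steady-state flux normalised by the donor
#' concentration.
#'
#' @param Flux Steady-state flux in ug/cm^2/h.
#' @param Cv Donor concentration in ug/mL. Must be positive.
#' @return Permeability coefficient in cm/h.
#' @export
compute_kp <- function(Flux, Cv) {
  if (any(!is.finite(Cv)) || any(Cv <= 0))
    stop("'Cv' must be positive")
  Flux / Cv
}

#' Diffusion coefficient from the lag time
#'
#' \eqn{D = L^2 / (6 T_{lag})}, the classical lag-time relation for
#' diffusion through a slab of thickness `L`.
#'
#' @param L Membrane thickness in cm.
#' @param Tlag Lag time in h. Must be positive.
#' @return Diffusion coefficient in cm^2/h.
#' @export
compute_D <- function(L, Tlag) {
  if (any(!is.finite(L)) || any(L <= 0)) stop("'L' must be positive")
  if (any(!is.finite(Tlag)) || any(Tlag <= 0))
    stop("lag time non-positive; D undefined")
  L^2 / (6 * Tlag)
}

#' Partition coefficient from lag time and permeability
#'
#' \eqn{K = 6 T_{lag} K_p / L}, the membrane/vehicle partition coefficient
#' implied by the lag-time relations (equivalently \eqn{K_p = K D / L}).
#'
#' @param Tlag Lag time in h.
#' @param Kp Permeability coefficient in cm/h.
#' @param L Membrane thickness in cm. Must be positive.
#' @return Dimensionless partition coefficient.
#' @export
compute_K <- function(Tlag, Kp, L) {
  if (any(!is.finite(L)) || any(L <= 0)) stop("'L' must be positive")
  6 * Tlag * Kp / L
}

#' Fit permeation parameters to an infinite-dose profile
#'
#' The central model fit: estimates the steady-state flux and lag time of a
#' cumulative permeation profile by ordinary least squares over a linear
#' window ([fit_steady_state()]), then derives the permeability coefficient
#' \eqn{K_p = Flux/C_v}, the diffusion coefficient
#' \eqn{D = L^2/(6 T_{lag})} and the partition coefficient
#' \eqn{K = 6 T_{lag} K_p / L}.
#'
#' A negative lag time (possible with noisy profiles) is retained as
#' computed and flagged with a warning rather than clamped, so that
#' downstream `D` and `K` visibly propagate the anomaly; `D` is `NA` when
#' `Tlag <= 0` since the lag-time relation is then undefined.
#'
#' @param profile A [permeation_profile()].
#' @param window Integer indices of profile points to fit, or `NULL` for
#'   the membrane default (see [fit_steady_state()]).
#' @return An object of class `perm_fit` with components `Flux`, `Tlag`,
#'   `Kp`, `D`, `K`, `fit_r2`, `n_points`, `window`, `negative_tlag`, the
#'   source `profile` and the underlying `lm` fit. Methods: [print()],
#'   [summary()], [coef()], [predict()], [residuals()], [plot()],
#'   [simulate()].
#' @examples
#' m <- membrane_spec("strat_m", L = 0.03)
#' prof <- simulate_permeation_profile(Kp = 2e-3, K = 0.5, Cv = 1e4,
#'                                     membrane = m, times = c(4, 6, 8))
#' fit <- fit_permeation(prof)
#' coef(fit)
#' @export
fit_permeation <- function(profile, window = NULL) {
  stopifnot(inherits(profile, "permeation_profile"))
  ss <- fit_steady_state(profile, window)
  L <- profile$membrane$L
  Kp <- compute_kp(ss$Flux, profile$Cv)
  K <- compute_K(ss$Tlag, Kp, L)
  D <- if (ss$Tlag > 0) compute_D(L, ss$Tlag) else {
    warning("lag time <= 0: diffusion coefficient undefined (NA)",
            call. = FALSE)
    NA_real_
  }
  structure(list(Flux = ss$Flux, Tlag = ss$Tlag, Kp = Kp, D = D, K = K,
                 fit_r2 = ss$r2, n_points = ss$n_points,
                 window = ss$window, negative_tlag = ss$negative_tlag,
                 intercept = ss$intercept, profile = profile, lm = ss$lm),
            class = "perm_fit")
}

#' @export
print.perm_fit <- function(x, digits = 4, ...) {
  p <- x$profile
  cat(sprintf("Permeation fit: %s through %s (%d of %d points, r^2 = %s)\n",
              p$chemical, p$membrane$name, x$n_points, length(p$times),
              signif(x$fit_r2, digits)))
  print(signif(coef(x), digits))
  if (isTRUE(x$negative_tlag))
    cat("warning: negative lag time; derived D/K are not physical\n")
  invisible(x)
}

#' @export
coef.perm_fit <- function(object, ...) {
  c(Flux = object$Flux, Tlag = object$Tlag, Kp = object$Kp,
    D = object$D, K = object$K)
}

#' @export
summary.perm_fit <- function(object, ...) {
  sl <- suppressWarnings(summary(object$lm))   # noiseless data is legitimate
  se_flux <- if (nrow(sl$coefficients) == 2L) sl$coefficients[2L, 2L]
             else NA_real_
  structure(list(fit = object, se_flux = se_flux,
                 se_kp = se_flux / object$profile$Cv,
                 sigma = sl$sigma),
            class = "summary.perm_fit")
}

#' @export
print.summary.perm_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("Flux standard error: %s ug/cm^2/h (Kp s.e. %s cm/h)\n",
              signif(x$se_flux, digits), signif(x$se_kp, digits)))
  cat(sprintf("Residual s.d. about the steady-state line: %s ug/cm^2\n",
              signif(x$sigma, digits)))
  invisible(x)
}

#' Predicted cumulative permeation from a fitted model
#'
#' @param object A `perm_fit`.
#' @param times Times (h) at which to predict; defaults to the profile's
#'   sampling times.
#' @param type `"linear"` for the steady-state tangent
#'   \eqn{Flux (t - T_{lag})} (floored at 0), or `"series"` for the full
#'   slab-diffusion series solution with the fitted `Kp` and `K` (requires
#'   a positive lag time).
#' @param ... Unused.
#' @return Numeric vector of cumulative amounts, ug/cm^2.
#' @export
predict.perm_fit <- function(object, times = object$profile$times,
                             type = c("linear", "series"), ...) {
  type <- match.arg(type)
  if (type == "linear")
    return(pmax(0, object$Flux * (times - object$Tlag)))
  if (!is.finite(object$D) || object$Tlag <= 0)
    stop("series prediction needs a positive fitted lag time")
  slab_series_cumulative(times, Kp = object$Kp, K = object$K,
                         L = object$profile$membrane$L,
                         Cv = object$profile$Cv)
}

#' @export
residuals.perm_fit <- function(object, ...) {
  idx <- object$window
  object$profile$cumulative[idx] -
    (object$Flux * (object$profile$times[idx] - object$Tlag))
}

#' Plot a permeation profile with its steady-state fit
#'
#' Base-graphics scatter of the cumulative profile, the fitted steady-state
#' tangent (dashed) and the lag-time intercept on the time axis.
#'
#' @param x A `perm_fit`.
#' @param ... Passed to [plot()].
#' @export
plot.perm_fit <- function(x, ...) {
  p <- x$profile
  plot(p$times, p$cumulative, xlab = "time (h)",
       ylab = expression(paste("cumulative amount (", mu, "g/", cm^2, ")")),
       main = sprintf("%s / %s", p$chemical, p$membrane$name),
       xlim = c(0, max(p$times)), ylim = c(0, max(p$cumulative)), ...)
  points(p$times[x$window], p$cumulative[x$window], pch = 19)
  abline(a = x$intercept, b = x$Flux, lty = 2)
  points(x$Tlag, 0, pch = 4)
  legend("topleft", bty = "n",
         legend = c(sprintf("Flux = %.3g ug/cm2/h", x$Flux),
                    sprintf("Tlag = %.3g h", x$Tlag)))
  invisible(x)
}

#' Simulate replicate profiles from a fitted permeation model
#'
#' Draws `nsim` noisy replicates of the source profile from the
#' slab-diffusion series solution with the fitted `Kp` and `K`, applying
#' multiplicative Gaussian noise.
#'
#' @param object A `perm_fit` with positive lag time.
#' @param nsim Number of replicate profiles.
#' @param seed Optional RNG seed.
#' @param sigma_rel Relative noise standard deviation.
#' @param ... Unused.
#' @return A data.frame with one column per replicate (`sim_1`, ...), rows
#'   matching the profile's sampling times.
#' @export
simulate.perm_fit <- function(object, nsim = 1, seed = NULL,
                              sigma_rel = 0.1, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.finite(object$D) || object$Tlag <= 0)
    stop("simulation needs a positive fitted lag time")
  p <- object$profile
  out <- replicate(nsim, {
    simulate_permeation_profile(Kp = object$Kp, K = object$K,
                                L = p$membrane$L, Cv = p$Cv,
                                times = p$times, sigma_rel = sigma_rel,
                                membrane = p$membrane)$cumulative
  })
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Aggregate permeation parameters over replicates
#'
#' Parameters are estimated per replicate Franz cell and reported as mean
#' with standard error, the conventional presentation for n = 3-4 cells.
#'
#' @param fits A list of `perm_fit` objects (replicates of one
#'   chemical/membrane combination).
#' @return A data.frame with columns `parameter`, `mean`, `se`, `n`.
#' @export
summarize_replicates <- function(fits) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "perm_fit")))
  mat <- vapply(fits, coef, numeric(5L))
  data.frame(parameter = rownames(mat),
             mean = rowMeans(mat),
             se = apply(mat, 1L, function(v) sd(v) / sqrt(length(v))),
             n = length(fits),
             row.names = NULL)
}
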