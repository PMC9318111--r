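#' Exact cumulative permeation of a slab membrane
#'
#' Series solution for diffusion through a homogeneous slab held at a
#' constant donor concentration (infinite dose), the physics underlying the
#' lag-time relations:
#' \deqn{Q(t) = K L C_v \left( \frac{D t}{L^2} - \frac{1}{6}
#'   - \frac{2}{\pi^2} \sum_{n \ge 1} \frac{(-1)^n}{n^2}
#'     e^{-D n^2 \pi^2 t / L^2} \right), \quad D = K_p L / K}
#' Its large-time tangent has slope \eqn{K_p C_v} and x-intercept
#' \eqn{L^2/(6D)} — exactly the steady-state flux and lag time recovered by
#' [fit_permeation()].
#'
#' @param times Times in h (non-negative).
#' @param Kp Permeability coefficient, cm/h (> 0).
#' @param K Partition coefficient (> 0; `D = Kp*L/K` is undefined at 0).
#' @param L Membrane thickness, cm.
#' @param Cv Donor concentration, ug/mL.
#' @param tol Series truncation tolerance on a term (default 1e-12).
#' @param max_terms Series length cap (default 200).
#' @return Cumulative amounts per area, ug/cm^2 (floored at 0 against
#'   truncation round-off near t = 0).
#' @export
slab_series_cumulative <- function(times, Kp, K, L, Cv,
                                   tol = 1e-12, max_terms = 200) {
  check_positive_scalar(Kp, "Kp")
  check_positive_scalar(L, "L")
  check_positive_scalar(Cv, "Cv")
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K <= 0)
    stop("'K' must be positive (K = 0 leaves D = Kp*L/K undefined)")
  if (any(times < 0)) stop("'times' must be non-negative")
  D <- Kp * L / K
  tau <- D * pi^2 / L^2                 # slowest relaxation rate, 1/h
  s <- numeric(length(times))
  live <- rep(TRUE, length(times))
  for (n in seq_len(max_terms)) {
    term <- ((-1)^n / n^2) * exp(-tau * n^2 * times[live])
    s[live] <- s[live] + term
    live[live] <- abs(term) >= tol
    if (!any(live)) break
  }
  pmax(0, K * L * Cv * (D * times / L^2 - 1 / 6 - (2 / pi^2) * s))
}

#' Simulate an infinite-dose Franz-cell permeation profile
#'
#' Generates a cumulative permeation time course from the exact
#' slab-diffusion series solution with known ground-truth parameters,
#' optionally perturbed by multiplicative Gaussian noise (measured
#' concentrations are positive and replicate scatter roughly scales with
#' the mean, which multiplicative noise reflects). With `sigma_rel = 0` the
#' profile is exact, and fitting it back with [fit_permeation()] recovers
#' the generating parameters up to finite-window bias.
#'
#' @param Kp,K Ground-truth permeability (cm/h) and partition coefficient.
#' @param Cv Donor concentration, ug/mL.
#' @param membrane A [membrane_spec()]; or give `L` to use a generic
#'   synthetic membrane of that thickness.
#' @param L Membrane thickness in cm (ignored when `membrane` is given).
#' @param times Sampling times in h (default `c(2, 4, 6, 8)`, the standard
#'   2-hourly schedule).
#' @param sigma_rel Relative noise s.d. (0 = noiseless).
#' @param seed Optional RNG seed for reproducibility.
#' @param chemical Label for the profile.
#' @return A [permeation_profile()] carrying attribute `"truth"` with the
#'   generating parameters.
#' @examples
#' prof <- simulate_permeation_profile(Kp = 1e-2, K = 1.5, Cv = 1.83e3,
#'                                     L = 0.03, times = c(4, 6, 8))
#' coef(fit_permeation(prof))
#' @export
simulate_permeation_profile <- function(Kp, K, Cv, membrane = NULL,
                                        L = NULL, times = c(2, 4, 6, 8),
                                        sigma_rel = 0, seed = NULL,
                                        chemical = "synthetic") {
  if (is.null(membrane)) {
    if (is.null(L)) stop("supply either 'membrane' or 'L'")
    membrane <- membrane_spec("synthetic", L = L)
  }
  if (!is.null(seed)) set.seed(seed)
  Q <- slab_series_cumulative(times, Kp, K, membrane$L, Cv)
  if (sigma_rel < 0) stop("'sigma_rel' must be non-negative")
  if (sigma_rel > 0)
    Q <- pmax(0, Q * (1 + rnorm(length(Q), 0, sigma_rel)))
  prof <- permeation_profile(times, Q, Cv = Cv, membrane = membrane,
                             chemical = chemical)
  attr(prof, "truth") <- list(Kp = Kp, K = K, D = Kp * membrane$L / K,
                              Tlag = membrane$L * K / (6 * Kp))
  prof
}

#' Simulate an applied-solution weight series
#'
#' Emulates the evaporation kinetics of a small aqueous dose: near-linear
#' weight loss from `w0` down to a residual plateau (the non-volatile
#' fraction, default 1\% of `w0`) reached at `Teva_true`, measured at a
#' fixed cadence and continued for a few confirming points, with optional
#' multiplicative noise.
#'
#' @param w0 Initial solution weight, mg.
#' @param Teva_true True complete-evaporation time, h; must be a multiple
#'   of `interval`.
#' @param interval Weighing cadence, h (default 0.25).
#' @param residual_frac Plateau weight as a fraction of `w0`.
#' @param n_plateau Number of measurements taken after the plateau is
#'   reached (default 4).
#' @param sigma_rel Relative noise s.d.
#' @param seed Optional RNG seed.
#' @return An [evaporation_series()].
#' @examples
#' s <- simulate_evaporation_series(w0 = 10, Teva_true = 1.5)
#' estimate_teva(s)
#' @export
simulate_evaporation_series <- function(w0 = 10, Teva_true = 1.5,
                                        interval = 0.25,
                                        residual_frac = 0.01,
                                        n_plateau = 4, sigma_rel = 0,
                                        seed = NULL) {
  check_positive_scalar(w0, "w0")
  check_positive_scalar(interval, "interval")
  check_positive_scalar(Teva_true, "Teva_true")
  k <- Teva_true / interval
  if (abs(k - round(k)) > 1e-9)
    stop("'Teva_true' must be a multiple of 'interval'")
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, Teva_true + n_plateau * interval, by = interval)
  wres <- residual_frac * w0
  w <- pmax(w0 - (w0 - wres) * times / Teva_true, wres)
  if (sigma_rel > 0)
    w <- pmax(0, w * (1 + rnorm(length(w), 0, sigma_rel)))
  evaporation_series(times, w)
}

#' Simulate an observed finite-dose absorption ratio
#'
#' Stands in for a finite-dose Franz-cell experiment: the ground-truth
#' absorption ratio is computed by the numerical integrator
#' ([ode_absorption()], independent of the closed-form prediction path)
#' and perturbed by multiplicative Gaussian noise, clipped to `[0, 1]`.
#'
#' @inheritParams ode_absorption
#' @param sigma_rel Relative noise s.d. (0 = return the true ratio).
#' @param seed Optional RNG seed.
#' @return A single observed absorption ratio in `[0, 1]`.
#' @export
simulate_observed_absorption <- function(Kp, K, Cv,
                                         cfg = finite_dose_config(),
                                         sigma_rel = 0, seed = NULL,
                                         n_steps = 10000) {
  if (!is.null(seed)) set.seed(seed)
  r <- ode_absorption(Kp, K, Cv, cfg, n_steps = n_steps)$ratio
  if (sigma_rel > 0)
    r <- r * (1 + rnorm(1L, 0, sigma_rel))
  min(1, max(0, r))
}

#' Simulate a complete synthetic study
#'
#' Generates a self-contained study with known ground truth: per-chemical
#' infinite-dose profiles (replicated), one evaporation series, and noisy
#' "observed" finite-dose absorption ratios paired with their closed-form
#' predictions. Used to exercise the full estimate-predict-evaluate
#' pipeline without external data.
#'
#' @param chemicals Data frame with columns `chemical`, `Kp`, `K`, `Cv`
#'   (ground truths). Default: seven chemicals spanning Kp from 1e-4 to
#'   2e-2 cm/h and K from 0.05 to 3, the ranges seen across hydrophilic to
#'   moderately lipophilic solutes.
#' @param membrane A [membrane_spec()].
#' @param times Profile sampling times, h.
#' @param n_replicates Franz cells per chemical.
#' @param sigma_profile Relative noise on profiles.
#' @param sigma_observed Relative noise on observed ratios (default 0.15,
#'   typical of replicate scatter in finite-dose experiments).
#' @param cfg A [finite_dose_config()].
#' @param seed RNG seed; fixed seed gives identical output.
#' @return List with `chemicals` (ground truth), `profiles` (list of lists
#'   of [permeation_profile()]s), `evaporation`
#'   ([evaporation_series()]) and `comparison` (data.frame of chemical,
#'   predicted and observed ratios).
#' @export
simulate_study <- function(chemicals = default_synthetic_chemicals(),
                           membrane = membrane_spec("strat_m", L = 0.03),
                           times = c(2, 4, 6, 8), n_replicates = 3,
                           sigma_profile = 0.05, sigma_observed = 0.15,
                           cfg = finite_dose_config(), seed = 1) {
  stopifnot(is.data.frame(chemicals),
            all(c("chemical", "Kp", "K", "Cv") %in% names(chemicals)))
  set.seed(seed)
  profiles <- lapply(seq_len(nrow(chemicals)), function(i) {
    lapply(seq_len(n_replicates), function(r) {
      simulate_permeation_profile(chemicals$Kp[i], chemicals$K[i],
                                  Cv = chemicals$Cv[i], membrane = membrane,
                                  times = times, sigma_rel = sigma_profile,
                                  chemical = chemicals$chemical[i])
    })
  })
  evap <- simulate_evaporation_series(sigma_rel = 0.005)
  comparison <- data.frame(
    chemical = chemicals$chemical,
    predicted = vapply(seq_len(nrow(chemicals)), function(i)
      predict_absorption(chemicals$Kp[i], chemicals$K[i],
                         chemicals$Cv[i], cfg)$ratio, 0),
    observed = vapply(seq_len(nrow(chemicals)), function(i)
      simulate_observed_absorption(chemicals$Kp[i], chemicals$K[i],
                                   chemicals$Cv[i], cfg,
                                   sigma_rel = sigma_observed), 0))
  list(chemicals = chemicals, profiles = profiles, evaporation = evap,
       comparison = comparison)
}

#' @rdname simulate_study
#' @export
default_synthetic_chemicals <- function() {
  data.frame(
    chemical = paste0("syn", 1:7),
    Kp = 10^seq(log10(1e-4), log10(2e-2), length.out = 7),
    K = 10^seq(log10(0.05), log10(3), length.out = 7),
    Cv = 1e4)
}
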