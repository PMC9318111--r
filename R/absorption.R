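#' Surface + stratum corneum amount during the evaporation phase
#'
#' While the vehicle is still present (phase 1, `0 <= t <= Teva`), the
#' applied chemical is modelled as one well-mixed compartment pooling the
#' surface solution and the stratum corneum (SC). First-order clearance
#' through the SC gives exponential depletion:
#' \deqn{M_{sur+SC}(t) = M_0 \exp(-K_p A t / (V + V_{sc}))}
#'
#' @param t Time since application, h; must lie in `[0, cfg$Teva]`.
#' @param M0 Applied amount at `t = 0`, ug.
#' @param Kp Permeability coefficient, cm/h.
#' @param cfg A [finite_dose_config()].
#' @return Remaining amount in the pooled compartment, ug.
#' @export
msur_sc_at <- function(t, M0, Kp, cfg = finite_dose_config()) {
  stopifnot(inherits(cfg, "finite_dose_config"))
  if (any(t < 0) || any(t > cfg$Teva))
    stop("'t' must lie within the evaporation phase [0, Teva]")
  check_nonneg(Kp, "Kp")
  M0 * exp(-Kp * cfg$A * t / (cfg$V + cfg$Vsc))
}

#' Amount permeated before complete evaporation (M1)
#'
#' The cumulative amount that has permeated through the stratum corneum by
#' the complete-evaporation time `Teva`, i.e. the phase-1 depletion
#' \eqn{M_1 = M_0 (1 - \exp(-K_p A T_{eva} / (V + V_{sc})))}.
#'
#' @inheritParams msur_sc_at
#' @return M1 in ug.
#' @export
m1_absorbed <- function(M0, Kp, cfg = finite_dose_config()) {
  M0 - msur_sc_at(cfg$Teva, M0, Kp, cfg)
}

#' Stratum corneum depot at the evaporation time
#'
#' At `Teva` the vehicle is gone; the amount remaining in the pooled
#' compartment splits between the (now inert) surface residue and the SC
#' depot according to the K-weighted volume fraction
#' \eqn{V_{sc} K / (V + V_{sc} K)}:
#' \deqn{M_{SC}(T_{eva}) = M_{sur+SC}(T_{eva})
#'       \frac{V_{sc} K}{V + V_{sc} K}}
#'
#' @inheritParams msur_sc_at
#' @param K Dimensionless SC/vehicle partition coefficient, `>= 0`.
#' @return SC depot at `Teva`, ug.
#' @export
msc_at_teva <- function(M0, Kp, K, cfg = finite_dose_config()) {
  check_nonneg(K, "K")
  msur_sc_at(cfg$Teva, M0, Kp, cfg) * partition_fraction(K, cfg)
}

# Vsc*K / (V + Vsc*K), with the K -> Inf limit handled exactly
partition_fraction <- function(K, cfg) {
  if (is.infinite(K)) 1 else cfg$Vsc * K / (cfg$V + cfg$Vsc * K)
}

#' Stratum corneum depot at the end of exposure
#'
#' After `Teva` (phase 2) the SC depot clears first-order into the deeper
#' layers with rate \eqn{K_p A / V_{sc}}:
#' \deqn{M_{SC}(t_{end}) = M_{SC}(T_{eva})
#'       \exp(-K_p A (t_{end} - T_{eva}) / V_{sc})}
#' The exponent can exceed several hundred for permeable chemicals; the
#' resulting underflow to 0 is the correct limit (complete clearance).
#'
#' @param Msc_teva SC depot at `Teva`, ug.
#' @inheritParams msur_sc_at
#' @return SC depot at `t_end`, ug.
#' @export
msc_at_end <- function(Msc_teva, Kp, cfg = finite_dose_config()) {
  stopifnot(inherits(cfg, "finite_dose_config"))
  check_nonneg(Kp, "Kp")
  Msc_teva * exp(-Kp * cfg$A * (cfg$t_end - cfg$Teva) / cfg$Vsc)
}

#' Amount permeated after complete evaporation (M2)
#'
#' Phase-2 depletion of the SC depot between `Teva` and `t_end`:
#' \deqn{M_2 = M_0 \frac{V_{sc} K}{V + V_{sc} K}
#'       \exp\!\left(-\frac{K_p A T_{eva}}{V + V_{sc}}\right)
#'       \left(1 - \exp\!\left(-\frac{K_p A (t_{end} - T_{eva})}{V_{sc}}
#'       \right)\right)}
#' Identically equal to `msc_at_teva() - msc_at_end()`.
#'
#' @inheritParams msc_at_teva
#' @return M2 in ug.
#' @export
m2_absorbed <- function(M0, Kp, K, cfg = finite_dose_config()) {
  msc <- msc_at_teva(M0, Kp, K, cfg)
  msc - msc_at_end(msc, Kp, cfg)
}

#' Predict finite-dose percutaneous absorption
#'
#' Closed-form prediction of the percutaneous absorption of a chemical
#' applied as a small, in-use-like dose of aqueous solution. Absorption is
#' the sum of two phases: `M1`, permeated while the vehicle is present
#' (pooled surface + SC compartment, exponential depletion), and `M2`,
#' cleared from the SC depot after the vehicle has evaporated at `Teva`.
#' The surface residue left when the vehicle evaporates is assumed never to
#' penetrate. The applied amount is `M0 = dose_volume * Cv`.
#'
#' @param Kp Permeability coefficient (cm/h), or a [fit_permeation()]
#'   object from which `Kp`, `K` and `Cv` are taken.
#' @param K SC/vehicle partition coefficient (dimensionless, `>= 0`;
#'   `Inf` allowed as the all-in-SC limit).
#' @param Cv Donor/applied concentration, ug/mL.
#' @param cfg A [finite_dose_config()].
#' @return An object of class `absorption_prediction`: list with `M0`,
#'   `M1`, `M2`, `total`, `ratio` (= total/M0), `Msc_at_teva`,
#'   `Msc_at_end`, `surface_residue`, and the inputs. The components
#'   satisfy `M1 + M2 + Msc_at_end + surface_residue = M0` exactly.
#' @examples
#' # caffeine through Strat-M, standard in-use conditions
#' predict_absorption(Kp = 1.23e-3, K = 0.422, Cv = 1.00e4)
#' @export
predict_absorption <- function(Kp, K = NULL, Cv = NULL,
                               cfg = finite_dose_config()) {
  if (inherits(Kp, "perm_fit")) {
    fit <- Kp
    Kp <- fit$Kp
    if (is.null(K)) K <- fit$K
    if (is.null(Cv)) Cv <- fit$profile$Cv
  }
  stopifnot(inherits(cfg, "finite_dose_config"))
  check_nonneg(Kp, "Kp")
  check_nonneg(K, "K")
  check_positive_scalar(Cv, "Cv")
  M0 <- cfg$dose_volume * Cv
  Mteva <- msur_sc_at(cfg$Teva, M0, Kp, cfg)
  M1 <- M0 - Mteva
  frac <- partition_fraction(K, cfg)
  Msc1 <- Mteva * frac
  Msc2 <- msc_at_end(Msc1, Kp, cfg)
  M2 <- Msc1 - Msc2
  total <- M1 + M2
  structure(list(M0 = M0, M1 = M1, M2 = M2, total = total,
                 ratio = total / M0, Msc_at_teva = Msc1, Msc_at_end = Msc2,
                 surface_residue = Mteva * (1 - frac),
                 Kp = Kp, K = K, Cv = Cv, cfg = cfg,
                 method = "closed_form"),
            class = "absorption_prediction")
}

#' @export
print.absorption_prediction <- function(x, digits = 4, ...) {
  cat(sprintf("Finite-dose absorption prediction (%s; Kp = %g cm/h, K = %g)\n",
              x$method, x$Kp, x$K))
  cat(sprintf("  applied M0          %s ug\n", signif(x$M0, digits)))
  cat(sprintf("  M1 (0..Teva)        %s ug\n", signif(x$M1, digits)))
  cat(sprintf("  M2 (Teva..t_end)    %s ug\n", signif(x$M2, digits)))
  cat(sprintf("  total absorbed      %s ug\n", signif(x$total, digits)))
  cat(sprintf("  absorption ratio    %s\n", signif(x$ratio, digits)))
  cat(sprintf("  SC depot at t_end   %s ug\n", signif(x$Msc_at_end, digits)))
  cat(sprintf("  surface residue     %s ug\n",
              signif(x$surface_residue, digits)))
  invisible(x)
}

#' Numerical cross-check of the finite-dose model
#'
#' Independently recomputes the finite-dose prediction by fixed-step
#' classical 4th-order Runge-Kutta integration (via \pkg{deSolve}) of the
#' two first-order clearance equations: phase 1,
#' \eqn{-dM/dt = K_p A M/(V+V_{sc})} on `[0, Teva]`; the K-weighted
#' partition split at `Teva`; phase 2, \eqn{-dM/dt = K_p A M/V_{sc}} on
#' `[Teva, t_end]`. Fixed steps keep the result deterministic; the system
#' is linear and non-stiff, so 4th-order convergence applies.
#'
#' @inheritParams predict_absorption
#' @param n_steps Number of integration steps per phase (default 10000).
#' @return An `absorption_prediction` with `method = "rk4"`.
#' @export
ode_absorption <- function(Kp, K, Cv, cfg = finite_dose_config(),
                           n_steps = 10000) {
  stopifnot(inherits(cfg, "finite_dose_config"), n_steps >= 1)
  check_nonneg(Kp, "Kp")
  check_nonneg(K, "K")
  check_positive_scalar(Cv, "Cv")
  M0 <- cfg$dose_volume * Cv
  Mteva <- if (cfg$Teva > 0) {
    rate <- Kp * cfg$A / (cfg$V + cfg$Vsc)
    rk4_decay(M0, rate, 0, cfg$Teva, n_steps)
  } else M0
  M1 <- M0 - Mteva
  frac <- partition_fraction(K, cfg)
  Msc1 <- Mteva * frac
  Msc2 <- if (cfg$t_end > cfg$Teva) {
    rate2 <- Kp * cfg$A / cfg$Vsc
    rk4_decay(Msc1, rate2, cfg$Teva, cfg$t_end, n_steps)
  } else Msc1
  M2 <- Msc1 - Msc2
  structure(list(M0 = M0, M1 = M1, M2 = M2, total = M1 + M2,
                 ratio = (M1 + M2) / M0, Msc_at_teva = Msc1,
                 Msc_at_end = Msc2, surface_residue = Mteva * (1 - frac),
                 Kp = Kp, K = K, Cv = Cv, cfg = cfg, method = "rk4"),
            class = "absorption_prediction")
}

# fixed-step RK4 of dM/dt = -rate * M from t0 to t1; returns M(t1)
rk4_decay <- function(M0, rate, t0, t1, n_steps) {
  out <- deSolve::ode(y = c(M = M0),
                      times = seq(t0, t1, length.out = n_steps + 1),
                      func = function(t, y, p) list(-p * y),
                      parms = rate, method = "rk4")
  unname(out[nrow(out), "M"])
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop(sprintf("'%s' must be a non-negative number", name), call. = FALSE)
  invisible(TRUE)
}
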