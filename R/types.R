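#' Membrane specification
#'
#' Describes the diffusion membrane mounted in the Franz cell: its thickness
#' `L` (the length scale of the lag-time relations \eqn{D = L^2/(6 T_{lag})}
#' and \eqn{K = 6 T_{lag} K_p / L}) and the effective diffusion area `A`.
#'
#' Two presets match common experimental setups: excised (porcine) skin with
#' `L = 0.10` cm, and the synthetic Strat-M membrane with `L = 0.03` cm, both
#' with an effective area of 1.0 cm^2.
#'
#' @param name Label, e.g. `"porcine_skin"` or `"strat_m"`.
#' @param L Membrane thickness in cm. Must be positive.
#' @param A Effective diffusion area in cm^2. Must be positive.
#' @return An object of class `membrane_spec`: a list with elements `name`,
#'   `L` and `A`.
#' @examples
#' membrane_spec("strat_m", L = 0.03)
#' membrane_spec("porcine_skin", L = 0.10)
#' @export
membrane_spec <- function(name, L, A = 1.0) {
  stopifnot(is.character(name), length(name) == 1L)
  check_positive_scalar(L, "L")
  check_positive_scalar(A, "A")
  structure(list(name = name, L = L, A = A), class = "membrane_spec")
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat(sprintf("Membrane '%s': thickness L = %g cm, area A = %g cm^2\n",
              x$name, x$L, x$A))
  invisible(x)
}

#' Infinite-dose cumulative permeation profile
#'
#' Bundles one Franz-cell time course: sampling times, cumulative amount
#' permeated per unit area, the donor concentration `Cv` and the membrane.
#' This is the input to [fit_permeation()].
#'
#' @param times Sampling times in hours; strictly increasing, all positive,
#'   at least two points.
#' @param cumulative Cumulative amount permeated per area (ug/cm^2), one
#'   value per time point, all non-negative.
#' @param Cv Donor concentration in ug/mL. Must be positive.
#' @param membrane A [membrane_spec()].
#' @param chemical Optional chemical label.
#' @return An object of class `permeation_profile`.
#' @examples
#' permeation_profile(c(2, 4, 6, 8), c(5, 15, 25, 35),
#'                    Cv = 1e4, membrane = membrane_spec("strat_m", 0.03))
#' @export
permeation_profile <- function(times, cumulative, Cv, membrane,
                               chemical = "unknown") {
  times <- as.numeric(times)
  cumulative <- as.numeric(cumulative)
  if (length(times) < 2L)
    stop("a permeation profile needs at least two time points")
  if (length(times) != length(cumulative))
    stop("'times' and 'cumulative' must have the same length")
  if (any(times <= 0) || any(diff(times) <= 0))
    stop("'times' must be positive and strictly increasing")
  if (any(cumulative < 0))
    stop("cumulative amounts must be non-negative")
  check_positive_scalar(Cv, "Cv")
  if (!inherits(membrane, "membrane_spec"))
    stop("'membrane' must be a membrane_spec object")
  structure(list(chemical = chemical, times = times, cumulative = cumulative,
                 Cv = Cv, membrane = membrane),
            class = "permeation_profile")
}

#' @export
print.permeation_profile <- function(x, ...) {
  cat(sprintf("Permeation profile: %s through %s (Cv = %g ug/mL, %d points, t = %g..%g h)\n",
              x$chemical, x$membrane$name, x$Cv, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Receiver sampling scheme
#'
#' Volumes governing the withdrawal correction of
#' [correct_cumulative_for_sampling()]: the receiver chamber volume and the
#' aliquot removed (and replaced by fresh solvent) at each sampling time.
#' Defaults follow a standard Franz-cell protocol (8.0 mL receiver, 500 uL
#' aliquots).
#'
#' @param receiver_volume Receiver chamber volume in mL.
#' @param aliquot_volume Withdrawn aliquot volume in mL; must satisfy
#'   `0 < aliquot_volume <= receiver_volume`.
#' @return An object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(receiver_volume = 8.0, aliquot_volume = 0.5) {
  check_positive_scalar(receiver_volume, "receiver_volume")
  check_positive_scalar(aliquot_volume, "aliquot_volume")
  if (aliquot_volume > receiver_volume)
    stop("'aliquot_volume' cannot exceed 'receiver_volume'")
  structure(list(receiver_volume = receiver_volume,
                 aliquot_volume = aliquot_volume),
            class = "sampling_scheme")
}

#' Finite-dose model configuration
#'
#' Geometry, dose and timing constants of the two-phase finite-dose
#' absorption model. The defaults are the in-use conditions for a 10-uL
#' aqueous dose on 1 cm^2: application area `A` = 1.0 cm^2, solvent volume
#' `V` = 0.01 cm^3, stratum-corneum volume `Vsc` = 0.002 cm^3, complete
#' evaporation at `Teva` = 1.5 h, experiment end at `t_end` = 24 h, and an
#' applied amount `M0 = dose_volume * Cv`.
#'
#' @param A Application area, cm^2.
#' @param V Solvent (vehicle) volume, cm^3, held constant over phase 1.
#' @param Vsc Stratum-corneum volume, cm^3.
#' @param Teva Complete-evaporation time of the vehicle, h; must lie in
#'   `[0, t_end]`.
#' @param t_end End of the exposure, h.
#' @param dose_volume Applied dose volume, cm^3, used to convert the donor
#'   concentration into the applied amount `M0`.
#' @return An object of class `finite_dose_config`.
#' @examples
#' finite_dose_config()              # the standard in-use configuration
#' finite_dose_config(Teva = 3.0)    # slower-evaporating vehicle
#' @export
finite_dose_config <- function(A = 1.0, V = 0.01, Vsc = 0.002,
                               Teva = 1.5, t_end = 24, dose_volume = 0.01) {
  check_positive_scalar(A, "A")
  check_positive_scalar(V, "V")
  check_positive_scalar(Vsc, "Vsc")
  check_positive_scalar(t_end, "t_end")
  check_positive_scalar(dose_volume, "dose_volume")
  if (!is.numeric(Teva) || length(Teva) != 1L || is.na(Teva) || Teva < 0)
    stop("'Teva' must be a non-negative number")
  if (Teva > t_end)
    stop("'Teva' cannot exceed 't_end'")
  structure(list(A = A, V = V, Vsc = Vsc, Teva = Teva, t_end = t_end,
                 dose_volume = dose_volume),
            class = "finite_dose_config")
}

#' @export
print.finite_dose_config <- function(x, ...) {
  cat("Finite-dose configuration:\n")
  cat(sprintf("  area A        %g cm^2\n", x$A))
  cat(sprintf("  solvent V     %g cm^3\n", x$V))
  cat(sprintf("  SC volume Vsc %g cm^3\n", x$Vsc))
  cat(sprintf("  Teva          %g h\n", x$Teva))
  cat(sprintf("  t_end         %g h\n", x$t_end))
  cat(sprintf("  dose volume   %g cm^3\n", x$dose_volume))
  invisible(x)
}

# shared scalar validator
check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("'%s' must be a positive number", name), call. = FALSE)
  invisible(TRUE)
}
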