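#' Default run configuration
#'
#' All constants of the standard study setup in one validated object:
#' membrane thicknesses (skin 0.10 cm, Strat-M 0.03 cm), the finite-dose
#' geometry (`A` = 1 cm^2, `V` = 0.01 cm^3, `Vsc` = 0.002 cm^3, 10-uL dose,
#' `Teva` = 1.5 h, `t_end` = 24 h), the receiver sampling scheme (8.0 mL
#' receiver, 0.5 mL aliquots), the steady-state window policy (points at
#' t >= 2 h on skin, t >= 4 h on Strat-M) and the applicability domain in
#' log Kow for Strat-M-based prediction.
#'
#' @return An object of class `run_config` (a named list).
#' @export
default_run_config <- function() {
  structure(list(
    L_skin = 0.10, L_stratm = 0.03,
    A = 1.0, V = 0.01, Vsc = 0.002,
    Teva = 1.5, t_end = 24, dose_volume = 0.01,
    receiver_volume = 8.0, aliquot_volume = 0.5,
    window_tmin_skin = 2, window_tmin_stratm = 4,
    logkow_min = -0.2, logkow_max = 2.0,
    seed = 1L), class = "run_config")
}

#' Load a run configuration file
#'
#' Reads a plain `key: value` (YAML) configuration file and merges it over
#' the defaults of [default_run_config()]. Unknown keys and non-positive
#' physical constants are rejected with a descriptive error, so typos do
#' not silently fall back to defaults. An empty or missing-key file yields
#' the full default configuration.
#'
#' @param path Path to the configuration file.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- default_run_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  positive <- c("L_skin", "L_stratm", "A", "V", "Vsc", "t_end",
                "dose_volume", "receiver_volume", "aliquot_volume")
  for (k in positive) check_positive_scalar(cfg[[k]], k)
  if (!is.numeric(cfg$Teva) || cfg$Teva < 0 || cfg$Teva > cfg$t_end)
    stop("'Teva' must lie in [0, t_end]")
  if (cfg$aliquot_volume > cfg$receiver_volume)
    stop("'aliquot_volume' cannot exceed 'receiver_volume'")
  if (cfg$logkow_min > cfg$logkow_max)
    stop("'logkow_min' must not exceed 'logkow_max'")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Finite-dose configuration from a run configuration
#'
#' @param cfg A `run_config`.
#' @return A [finite_dose_config()] with the run's constants.
#' @export
as_finite_dose_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  finite_dose_config(A = cfg$A, V = cfg$V, Vsc = cfg$Vsc, Teva = cfg$Teva,
                     t_end = cfg$t_end, dose_volume = cfg$dose_volume)
}
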