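#' Read a permeation profile from CSV
#'
#' Reads one replicate's Franz-cell time course. The file must have a
#' `time_h` column and either `cumulative_ug_per_cm2` (taken as-is) or
#' `receiver_conc_ug_per_ml` (converted to cumulative amounts with the
#' withdrawal correction of [correct_cumulative_for_sampling()]).
#' Metadata (chemical, `Cv`, membrane geometry, sampling volumes) comes
#' from the function arguments or from a YAML sidecar file
#' (`<path>.yaml`, or given via `sidecar`) with keys `chemical`, `Cv`,
#' `membrane`, `L`, `A`, `receiver_volume`, `aliquot_volume`; explicit
#' arguments win over the sidecar.
#'
#' @param path CSV file path.
#' @param Cv Donor concentration, ug/mL.
#' @param membrane A [membrane_spec()].
#' @param scheme A [sampling_scheme()] for concentration files.
#' @param chemical Chemical label.
#' @param sidecar Optional path to a YAML metadata file.
#' @return A [permeation_profile()].
#' @export
read_permeation_profile <- function(path, Cv = NULL, membrane = NULL,
                                    scheme = NULL, chemical = NULL,
                                    sidecar = NULL) {
  if (is.null(sidecar)) {
    guess <- paste0(path, ".yaml")
    if (file.exists(guess)) sidecar <- guess
  }
  meta <- if (!is.null(sidecar)) yaml::read_yaml(sidecar) else list()
  if (is.null(Cv)) Cv <- meta$Cv
  if (is.null(chemical)) chemical <- if (!is.null(meta$chemical))
    meta$chemical else "unknown"
  if (is.null(membrane) && !is.null(meta$L))
    membrane <- membrane_spec(if (!is.null(meta$membrane)) meta$membrane
                              else "membrane",
                              L = meta$L,
                              A = if (!is.null(meta$A)) meta$A else 1.0)
  if (is.null(scheme))
    scheme <- sampling_scheme(
      receiver_volume = if (!is.null(meta$receiver_volume))
        meta$receiver_volume else 8.0,
      aliquot_volume = if (!is.null(meta$aliquot_volume))
        meta$aliquot_volume else 0.5)
  if (is.null(Cv) || is.null(membrane))
    stop("'Cv' and 'membrane' are required (as arguments or via sidecar)")
  dat <- read.csv(path, stringsAsFactors = FALSE)
  if (!"time_h" %in% names(dat)) stop("profile CSV needs a 'time_h' column")
  cum <- if ("cumulative_ug_per_cm2" %in% names(dat)) {
    dat$cumulative_ug_per_cm2
  } else if ("receiver_conc_ug_per_ml" %in% names(dat)) {
    correct_cumulative_for_sampling(dat$receiver_conc_ug_per_ml, scheme,
                                    area = membrane$A)
  } else {
    stop("profile CSV needs 'cumulative_ug_per_cm2' or 'receiver_conc_ug_per_ml'")
  }
  permeation_profile(dat$time_h, cum, Cv = Cv, membrane = membrane,
                     chemical = chemical)
}

#' Read an applied-solution weight series from CSV
#'
#' Expects columns `time_h` and `weight_mg`.
#'
#' @param path CSV file path.
#' @return An [evaporation_series()].
#' @export
read_evaporation_series <- function(path) {
  dat <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_h", "weight_mg") %in% names(dat)))
    stop("evaporation CSV needs 'time_h' and 'weight_mg' columns")
  evaporation_series(dat$time_h, dat$weight_mg)
}
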