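#' Bundled reference chemicals
#'
#' Physicochemical properties and applied aqueous concentrations of the
#' seven reference chemicals shipped with the package (kojic acid,
#' caffeine, isosorbide 5-mononitrate, lidocaine, sodium benzoate at two
#' pH values, methyl paraben), spanning log Kow from -2.3 to 2.0.
#'
#' @return Data frame with columns `chemical`, `abbrev`, `MW`, `logKow`,
#'   `Cv_ug_per_ml`, `solvent`.
#' @export
chemical_properties <- function() {
  read.csv(fixture_path("chemical_properties.csv"),
           stringsAsFactors = FALSE)
}

#' Bundled reference permeation parameters
#'
#' Measured permeability (`Kp`, cm/h) and partition (`K`) coefficients of
#' the reference chemicals through excised porcine skin and through the
#' Strat-M synthetic membrane (mean and standard error over 3-4 replicate
#' Franz cells; skin fitted over 2-8 h, Strat-M over 4-8 h).
#'
#' @return Data frame with columns `abbrev`, `membrane`, `Kp_cm_per_h`,
#'   `Kp_se`, `K`, `K_se`.
#' @export
permeation_parameters <- function() {
  read.csv(fixture_path("permeation_parameters.csv"),
           stringsAsFactors = FALSE)
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "findose")
  if (p == "") stop("bundled data file not found: ", file)
  p
}
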