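#' Withdrawal-corrected cumulative permeated amounts
#'
#' Converts receiver-chamber concentrations measured at successive sampling
#' times into cumulative amounts permeated per unit area, correcting for the
#' analyte removed with each aliquot. When an aliquot of volume `Va` is
#' withdrawn and replaced by fresh solvent, the mass removed at earlier
#' samplings must be added back:
#' \deqn{Q_n = \left(C_n V_{rec} + \sum_{i<n} C_i V_a\right) / A}
#'
#' With 500 uL drawn from an 8 mL receiver, about 6\% of the receiver
#' content leaves at every sampling; skipping the correction biases late
#' time points (and hence the fitted flux) low.
#'
#' @param concentrations Receiver concentrations in ug/mL, ordered by time.
#' @param scheme A [sampling_scheme()].
#' @param area Effective diffusion area in cm^2.
#' @return Numeric vector of cumulative amounts in ug/cm^2.
#' @examples
#' correct_cumulative_for_sampling(c(1, 2, 3), sampling_scheme(8.0, 0.5))
#' @export
correct_cumulative_for_sampling <- function(concentrations,
                                            scheme = sampling_scheme(),
                                            area = 1.0) {
  concentrations <- as.numeric(concentrations)
  if (length(concentrations) == 0L)
    stop("'concentrations' is empty")
  if (any(is.na(concentrations)) || any(concentrations < 0))
    stop("receiver concentrations must be non-negative")
  if (!inherits(scheme, "sampling_scheme"))
    stop("'scheme' must be a sampling_scheme object")
  check_positive_scalar(area, "area")
  removed <- c(0, cumsum(concentrations * scheme$aliquot_volume))
  (concentrations * scheme$receiver_volume +
     removed[seq_along(concentrations)]) / area
}
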