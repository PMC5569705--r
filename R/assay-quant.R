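#' Splicing efficiency from spliced / unspliced band quantification
#'
#' The fraction of transcripts spliced, computed as spliced signal divided by
#' the total (spliced + unspliced). Works identically for gel band
#' intensities and for Bioanalyser molarities (pmol/l); the two inputs must
#' simply share units.
#'
#' @param spliced,unspliced Non-negative signal vectors (recycled).
#' @return Numeric vector of fractions in \[0, 1\].
#' @examples
#' splicing_efficiency(95, 5) # 0.95
#' @export
splicing_efficiency <- function(spliced, unspliced) {
  if (any(spliced < 0) || any(unspliced < 0)) abort("band signals must be non-negative")
  total <- spliced + unspliced
  if (any(total == 0)) abort("spliced and unspliced signals are both zero")
  spliced / total
}

#' Normalise plate-reader fluorescence to mock and control transfections
#'
#' Each reading has the mock-transfected background subtracted and is then
#' divided by the mean mock-subtracted control reading, so controls average
#' exactly 1. Mock subtraction is applied to the controls too: without it the
#' controls would not normalise to 1, which is the contract of the assay.
#'
#' @param values Numeric readings to normalise.
#' @param mock Mock-transfected background reading (scalar).
#' @param controls Readings from control-transfected cells.
#' @return Normalised numeric vector.
#' @examples
#' normalize_fluorescence(60, mock = 10, controls = 110) # 0.5
#' @export
normalize_fluorescence <- function(values, mock, controls) {
  denom <- mean(controls - mock)
  if (!is.finite(denom) || denom <= 0) {
    abort("degenerate controls: mean mock-subtracted control signal must be positive")
  }
  (values - mock) / denom
}

#' Relative dual-luciferase ratio
#'
#' Renilla-to-firefly luminescence ratio, expressed relative to the ratio
#' obtained with a control construct (so the control reads 1). Scaling both
#' channels by a common factor leaves the result unchanged.
#'
#' @param renilla,firefly Luminescence readings (firefly must be positive).
#' @param control_ratio Renilla:firefly ratio of the control (positive).
#' @return Relative ratio vector.
#' @export
dual_luciferase_ratio <- function(renilla, firefly, control_ratio = 1) {
  if (any(firefly <= 0)) abort("firefly luminescence must be positive")
  if (any(control_ratio <= 0)) abort("control ratio must be positive")
  (renilla / firefly) / control_ratio
}
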