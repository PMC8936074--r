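#' Convert oxygen uptake between mmol s^-1 and L(STPD) min^-1
#'
#' All internal computation in the package uses molar units (VO2 in
#' mmol s^-1, power in W, demand slopes in umol J^-1); volumetric
#' L(STPD) min^-1 values appear only at the reporting edge. The
#' conversion uses the STPD molar volume of an ideal gas,
#' 22.4 L mol^-1 by default (22.393 is available for users who prefer
#' the real-gas value).
#'
#' @param vo2 Oxygen uptake in mmol s^-1. Must be non-negative.
#' @param l_per_min Oxygen uptake in L(STPD) min^-1. Must be non-negative.
#' @param molar_volume Molar volume of O2 at STPD, L mol^-1.
#'
#' @return A numeric vector in the target unit.
#'
#' @examples
#' vo2_to_l_per_min(2.9) # 3.9 L/min to two significant figures
#' vo2_from_l_per_min(3.9)
#' @export
vo2_to_l_per_min <- function(vo2, molar_volume = 22.4) {
  stopifnot(is.numeric(vo2), is.numeric(molar_volume), molar_volume > 0)
  if (any(vo2 < 0, na.rm = TRUE)) {
    abort("`vo2` must be non-negative.", class = "o2deficit_domain_error")
  }
  vo2 * 60 * molar_volume / 1000
}

#' @rdname vo2_to_l_per_min
#' @export
vo2_from_l_per_min <- function(l_per_min, molar_volume = 22.4) {
  stopifnot(is.numeric(l_per_min), is.numeric(molar_volume), molar_volume > 0)
  if (any(l_per_min < 0, na.rm = TRUE)) {
    abort("`l_per_min` must be non-negative.", class = "o2deficit_domain_error")
  }
  l_per_min * 1000 / (60 * molar_volume)
}
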