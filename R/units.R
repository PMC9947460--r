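# Unit conventions used throughout the package:
#   lengths mm, stresses/pressures Pa, assembled forces micro-Newton (uN),
#   reported resultants mN.  1 Pa * 1 mm^2 = 1 uN.

# cmH2O in Pa (conventional water column at 4 degC, g = 9.80665)
.PA_PER_CMH2O <- 98.0665
# mmHg expressed in cmH2O.  The clinical rounding 1 mmHg = 1.36 cmH2O is used
# so that quoted pressure pairs (e.g. 10 mmHg = 13.6 cmH2O) convert exactly.
.CMH2O_PER_MMHG <- 1.36

#' Convert pressures between mmHg, cmH2O and Pa
#'
#' Conversions use the clinical rounding 1 mmHg = 1.36 cmH2O, so that quoted
#' pairs such as 10 mmHg = 13.6 cmH2O round-trip exactly, and
#' 1 cmH2O = 98.0665 Pa.
#'
#' @param value numeric vector of pressures.
#' @param from,to units, one of `"mmHg"`, `"cmH2O"`, `"Pa"`.
#' @return numeric vector in the target unit.
#' @examples
#' pressure_convert(10, "mmHg", "cmH2O") # 13.6
#' pressure_convert(20, "cmH2O", "Pa")   # 1961.33
#' @export
pressure_convert <- function(value, from, to) {
  units <- c("mmHg", "cmH2O", "Pa")
  from <- match.arg(from, units)
  to <- match.arg(to, units)
  to_pa <- c(mmHg = .CMH2O_PER_MMHG * .PA_PER_CMH2O, cmH2O = .PA_PER_CMH2O, Pa = 1)
  value * to_pa[[from]] / to_pa[[to]]
}
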