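#' Oxygen solubility in seawater at 100% air saturation
#'
#' Dissolved-oxygen concentration of air-equilibrated seawater at 1 atm
#' total pressure, from the Garcia & Gordon (1992) polynomial fit to the
#' Benson & Krause data (the standard refit used throughout aquatic
#' respirometry). The fit in mL(STP) L^-1 is converted to mg L^-1 with the
#' molar volume of O2 (22.3916 L mol^-1, i.e. 1 mL O2 = 1.42905 mg).
#'
#' @param temperature Water temperature, degrees C (valid -2 to 40).
#' @param salinity Practical salinity (valid 0 to 42).
#' @return Oxygen concentration at 100% air saturation, mg O2 L^-1.
#'   Vectorised over both arguments.
#' @examples
#' o2_solubility(13, 33) # ~8.4 mg/L
#' @export
o2_solubility <- function(temperature, salinity) {
  if (any(!is.finite(temperature)) || any(!is.finite(salinity))) {
    stop("temperature and salinity must be finite")
  }
  if (any(temperature < -2 | temperature > 40)) {
    stop("temperature outside the valid range [-2, 40] degC")
  }
  if (any(salinity < 0 | salinity > 42)) {
    stop("salinity outside the valid range [0, 42]")
  }
  # Garcia & Gordon (1992), Benson & Krause refit, O2 in mL/L
  a <- c(2.00907, 3.22014, 4.05010, 4.94457, -2.56847e-1, 3.88767)
  b <- c(-6.24523e-3, -7.37614e-3, -1.03410e-2, -8.17083e-3)
  c0 <- -4.88682e-7
  ts <- log((298.15 - temperature) / (273.15 + temperature))
  lnc <- a[1] + a[2] * ts + a[3] * ts^2 + a[4] * ts^3 + a[5] * ts^4 +
    a[6] * ts^5 +
    salinity * (b[1] + b[2] * ts + b[3] * ts^2 + b[4] * ts^3) +
    c0 * salinity^2
  ml_per_l <- exp(lnc)
  ml_per_l * 1.42905
}
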