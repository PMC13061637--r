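#' Oxygen solubility in seawater at atmospheric equilibrium
#'
#' Equilibrium (100% air saturation) dissolved O2 concentration from the
#' Garcia & Gordon (1992) closed-form fit to the Benson & Krause data,
#' evaluated with the volumetric (cm3 dm-3) coefficient set and converted to
#' umol l-1 with the ideal molar volume of O2 (22.3916 l mol-1).
#'
#' Used to assign the reference concentration of 100%-saturation calibration
#' baths from their temperature and salinity.
#'
#' @param temperature_c water temperature, deg C (valid -2 to 40)
#' @param salinity practical salinity (valid 0 to 42)
#' @return O2 solubility in umol l-1
#' @references Garcia, H.E. & Gordon, L.I. (1992) Oxygen solubility in
#'   seawater: better fitting equations. Limnol. Oceanogr. 37, 1307-1312.
#' @examples
#' o2_saturation_concentration(1.2, 35)
#' @export
o2_saturation_concentration <- function(temperature_c, salinity) {
  if (any(!is.finite(temperature_c)) || any(!is.finite(salinity)))
    stop("temperature and salinity must be finite")
  if (any(temperature_c < -2 | temperature_c > 40))
    stop("temperature out of fit range [-2, 40] degC")
  if (any(salinity < 0 | salinity > 42))
    stop("salinity out of fit range [0, 42]")
  # Benson-Krause volumetric coefficients, Garcia & Gordon (1992) Table 1
  A <- c(2.00907, 3.22014, 4.05010, 4.94457, -2.56847e-1, 3.88767)
  B <- c(-6.24523e-3, -7.37614e-3, -1.03410e-2, -8.17083e-3)
  C0 <- -4.88682e-7
  ts <- log((298.15 - temperature_c) / (273.15 + temperature_c))
  lnc <- A[1] + A[2] * ts + A[3] * ts^2 + A[4] * ts^3 + A[5] * ts^4 +
    A[6] * ts^5 +
    salinity * (B[1] + B[2] * ts + B[3] * ts^2 + B[4] * ts^3) +
    C0 * salinity^2
  # ml(STP) l-1 -> umol l-1
  exp(lnc) * 1000 / 22.3916
}
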