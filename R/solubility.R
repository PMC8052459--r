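#' Oxygen saturation concentration of seawater
#'
#' Evaluates the Garcia & Gordon (1992) combined-fit polynomial for the
#' oxygen saturation concentration at one atmosphere of water-saturated air,
#' and converts from umol/kg to mmol/m3 with a constant reference density.
#' The result is strictly decreasing in both temperature (over 0--35 C) and
#' salinity (salting-out).
#'
#' @param temp Temperature (degrees C), in \[-2, 40\]. Vectorised.
#' @param sal Salinity (psu), in \[0, 42\]. Vectorised.
#' @param rho Seawater density used for the unit conversion (kg/m3).
#' @param units `"mmol_m3"` (default) or `"umol_kg"`.
#' @return Saturation concentration; about 282 mmol/m3 (274.6 umol/kg) at
#'   10 C and salinity 35.
#' @export
#' @examples
#' o2_saturation(10, 35)
o2_saturation <- function(temp, sal, rho = 1026.5,
                          units = c("mmol_m3", "umol_kg")) {
  units <- match.arg(units)
  if (any(temp < -2 | temp > 40)) {
    abort("`temp` out of range [-2, 40] C.", class = "o2c_domain_error")
  }
  if (any(sal < 0 | sal > 42)) {
    abort("`sal` out of range [0, 42] psu.", class = "o2c_domain_error")
  }
  # Garcia & Gordon (1992), combined fit, umol/kg
  a <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)
  b <- c(-7.01577e-3, -7.70028e-3, -1.13864e-2, -9.51519e-3)
  c0 <- -2.75915e-7
  ts <- log((298.15 - temp) / (273.15 + temp))
  lnc <- a[1] + a[2] * ts + a[3] * ts^2 + a[4] * ts^3 + a[5] * ts^4 + a[6] * ts^5 +
    sal * (b[1] + b[2] * ts + b[3] * ts^2 + b[4] * ts^3) + c0 * sal^2
  umol_kg <- exp(lnc)
  if (units == "umol_kg") umol_kg else umol_kg * rho / 1000
}

#' CO2 solubility in seawater
#'
#' Weiss (1974) fit for the CO2 solubility K0 in mol/(kg atm).
#'
#' @inheritParams o2_saturation
#' @return K0 in mol/(kg atm); about 0.0284 at 25 C, salinity 35.
#' @export
co2_solubility <- function(temp, sal) {
  tk <- (temp + 273.15) / 100
  exp(-60.2409 + 93.4517 / tk + 23.3585 * log(tk) +
        sal * (0.023517 - 0.023656 * tk + 0.0047036 * tk^2))
}

#' First and second dissociation constants of carbonic acid
#'
#' Lueker, Dickson & Keeling (2000) fits for K1 and K2 on the total pH
#' scale, mol/kg.
#'
#' @inheritParams o2_saturation
#' @return List with vectors `k1` and `k2`.
#' @export
carbonate_constants <- function(temp, sal) {
  tk <- temp + 273.15
  pk1 <- 3633.86 / tk - 61.2172 + 9.6777 * log(tk) -
    0.011555 * sal + 0.0001152 * sal^2
  pk2 <- 471.78 / tk + 25.929 - 3.16967 * log(tk) -
    0.01781 * sal + 0.0001122 * sal^2
  list(k1 = 10^(-pk1), k2 = 10^(-pk2))
}

#' Air--sea oxygen flux
#'
#' Bulk gas-exchange flux `piston * area * (saturation - surface
#' concentration)`, positive into the ocean and zero at saturation.
#'
#' @param surface_o2 Surface O2 concentration (mmol/m3).
#' @param temp,sal Surface temperature (C) and salinity (psu).
#' @param piston Piston velocity (m/yr), >= 0.
#' @param area Outcrop area (m2), >= 0.
#' @return Flux in mol O2/yr (positive = ingassing).
#' @export
airsea_flux_o2 <- function(surface_o2, temp, sal, piston, area) {
  if (any(piston < 0) || any(area < 0)) {
    abort("`piston` and `area` must be non-negative.", class = "o2c_parameter_error")
  }
  piston * area * (o2_saturation(temp, sal) - surface_o2) * 1e-3
}

#' Air--sea CO2 flux
#'
#' Bulk flux `piston * area * K0 * rho * (pCO2_atm - pCO2_ocean)`, positive
#' into the ocean.
#'
#' @param pco2_ocean,pco2_atm Partial pressures (uatm).
#' @param temp,sal Surface temperature (C) and salinity (psu).
#' @param piston Piston velocity (m/yr).
#' @param area Outcrop area (m2).
#' @param rho Seawater density (kg/m3).
#' @return Flux in mol C/yr (positive = ingassing).
#' @export
airsea_flux_co2 <- function(pco2_ocean, pco2_atm, temp, sal, piston, area,
                            rho = 1026.5) {
  if (any(piston < 0) || any(area < 0)) {
    abort("`piston` and `area` must be non-negative.", class = "o2c_parameter_error")
  }
  k0 <- co2_solubility(temp, sal)
  piston * area * k0 * rho * (pco2_atm - pco2_ocean) * 1e-6
}

#' Oxygen partial pressure from concentration
#'
#' Converts dissolved O2 to partial pressure via the surface-referenced
#' saturation: `pO2 = [O2] / sat(T, S) * 0.21 atm`.  No hydrostatic pressure
#' correction is applied; the metabolic index uses only pO2 ratios, which a
#' constant reference leaves untouched.
#'
#' @param o2 Dissolved oxygen (mmol/m3).
#' @param temp,sal Temperature (C) and salinity (psu).
#' @param atm_po2 Atmospheric O2 partial pressure (atm).
#' @return pO2 in atm.
#' @export
po2_from_o2 <- function(o2, temp, sal, atm_po2 = 0.21) {
  o2 / o2_saturation(temp, sal) * atm_po2
}
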