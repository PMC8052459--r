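#' Ocean pCO2 from DIC and alkalinity
#'
#' Solves the carbonate-alkalinity system (CO2*, HCO3-, CO3-- only, with
#' borate and water terms absorbed into the calibrated alkalinity) for the
#' hydrogen-ion concentration by safeguarded bracketing iteration to 1e-6
#' relative tolerance, and returns `pCO2 = [CO2*] / K0`.  The result is
#' strictly increasing in DIC at fixed alkalinity and decreasing in
#' alkalinity at fixed DIC.
#'
#' @param dic Dissolved inorganic carbon (mmol/m3), with `0 < dic <
#'   1.5 * alk`.
#' @param alk Carbonate alkalinity (mmol eq/m3).
#' @param temp,sal Temperature (C) and salinity (psu).
#' @param rho Seawater density for the mmol/m3 to mol/kg conversion.
#' @return Ocean pCO2 in uatm. Vectorised over all arguments.
#' @export
#' @examples
#' solve_pco2(2100, 2370, 18, 35)
solve_pco2 <- function(dic, alk, temp, sal, rho = 1026.5) {
  n <- max(length(dic), length(alk), length(temp), length(sal))
  dic <- rep_len(dic, n); alk <- rep_len(alk, n)
  temp <- rep_len(temp, n); sal <- rep_len(sal, n)
  if (any(dic <= 0) || any(dic >= 1.5 * alk)) {
    abort("require 0 < dic < 1.5 * alk for the carbonate-alkalinity system.",
          class = "o2c_domain_error")
  }
  if (any(alk >= 2 * dic)) {
    # carbonate alkalinity cannot exceed 2 * DIC: no CO2* solution exists
    abort("require alk < 2 * dic: carbonate alkalinity cannot exceed 2 DIC.",
          class = "o2c_domain_error")
  }
  ks <- carbonate_constants(temp, sal)
  k0 <- co2_solubility(temp, sal)
  dic_kg <- dic * 1e-3 / rho
  alk_kg <- alk * 1e-3 / rho
  out <- numeric(n)
  for (i in seq_len(n)) {
    f <- function(h) {
      d <- h^2 + ks$k1[i] * h + ks$k1[i] * ks$k2[i]
      dic_kg[i] * (ks$k1[i] * h + 2 * ks$k1[i] * ks$k2[i]) / d - alk_kg[i]
    }
    lo <- 1e-14; hi <- 1e-2
    if (f(lo) * f(hi) > 0) {
      abort(sprintf(
        "no sign change in [H+] bracket (dic=%.1f, alk=%.1f, T=%.1f): chemistry failure.",
        dic[i], alk[i], temp[i]), class = "o2c_chemistry_error")
    }
    root <- uniroot(f, c(lo, hi), tol = 1e-6 * 1e-8, maxiter = 200)
    h <- root$root
    d <- h^2 + ks$k1[i] * h + ks$k1[i] * ks$k2[i]
    co2star <- dic_kg[i] * h^2 / d
    out[i] <- co2star / k0[i] * 1e6
  }
  out
}

# Closed-form root of the same carbonate-alkalinity system, used in the
# annual stepping loop; pinned to solve_pco2() by an equivalence test.
# With CA = alkalinity, [H+] solves CA h^2 + K1 (CA - DIC) h + K1 K2 (CA - 2 DIC) = 0.
pco2_closed_form <- function(dic, alk, temp, sal, rho = 1026.5) {
  ks <- carbonate_constants(temp, sal)
  k0 <- co2_solubility(temp, sal)
  dic_kg <- dic * 1e-3 / rho
  alk_kg <- alk * 1e-3 / rho
  a <- alk_kg
  b <- ks$k1 * (alk_kg - dic_kg)
  cc <- ks$k1 * ks$k2 * (alk_kg - 2 * dic_kg)
  h <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  d <- h^2 + ks$k1 * h + ks$k1 * ks$k2
  dic_kg * h^2 / d / k0 * 1e6
}
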