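#' Radiative forcing from atmospheric CO2
#'
#' Standard logarithmic CO2 forcing `a * ln(pCO2 / pCO2_preindustrial)`,
#' zero at the pre-industrial reference and monotone increasing in pCO2.
#'
#' @param pco2 Atmospheric CO2 partial pressure (uatm), > 0. Vectorised.
#' @param params Climate parameter list (the `climate` block of
#'   [default_config()]): uses `forcing_coeff_w_m2` and `co2_preind_uatm`.
#' @return Forcing in W/m2.
#' @export
#' @examples
#' radiative_forcing(2 * 278, default_config()$climate) # ~3.71 W/m2
radiative_forcing <- function(pco2, params) {
  if (any(!is.finite(pco2)) || any(pco2 <= 0)) {
    abort("`pco2` must be positive.", class = "o2c_domain_error")
  }
  params$forcing_coeff_w_m2 * log(pco2 / params$co2_preind_uatm)
}

#' Advance the atmospheric carbon and energy balance by one step
#'
#' Updates atmospheric pCO2 from the carbon mass balance (emissions net of
#' the constant-fraction land sink, minus ocean uptake, converted with the
#' Gt C per uatm factor) and the surface air temperature anomaly from a
#' one-layer energy balance `C dSAT/dt = F - lambda SAT - H_ocean`, solved
#' implicitly in SAT so the small atmospheric heat capacity never limits the
#' step.  Carbon is conserved exactly: the atmospheric change equals emitted
#' carbon minus land and ocean sinks.
#'
#' @param state List with `pco2` (uatm) and `sat_anom` (degrees C).
#' @param emissions_gtco2 Emission rate over the step (Gt CO2/yr).
#' @param ocean_co2_uptake_gtc Ocean carbon uptake rate (Gt C/yr, positive
#'   into the ocean).
#' @param ocean_heat_flux_w_m2 Ocean heat uptake averaged over the Earth
#'   surface (W/m2, positive into the ocean).
#' @param dt Time step (yr), > 0.
#' @param params Climate parameter list (see [default_config()]).
#' @return Updated state list with an added `land_uptake_gtc` element giving
#'   the land sink over the step (Gt C).
#' @export
step_atmosphere <- function(state, emissions_gtco2, ocean_co2_uptake_gtc,
                            ocean_heat_flux_w_m2, dt, params) {
  if (!is.numeric(dt) || dt <= 0) {
    abort("`dt` must be positive.", class = "o2c_parameter_error")
  }
  emis_gtc <- emissions_gtco2 / GTCO2_PER_GTC
  land_gtc <- params$land_sink_fraction * emis_gtc
  d_atm_gtc <- (emis_gtc - land_gtc - ocean_co2_uptake_gtc) * dt
  pco2 <- state$pco2 + d_atm_gtc / params$gtc_per_uatm
  if (!is.finite(pco2) || pco2 <= 0) {
    abort("atmospheric pCO2 driven non-positive; integration failed.",
          class = "o2c_integration_error")
  }
  forcing <- radiative_forcing(pco2, params)
  c_heat <- params$atm_heat_capacity_j_k_m2
  dt_s <- dt * SECONDS_PER_YEAR
  # implicit (backward Euler) in the lambda*SAT term
  sat <- (state$sat_anom + dt_s / c_heat * (forcing - ocean_heat_flux_w_m2)) /
    (1 + dt_s * params$feedback_w_m2_k / c_heat)
  list(pco2 = pco2, sat_anom = sat, land_uptake_gtc = land_gtc * dt)
}
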