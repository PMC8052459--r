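#' Export production from a surface box
#'
#' Diagnostic export flux of organic phosphorus out of a surface box:
#' Michaelis--Menten uptake in phosphate times a Q10 temperature factor,
#' `flux = max_uptake * Q10^((T - T_ref)/10) * PO4 / (PO4 + K) * PO4 * V`.
#' Export removes PO4 (and NO3 at 16:1, DIC at 112:1) from the surface box
#' and releases O2 at 169.6:1; those debits are applied by the caller from
#' the returned flux.  If a step length is supplied the flux is limited so
#' the available phosphate is never overdrawn.
#'
#' @param surface_po4 Surface phosphate (mmol/m3), >= 0.
#' @param surface_t Surface temperature (C).
#' @param params The `biogeochem` block of the configuration (uses
#'   `max_uptake_yr`, `k_po4`, `q10`, `t_ref_c`).
#' @param surface_volume Surface box volume (m3).
#' @param dt Optional step (yr); when given, the flux is capped at the
#'   phosphate available during the step (with a warning).
#' @return Export flux in mol P/yr.
#' @export
export_production <- function(surface_po4, surface_t, params, surface_volume,
                              dt = NULL) {
  if (any(surface_po4 < 0) || any(surface_volume < 0)) {
    abort("`surface_po4` and `surface_volume` must be non-negative.",
          class = "o2c_parameter_error")
  }
  q10f <- params$q10^((surface_t - params$t_ref_c) / 10)
  mm <- surface_po4 / (surface_po4 + params$k_po4)
  mm[surface_po4 == 0] <- 0
  flux <- params$max_uptake_yr * q10f * mm * surface_po4 * 1e-3 * surface_volume
  if (!is.null(dt)) {
    avail <- surface_po4 * 1e-3 * surface_volume / dt
    over <- flux > avail
    if (any(over)) {
      warn("export limited to available phosphate.")
      flux[over] <- avail[over]
    }
  }
  flux
}

#' Partition export over the subsurface water column
#'
#' Distributes an export flux over the subsurface depth classes with the
#' reference fractions shifted toward shallower classes as the surface
#' warms: the shallow-class fraction is multiplied by `1 + shoaling * dT`
#' (clipped to \[0, 1\]) and the remaining fractions are renormalised, so the
#' delivered sum always equals the export flux.
#'
#' @param export_flux Export flux (mol P/yr), >= 0.
#' @param fractions Named numeric reference fractions (shallowest class
#'   first), in \[0, 1\] and summing to 1.
#' @param delta_t Surface temperature anomaly versus the reference (C).
#' @param shoaling_per_k Shoaling coefficient (1/K).
#' @return Named numeric of per-class deliveries (mol P/yr).
#' @export
#' @examples
#' vertical_partition(1, c(thermo = 0.72, mid = 0.13, deep = 0.1, bottom = 0.05), 1, 0.01)
vertical_partition <- function(export_flux, fractions, delta_t = 0,
                               shoaling_per_k = 0) {
  fr <- unlist(fractions)
  if (any(fr < 0 | fr > 1) || abs(sum(fr) - 1) > 1e-8) {
    abort("`fractions` must lie in [0, 1] and sum to 1.",
          class = "o2c_parameter_error")
  }
  f_sh <- fr[1] * (1 + shoaling_per_k * delta_t)
  if (f_sh < 0 || f_sh > 1) {
    warn("shoaling shift clipped to [0, 1].")
    f_sh <- min(max(f_sh, 0), 1)
  }
  rest <- fr[-1]
  scale <- if (sum(rest) > 0) (1 - f_sh) / sum(rest) else 0
  out <- c(f_sh, rest * scale)
  names(out) <- names(fr)
  export_flux * out
}

#' Remineralize organic phosphorus in a box
#'
#' Applies the fixed-stoichiometry remineralization rules to a flux of
#' organic phosphorus delivered to one box.  With oxygen at or above the
#' denitrification threshold, aerobic remineralization consumes 169.6 mol O2
#' and releases 16 mol NO3, 112 mol DIC and 1 mol PO4 per mol P, capped at
#' the available oxygen.  Below the threshold, nitrate substitutes as the
#' electron acceptor: oxygen is untouched and the net nitrate debit is
#' 119.68 mol per mol P, capped at the available nitrate.  Whatever cannot
#' be remineralized is returned as a residual to be forwarded to the box
#' below (or redissolved next step at the bottom), so phosphorus is
#' conserved exactly and no tracer is driven below zero.
#'
#' @param p_flux Organic P delivery (mol P/yr), >= 0.
#' @param o2,no3 Box concentrations (mmol/m3).
#' @param volume Box volume (m3).
#' @param stoich Stoichiometry list (see [default_config()]`$biogeochem$stoich`).
#' @param dt Time step (yr).
#' @return List with concentration increments `d_o2`, `d_no3`, `d_po4`,
#'   `d_dic` (mmol/m3), the remineralized amount `p_remin` (mol P) and the
#'   forwarded residual `p_residual` (mol P).
#' @export
remineralize <- function(p_flux, o2, no3, volume, stoich, dt = 1) {
  if (p_flux < 0) abort("`p_flux` must be non-negative.", class = "o2c_parameter_error")
  demand <- p_flux * dt # mol P
  d <- list(d_o2 = 0, d_no3 = 0, d_po4 = 0, d_dic = 0)
  p_remin <- 0
  if (demand > 0) {
    if (o2 >= stoich$o2_denit_threshold) {
      o2_avail <- o2 * 1e-3 * volume
      p_remin <- min(demand, o2_avail / stoich$r_o2_p)
      d$d_o2 <- -stoich$r_o2_p * p_remin * 1e3 / volume
      d$d_no3 <- stoich$r_n_p * p_remin * 1e3 / volume
    } else {
      no3_avail <- no3 * 1e-3 * volume
      p_remin <- min(demand, no3_avail / stoich$r_no3_p_denit)
      d$d_no3 <- -stoich$r_no3_p_denit * p_remin * 1e3 / volume
    }
    d$d_po4 <- p_remin * 1e3 / volume
    d$d_dic <- stoich$r_c_p * p_remin * 1e3 / volume
  }
  c(d, list(p_remin = p_remin, p_residual = demand - p_remin))
}
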