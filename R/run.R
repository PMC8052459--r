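# Coupled integration of the reduced climate--ocean model.
#
# Tracers are carried as an n_box x 7 matrix; all fluxes are applied
# annually with internal sub-stepping inside the transport operator.

TRACERS <- c("temp", "dic", "po4", "no3", "o2", "abio_o2", "age")

init_state <- function(config, geom) {
  n <- nrow(geom$boxes)
  bg <- config$biogeochem
  tr <- matrix(0, n, length(TRACERS), dimnames = list(geom$boxes$box, TRACERS))
  tr[, "temp"] <- ifelse(is.na(geom$boxes$t_preind), 3, geom$boxes$t_preind)
  tr[, "dic"] <- bg$dic_init
  tr[, "po4"] <- bg$po4_init
  tr[, "no3"] <- bg$no3_init
  tr[, "o2"] <- bg$o2_init
  tr[, "abio_o2"] <- bg$o2_init
  tr[, "age"] <- 0
  list(
    tr = tr,
    pending = setNames(rep(0, length(geom$columns)), names(geom$columns)),
    pco2 = config$climate$co2_preind_uatm,
    sat_anom = 0,
    na_integral = 0,
    cum_emitted_gtc = 0,
    cum_land_gtc = 0
  )
}

# per-surface-box delivery fractions: class fractions split into boxes
column_fractions <- function(geom, config) {
  fr_class <- config$biogeochem$remin_fractions
  atl <- geom$lowlat_atl_share
  purrr::imap(geom$columns, function(cols, sb) {
    classes <- unlist(cols)
    # within-class split for columns that feed two basins
    share <- vapply(names(classes), function(bx) {
      if (sb == "surf_lowlat" && grepl("atl$", bx)) atl
      else if (sb == "surf_lowlat" && classes[[bx]] != "bottom") 1 - atl
      else 1
    }, numeric(1))
    present <- unique(classes)
    f <- unlist(fr_class)[present]
    f <- f / sum(f) # renormalise when a column lacks some classes
    per_box <- f[classes] * share
    per_box <- per_box / sum(per_box) * 1 # exact partition of unity
    names(per_box) <- names(classes)
    list(fractions = per_box, classes = classes)
  })
}

# one model year; returns the updated state plus flux bookkeeping
model_year <- function(state, geom, op, config, pco2_atm, emissions_gtco2,
                       coupled, biology, colfr, dt = 1) {
  boxes <- geom$boxes
  cl <- config$climate
  bg <- config$biogeochem
  gas <- config$gas
  sal <- config$ocean$salinity_psu
  rho <- config$ocean$rho_kg_m3
  cp <- config$ocean$cp_j_kg_k
  surf <- which(boxes$is_surface)
  tr <- state$tr

  # 1. energy balance: the surface air temperature anomaly is solved
  # implicitly together with the linearized ocean-restoring heat uptake,
  # C (s - s0)/dt = F - lambda s - H(s) with H linear in s, which keeps the
  # tight air-sea coupling stable at the annual step
  gamma <- unlist(cl$surface_warming_factor)[boxes$box[surf]]
  f_relax <- 1 - exp(-dt / cl$surface_restore_years)
  if (coupled) {
    forcing <- radiative_forcing(state$pco2, cl)
    w_conv <- 1 / (dt * SECONDS_PER_YEAR * cl$earth_area_m2) # J/yr -> W/m2
    h0 <- sum(rho * cp * boxes$volume[surf] * f_relax *
                (boxes$t_preind[surf] - tr[surf, "temp"])) * w_conv
    hs <- sum(rho * cp * boxes$volume[surf] * f_relax * gamma) * w_conv
    c_dt <- cl$atm_heat_capacity_j_k_m2 / (dt * SECONDS_PER_YEAR)
    sat_anom <- (c_dt * state$sat_anom + forcing - h0) /
      (c_dt + cl$feedback_w_m2_k + hs)
    state$sat_anom <- sat_anom
  } else {
    sat_anom <- 0
  }

  # 2. surface temperature restoring toward the anomaly-shifted target
  t_target <- boxes$t_preind[surf] + gamma * sat_anom
  d_t <- (t_target - tr[surf, "temp"]) * f_relax
  heat_in_j <- sum(rho * cp * boxes$volume[surf] * d_t)
  tr[surf, "temp"] <- tr[surf, "temp"] + d_t

  # 2. transport of all tracers, then ageing
  tr <- apply_transport(tr, op, dt, max_courant = config$transport$max_courant)
  tr[, "age"] <- tr[, "age"] + dt
  tr[surf, "age"] <- tr[surf, "age"] *
    exp(-dt / config$transport$surface_age_relax_yr)

  # 3. export production and column remineralization
  export_total <- 0
  if (biology) {
    for (sb_i in surf) {
      sb <- boxes$box[sb_i]
      cf <- colfr[[sb]]
      if (is.null(cf)) next
      vol <- boxes$volume[sb_i]
      flux <- export_production(tr[sb_i, "po4"], tr[sb_i, "temp"], bg, vol, dt = dt)
      export_total <- export_total + flux
      p_mol <- flux * dt
      tr[sb_i, "po4"] <- tr[sb_i, "po4"] - p_mol * 1e3 / vol
      tr[sb_i, "no3"] <- max(tr[sb_i, "no3"] - bg$stoich$r_n_p * p_mol * 1e3 / vol, 0)
      tr[sb_i, "dic"] <- tr[sb_i, "dic"] - bg$stoich$r_c_p * p_mol * 1e3 / vol
      tr[sb_i, "o2"] <- tr[sb_i, "o2"] + bg$stoich$r_o2_p * p_mol * 1e3 / vol
      # shoaling responds to the surface anomaly of the exporting box
      d_t_surf <- tr[sb_i, "temp"] - boxes$t_preind[sb_i]
      class_names <- unique(cf$classes)
      class_fr <- vapply(class_names, function(cn) sum(cf$fractions[cf$classes == cn]),
                         numeric(1))
      class_flux <- vertical_partition(flux, class_fr, d_t_surf, bg$shoaling_per_k)
      delivery <- cf$fractions
      for (cn in class_names) {
        sel <- cf$classes == cn
        delivery[sel] <- cf$fractions[sel] / sum(cf$fractions[sel]) * class_flux[[cn]]
      }
      # process the column top-down, forwarding what cannot be remineralized
      ord <- order(boxes$depth_top[match(names(delivery), boxes$box)])
      carry <- 0
      for (bx in names(delivery)[ord]) {
        bi <- match(bx, boxes$box)
        inflow <- delivery[[bx]] + carry / dt
        if (bx == names(delivery)[ord][length(ord)]) {
          inflow <- inflow + state$pending[[sb]] / dt
        }
        rem <- remineralize(inflow, tr[bi, "o2"], tr[bi, "no3"],
                            boxes$volume[bi], bg$stoich, dt = dt)
        tr[bi, "o2"] <- tr[bi, "o2"] + rem$d_o2
        tr[bi, "no3"] <- tr[bi, "no3"] + rem$d_no3
        tr[bi, "po4"] <- tr[bi, "po4"] + rem$d_po4
        tr[bi, "dic"] <- tr[bi, "dic"] + rem$d_dic
        carry <- rem$p_residual
      }
      state$pending[[sb]] <- carry
    }
  }

  # 4. air-sea oxygen exchange (implicit relaxation to saturation); the
  # abiotic twin exchanges identically but has no biological sources
  sat_o2 <- o2_saturation(tr[surf, "temp"], sal)
  g_fac <- exp(-gas$piston_o2_m_yr * boxes$area[surf] / boxes$volume[surf] * dt)
  tr[surf, "o2"] <- sat_o2 + (tr[surf, "o2"] - sat_o2) * g_fac
  tr[surf, "abio_o2"] <- sat_o2 + (tr[surf, "abio_o2"] - sat_o2) * g_fac

  # 5. air-sea CO2 exchange against the (fixed or interactive) atmosphere
  pco2_oc <- pco2_closed_form(tr[surf, "dic"], bg$alk, tr[surf, "temp"], sal, rho)
  co2_flux <- airsea_flux_co2(pco2_oc, pco2_atm, tr[surf, "temp"], sal,
                              gas$piston_co2_m_yr, boxes$area[surf], rho)
  tr[surf, "dic"] <- tr[surf, "dic"] + co2_flux * dt * 1e3 / boxes$volume[surf]
  uptake_gtc <- sum(co2_flux) * dt * 12.011 * 1e-15

  state$tr <- tr
  # 6. atmospheric carbon mass balance (SAT already advanced in step 1)
  if (coupled) {
    emis_gtc <- emissions_gtco2 / GTCO2_PER_GTC
    land_gtc <- cl$land_sink_fraction * emis_gtc
    state$pco2 <- state$pco2 +
      (emis_gtc - land_gtc - uptake_gtc / dt) * dt / cl$gtc_per_uatm
    if (!is.finite(state$pco2) || state$pco2 <= 0) {
      abort("atmospheric pCO2 driven non-positive; integration failed.",
            class = "o2c_integration_error")
    }
    state$cum_emitted_gtc <- state$cum_emitted_gtc + emis_gtc * dt
    state$cum_land_gtc <- state$cum_land_gtc + land_gtc * dt
    na_anom <- tr[match("surf_natl", boxes$box), "temp"] -
      boxes$t_preind[match("surf_natl", boxes$box)]
    state$na_integral <- state$na_integral + max(na_anom, 0) * dt
  }
  list(state = state, uptake_gtc = uptake_gtc, heat_in_j = heat_in_j,
       export_molp = export_total)
}

#' Spin the ocean up to pre-industrial equilibrium
#'
#' Integrates the ocean under fixed pre-industrial atmospheric CO2 and zero
#' temperature anomaly until the oxygen-inventory drift and the global
#' air--sea CO2 flux fall below tolerance, or the configured maximum years.
#' The twelve-box ocean equilibrates in a few residence times, so the
#' default 10,000 years runs in seconds.
#'
#' @param config Model configuration, see [default_config()].
#' @param geom Optional pre-built [default_geometry()].
#' @param biology Disable to spin up an abiotic ocean.
#' @return A list of class `o2_spinup` with the equilibrated `state`,
#'   `years_run`, the final `drift_pmol_yr` and `co2_flux_gtc_yr`, and
#'   `converged`.
#' @export
spinup <- function(config = default_config(), geom = NULL, biology = TRUE) {
  geom <- geom %||% default_geometry(config)
  sc <- config$scenario
  state <- init_state(config, geom)
  colfr <- column_fractions(geom, config)
  op <- geom$base_op
  chunk <- sc$spinup_check_interval
  years_run <- 0
  drift <- Inf; co2_flux <- Inf
  while (years_run < sc$spinup_years) {
    inv0 <- o2_inventory_pmol(state$tr[, "o2"], geom)
    uptake <- 0
    for (k in seq_len(chunk)) {
      stp <- model_year(state, geom, op, config,
                        pco2_atm = config$climate$co2_preind_uatm,
                        emissions_gtco2 = 0, coupled = FALSE,
                        biology = biology, colfr = colfr)
      state <- stp$state
      uptake <- uptake + stp$uptake_gtc
    }
    years_run <- years_run + chunk
    drift <- abs(o2_inventory_pmol(state$tr[, "o2"], geom) - inv0) / chunk
    co2_flux <- uptake / chunk
    if (years_run >= 2 * chunk && drift < sc$drift_tol_pmol_yr &&
        abs(co2_flux) < 0.02) break
  }
  if (drift >= sc$drift_tol_pmol_yr) {
    abort(sprintf(
      "spin-up not converged after %d years: O2 drift %.2g Pmol/yr (tol %.2g), CO2 flux %.2g GtC/yr.",
      years_run, drift, sc$drift_tol_pmol_yr, co2_flux),
      class = "o2c_convergence_error")
  }
  structure(list(state = state, years_run = years_run, drift_pmol_yr = drift,
                 co2_flux_gtc_yr = co2_flux, converged = TRUE),
            class = "o2_spinup")
}

o2_inventory_pmol <- function(o2, geom) sum(o2 * geom$boxes$volume) * 1e-18

#' Run the zero-emission commitment experiment
#'
#' Couples all model components through the full experiment: spin-up to
#' pre-industrial equilibrium, emission-driven integration from the scenario
#' start year with the idealized historical curve, an abrupt emission stop
#' (zero emissions afterwards), and continued integration to the scenario
#' end year.  Annual states and a full diagnostics table are archived;
#' commitment accounting is evaluated between the baseline, stop and
#' evaluation years.
#'
#' @param config Model configuration, see [default_config()].
#' @param emissions Optional `emission_scenario` (see [build_emissions()] or
#'   [read_emissions_csv()]); by default the embedded idealized curve.
#' @param spinup_state Optional pre-computed [spinup()] result to reuse.
#' @param biology Disable to run the ocean abiotically (then the abiotic
#'   tracer and O2 coincide by construction).
#' @return An object of class `o2_run`: list with `series` (annual tibble of
#'   inventories and state), `archive` (year x box x tracer array),
#'   `geometry`, `config`, `spinup`, and `provenance`.
#' @export
#' @examples
#' \donttest{
#' run <- run_commitment()
#' glance(run)
#' }
run_commitment <- function(config = default_config(), emissions = NULL,
                           spinup_state = NULL, biology = TRUE) {
  geom <- default_geometry(config)
  sc <- config$scenario
  emissions <- emissions %||% build_emissions(sc, stop_year = sc$stop_year,
                                              start_year = sc$start_year,
                                              end_year = sc$end_year)
  sp <- spinup_state %||% spinup(config, geom, biology = biology)
  state <- sp$state
  colfr <- column_fractions(geom, config)
  boxes <- geom$boxes
  t_ref <- state$tr[, "temp"]      # equilibrium temperatures for heat content
  t_surf_eq <- t_ref[boxes$is_surface]
  dic_ref_gtc <- ocean_carbon_gtc(state, geom, config)
  years <- sc$start_year:sc$end_year
  n_y <- length(years)
  archive <- array(NA_real_, dim = c(n_y, nrow(boxes), length(TRACERS)),
                   dimnames = list(years, boxes$box, TRACERS))
  series <- tibble::tibble(
    year = years, pco2 = NA_real_, sat_anom = NA_real_, o2_pmol = NA_real_,
    abiotic_pmol = NA_real_, heat_j = NA_real_, ocean_c_gtc = NA_real_,
    land_c_gtc = NA_real_, atm_c_gtc = NA_real_, cum_emissions_gtc = NA_real_,
    export_molp_yr = NA_real_, ocean_mean_t = NA_real_, total_p_mol = NA_real_,
    psi_amoc = NA_real_, psi_so = NA_real_, heat_flux_j_yr = NA_real_
  )
  heat_cum <- 0
  op <- geom$base_op
  for (iy in seq_len(n_y)) {
    y <- years[iy]
    # warming-modulated circulation, anomalies relative to spun-up surface
    anom <- state$tr[boxes$is_surface, "temp"] - t_surf_eq
    names(anom) <- boxes$box[boxes$is_surface]
    op <- modulate_overturning(geom, anom, config$transport, state$na_integral)
    stp <- model_year(state, geom, op, config,
                      pco2_atm = state$pco2,
                      emissions_gtco2 = emissions$emissions_gtco2[match(y, emissions$year)],
                      coupled = TRUE, biology = biology, colfr = colfr)
    state <- stp$state
    heat_cum <- heat_cum + stp$heat_in_j
    archive[iy, , ] <- state$tr
    series$pco2[iy] <- state$pco2
    series$sat_anom[iy] <- state$sat_anom
    series$o2_pmol[iy] <- o2_inventory_pmol(state$tr[, "o2"], geom)
    series$abiotic_pmol[iy] <- o2_inventory_pmol(state$tr[, "abio_o2"], geom)
    series$heat_j[iy] <- sum(config$ocean$rho_kg_m3 * config$ocean$cp_j_kg_k *
                               boxes$volume * (state$tr[, "temp"] - t_ref))
    series$ocean_c_gtc[iy] <- ocean_carbon_gtc(state, geom, config) - dic_ref_gtc
    series$land_c_gtc[iy] <- state$cum_land_gtc
    series$atm_c_gtc[iy] <- (state$pco2 - config$climate$co2_preind_uatm) *
      config$climate$gtc_per_uatm
    series$cum_emissions_gtc[iy] <- state$cum_emitted_gtc
    series$export_molp_yr[iy] <- stp$export_molp
    series$ocean_mean_t[iy] <- sum(state$tr[, "temp"] * boxes$volume) / sum(boxes$volume)
    series$total_p_mol[iy] <- total_p_mol(state, geom)
    series$psi_amoc[iy] <- op$cell_scale[["amoc"]]
    series$psi_so[iy] <- op$cell_scale[["so_abyssal"]]
    series$heat_flux_j_yr[iy] <- stp$heat_in_j
  }
  structure(list(
    series = series, archive = archive, geometry = geom, config = config,
    spinup = sp[c("years_run", "drift_pmol_yr", "co2_flux_gtc_yr")],
    heat_flux_cum_j = heat_cum,
    provenance = list(config_hash = rlang::hash(config),
                      emissions_hash = rlang::hash(emissions$emissions_gtco2),
                      package_version = as.character(utils::packageVersion("o2commit")))
  ), class = "o2_run")
}

ocean_carbon_gtc <- function(state, geom, config) {
  dic_mol <- sum(state$tr[, "dic"] * geom$boxes$volume) * 1e-3
  organic_mol <- sum(state$pending) * config$biogeochem$stoich$r_c_p
  (dic_mol + organic_mol) * 12.011 * 1e-15
}

total_p_mol <- function(state, geom) {
  sum(state$tr[, "po4"] * geom$boxes$volume) * 1e-3 + sum(state$pending)
}

#' Box-model state as a gridded-field tibble
#'
#' Extracts one archived year of a run as a tidy per-box field with the
#' mask columns used by the diagnostics (`region`, `depth_class`,
#' `depth2000`), so [volume_census()], [threshold_volumes()],
#' [regional_depth_table()] and [metabolic_index_map()] apply unchanged.
#'
#' @param run An `o2_run`.
#' @param year Archived year to extract.
#' @return A tibble with columns `box`, `region`, `depth_class`,
#'   `depth2000`, `volume`, `t`, `s`, `o2`, `abio_o2`, `age`.
#' @export
box_field <- function(run, year) {
  iy <- match(year, run$series$year)
  if (is.na(iy)) abort("year not in run archive.", class = "o2c_parameter_error")
  b <- run$geometry$boxes
  tibble::tibble(
    box = b$box,
    region = ifelse(b$basin == "Southern", "Southern Ocean (90S-50S)",
                    paste0(b$basin, " (", b$latitude_band, ")")),
    depth_class = b$depth_class,
    depth2000 = b$depth2000,
    volume = b$volume,
    t = run$archive[iy, , "temp"],
    s = run$config$ocean$salinity_psu,
    o2 = run$archive[iy, , "o2"],
    abio_o2 = run$archive[iy, , "abio_o2"],
    age = run$archive[iy, , "age"]
  )
}

#' @export
print.o2_run <- function(x, ...) {
  g <- glance(x)
  cat("<o2_run> ", nrow(x$series), " years (",
      min(x$series$year), "-", max(x$series$year), ")\n", sep = "")
  cat(sprintf("  pCO2 %d: %.1f uatm | SAT anomaly: %.2f C\n",
              x$config$scenario$stop_year, g$pco2_stop, g$sat_anom_stop))
  cat(sprintf("  O2 loss: realized %.1f, committed %.1f, total %.1f Pmol\n",
              g$realized_pmol, g$committed_pmol, g$total_pmol))
  invisible(x)
}
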