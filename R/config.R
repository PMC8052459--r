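#' Default model configuration
#'
#' Returns the full configuration of the reduced climate--ocean model as a
#' nested list: the emission scenario shape, the energy-balance climate
#' parameters, the box geometry and transport, air--sea exchange constants,
#' and the biogeochemical parameters.  The shipped defaults are calibrated so
#' that the coupled zero-emission run reproduces the headline state of the
#' reference simulation: atmospheric pCO2 of about 411 uatm and a surface air
#' temperature anomaly near 1 degree C at the end of 2020, a realized oxygen
#' loss of about 5 Pmol by 2020 and a total loss of about 20 Pmol by 2650, a
#' roughly 30 percent solubility share of the loss, and the bulk of the
#' committed loss below 2000 m.
#'
#' The same structure can be serialised to and read from YAML with
#' [write_config()] / [load_config()]; a copy of the calibrated default is
#' shipped at `system.file("extdata", "default_config.yaml", package =
#' "o2commit")`.
#'
#' @return A nested named list with blocks `scenario`, `climate`, `ocean`,
#'   `geometry`, `transport`, `gas`, `biogeochem`, and `diagnostics`.
#' @export
#' @examples
#' cfg <- default_config()
#' names(cfg)
default_config <- function() {
  list(
    scenario = list(
      start_year = 1765,
      stop_year = 2020,
      end_year = 3000,
      evaluation_year = 2650,
      baseline_year = 1770,
      spinup_years = 10000,
      spinup_check_interval = 500,
      # drift tolerance on the O2 inventory, Pmol per year
      drift_tol_pmol_yr = 5e-4,
      # idealized emission curve: E(y) = end_rate * exp(growth * (y - stop))
      emission_growth_rate = 0.010,
      emission_end_rate_gtco2 = 40.0,
      # cumulative 1765-2020 emissions implied by the two shape parameters,
      # recorded here for reference (Gt CO2); recomputed in tests
      expected_cumulative_gtco2 = 3709.3
    ),
    climate = list(
      co2_preind_uatm = 278,
      forcing_coeff_w_m2 = 5.35,       # a in a*ln(pCO2/pCO2_pre)
      feedback_w_m2_k = 1.0,          # lambda
      atm_heat_capacity_j_k_m2 = 1e8,  # small: atmosphere + skin layer
      gtc_per_uatm = 2.124,
      land_sink_fraction = 0.58,
      earth_area_m2 = 5.101e14,
      sat_plateau_tol_c = 0.25,
      # surface boxes relax toward T_preind + gamma * SAT anomaly
      surface_restore_years = 0.5,
      surface_warming_factor = list(
        surf_lowlat = 0.92, surf_natl = 1.10,
        surf_npac = 0.92, surf_so = 1.38
      )
    ),
    ocean = list(
      rho_kg_m3 = 1026.5,
      cp_j_kg_k = 3990,
      salinity_psu = 34.7
    ),
    geometry = default_geometry_config(),
    transport = list(
      # overturning response to surface warming
      alpha_so_per_k = 0.46,        # Southern cell slowdown per K of SO anomaly
      amoc_dip_per_k = 0.5,        # initial AMOC weakening per K of NA anomaly
      amoc_recovery_gain = 0.18,    # late AMOC strengthening above baseline
      amoc_integral_scale_k_yr = 200,
      psi_floor_frac = 0.2,
      surface_age_relax_yr = 0.05,
      max_courant = 0.5
    ),
    gas = list(
      piston_o2_m_yr = 1100,
      piston_co2_m_yr = 1200,
      atm_po2_atm = 0.21
    ),
    biogeochem = list(
      stoich = list(
        r_c_p = 112, r_n_p = 16, r_o2_p = 169.6,
        r_no3_p_denit = 119.68, o2_denit_threshold = 5
      ),
      max_uptake_yr = 0.4,
      k_po4 = 0.5,          # mmol P m-3
      q10 = 2.0,
      t_ref_c = 16,
      shoaling_per_k = 0.01, # shift of the shallow remineralization fraction
      # reference vertical remineralization fractions by depth class
      remin_fractions = list(thermo = 0.62, mid = 0.14, deep = 0.15, bottom = 0.09),
      po4_init = 1.48,       # mmol m-3, sets the conserved P inventory
      no3_init = 23,
      dic_init = 2260,       # mmol m-3 initial guess, equilibrated in spin-up
      alk = 2371,            # mmol eq m-3, held fixed
      o2_init = 200,
      metabolic_e0_ev = 0.4
    ),
    diagnostics = list(
      hypoxic_mmol_m3 = 70,
      suboxic_mmol_m3 = 5,
      census_bin_width = 10
    )
  )
}

#' Read / write a model configuration as YAML
#'
#' `load_config()` reads a YAML file and merges it over the calibrated
#' defaults, so a user file only needs the keys it overrides.
#' `write_config()` serialises a configuration list to YAML.
#'
#' @param path Path to a YAML file.
#' @param config A configuration list as returned by [default_config()].
#' @return `load_config()` returns a full configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

#' @rdname load_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# recursive right-biased merge of nested named lists
merge_config <- function(base, over) {
  if (!is.list(base) || !is.list(over)) return(over)
  for (nm in names(over)) {
    base[[nm]] <- if (nm %in% names(base)) merge_config(base[[nm]], over[[nm]]) else over[[nm]]
  }
  base
}

# The default box layout: volumes in m3, depths in m, areas in m2.
# Twelve boxes over four surface regions, three thermocline boxes, two
# mid-depth and three deep/abyssal boxes; total volume 1.3e18 m3.
default_geometry_config <- function() {
  boxes <- list(
    list(box = "surf_lowlat", basin = "Indo-Pacific", latitude_band = "50S-50N",
         depth_top = 0, depth_bottom = 100, volume = 2.45e16, is_surface = TRUE,
         area = 2.45e14, t_preind = 18.0),
    list(box = "surf_natl", basin = "Atlantic", latitude_band = "15N-60N",
         depth_top = 0, depth_bottom = 100, volume = 0.30e16, is_surface = TRUE,
         area = 0.30e14, t_preind = 4.0),
    list(box = "surf_npac", basin = "Indo-Pacific", latitude_band = "15N-60N",
         depth_top = 0, depth_bottom = 100, volume = 0.35e16, is_surface = TRUE,
         area = 0.35e14, t_preind = 6.0),
    list(box = "surf_so", basin = "Southern", latitude_band = "90S-50S",
         depth_top = 0, depth_bottom = 100, volume = 0.50e16, is_surface = TRUE,
         area = 0.50e14, t_preind = 0.8),
    list(box = "thermo_atl", basin = "Atlantic", latitude_band = "50S-50N",
         depth_top = 100, depth_bottom = 1200, volume = 7.5e16, is_surface = FALSE,
         area = NA, t_preind = NA),
    list(box = "thermo_ip", basin = "Indo-Pacific", latitude_band = "50S-50N",
         depth_top = 100, depth_bottom = 1200, volume = 21.0e16, is_surface = FALSE,
         area = NA, t_preind = NA),
    list(box = "thermo_so", basin = "Southern", latitude_band = "90S-50S",
         depth_top = 100, depth_bottom = 1200, volume = 6.0e16, is_surface = FALSE,
         area = NA, t_preind = NA),
    list(box = "mid_atl", basin = "Atlantic", latitude_band = "50S-50N",
         depth_top = 1200, depth_bottom = 2000, volume = 5.5e16, is_surface = FALSE,
         area = NA, t_preind = NA),
    list(box = "mid_ip", basin = "Indo-Pacific", latitude_band = "50S-50N",
         depth_top = 1200, depth_bottom = 2000, volume = 16.0e16, is_surface = FALSE,
         area = NA, t_preind = NA),
    list(box = "deep_atl", basin = "Atlantic", latitude_band = "50S-50N",
         depth_top = 2000, depth_bottom = 4000, volume = 14.0e16, is_surface = FALSE,
         area = NA, t_preind = NA),
    list(box = "deep_ip", basin = "Indo-Pacific", latitude_band = "50S-50N",
         depth_top = 2000, depth_bottom = 4000, volume = 40.0e16, is_surface = FALSE,
         area = NA, t_preind = NA),
    list(box = "bottom_so", basin = "Southern", latitude_band = "90S-50S",
         depth_top = 2000, depth_bottom = 5000, volume = 16.4e16, is_surface = FALSE,
         area = NA, t_preind = NA)
  )
  cells <- list(
    # North Atlantic overturning: subtropical inflow, sinking in the North
    # Atlantic, southward deep flow, return through the Atlantic interior
    list(name = "amoc", psi_sv = 16,
         path = c("surf_lowlat", "surf_natl", "deep_atl", "mid_atl",
                  "thermo_atl", "surf_lowlat")),
    # Southern-sourced abyssal cell: surface Southern Ocean to the abyss,
    # spreading into the deep Indo-Pacific and upwelling back to the surface
    list(name = "so_abyssal", psi_sv = 13,
         path = c("surf_so", "bottom_so", "deep_ip", "mid_ip",
                  "thermo_ip", "thermo_so", "surf_so"))
  )
  mixing <- list(
    list(from = "surf_lowlat", to = "thermo_atl", sv = 9.0),
    list(from = "surf_lowlat", to = "thermo_ip", sv = 30.0),
    list(from = "surf_npac", to = "thermo_ip", sv = 5.0),
    list(from = "surf_npac", to = "surf_lowlat", sv = 1.0),
    list(from = "surf_so", to = "thermo_so", sv = 6.0),
    list(from = "surf_so", to = "bottom_so", sv = 0.5),
    list(from = "thermo_so", to = "thermo_atl", sv = 0.5),
    list(from = "thermo_so", to = "thermo_ip", sv = 4.0),
    list(from = "thermo_so", to = "bottom_so", sv = 1.0),
    list(from = "thermo_atl", to = "mid_atl", sv = 1.0),
    list(from = "mid_atl", to = "deep_atl", sv = 1.0),
    list(from = "thermo_ip", to = "mid_ip", sv = 2.0),
    list(from = "mid_ip", to = "deep_ip", sv = 2.0),
    list(from = "deep_ip", to = "bottom_so", sv = 1.5),
    list(from = "deep_atl", to = "bottom_so", sv = 1.0)
  )
  # surface box feeding each water column and the class of each receiving box
  columns <- list(
    surf_lowlat = list(
      thermo_atl = "thermo", thermo_ip = "thermo",
      mid_atl = "mid", mid_ip = "mid",
      deep_atl = "deep", deep_ip = "deep", bottom_so = "bottom"
    ),
    surf_natl = list(thermo_atl = "thermo", mid_atl = "mid", deep_atl = "deep"),
    surf_npac = list(thermo_ip = "thermo", mid_ip = "mid", deep_ip = "deep"),
    surf_so = list(thermo_so = "thermo", bottom_so = "bottom")
  )
  list(boxes = boxes, cells = cells, mixing = mixing, columns = columns,
       # split of the low-latitude export between Atlantic and Indo-Pacific
       lowlat_atl_share = 0.26)
}
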