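test_that("the spin-up reaches a pre-industrial fixed point", {
  sp <- cached_spinup()
  expect_true(sp$converged)
  expect_lt(sp$drift_pmol_yr, default_config()$scenario$drift_tol_pmol_yr)
  # equilibrium air-sea CO2 flux is near zero
  expect_lt(abs(sp$co2_flux_gtc_yr), 0.02)
  # stepping the equilibrated state further barely moves the inventory
  cfg <- default_config()
  geom <- default_geometry(cfg)
  st <- sp$state
  colfr <- o2commit:::column_fractions(geom, cfg)
  inv0 <- o2commit:::o2_inventory_pmol(st$tr[, "o2"], geom)
  for (k in 1:100) {
    st <- o2commit:::model_year(st, geom, geom$base_op, cfg,
                                pco2_atm = cfg$climate$co2_preind_uatm,
                                emissions_gtco2 = 0, coupled = FALSE,
                                biology = TRUE, colfr = colfr)$state
  }
  inv1 <- o2commit:::o2_inventory_pmol(st$tr[, "o2"], geom)
  expect_lt(abs(inv1 - inv0) / 100, 2 * cfg$scenario$drift_tol_pmol_yr)
})

test_that("equilibrium ideal ages match the linear-solve oracle", {
  sp <- cached_spinup()
  geom <- default_geometry()
  surf <- geom$boxes$is_surface
  oracle <- age_oracle(geom$base_op, surf)
  expect_equal(sp$state$tr[!surf, "age"], oracle[!surf], tolerance = 0.01,
               ignore_attr = TRUE)
})

test_that("phosphorus, carbon and heat budgets close over the full run", {
  run <- cached_run()
  s <- run$series
  # P conservation to round-off
  expect_lt(diff(range(s$total_p_mol)) / s$total_p_mol[1], 1e-10)
  # carbon closure: cumulative emissions = atmosphere + land + ocean
  resid <- s$cum_emissions_gtc - (s$atm_c_gtc + s$land_c_gtc + s$ocean_c_gtc)
  expect_lt(max(abs(resid)) / max(s$cum_emissions_gtc), 1e-6)
  # ocean heat content change equals the time-integrated air-sea heat flux
  expect_equal(s$heat_j[nrow(s)], sum(s$heat_flux_j_yr), tolerance = 1e-9)
  expect_equal(run$heat_flux_cum_j, s$heat_j[nrow(s)], tolerance = 1e-9)
})

test_that("a zero-emission control run stays flat", {
  cfg <- default_config()
  cfg$scenario$end_year <- 2150
  cfg$scenario$evaluation_year <- 2100
  zero <- build_emissions(list(emission_growth_rate = 0.01,
                               emission_end_rate_gtco2 = 0),
                          end_year = 2150)
  run <- run_commitment(cfg, emissions = zero, spinup_state = cached_spinup())
  s <- run$series
  expect_lt(max(abs(s$o2_pmol - s$o2_pmol[1])), 0.3)
  expect_lt(max(abs(s$pco2 - s$pco2[1])), 2)
  expect_lt(max(abs(s$sat_anom)), 0.05)
})

test_that("with biology disabled the abiotic tracer coincides with oxygen", {
  cfg <- default_config()
  cfg$scenario$end_year <- 2100
  cfg$scenario$evaluation_year <- 2090
  sp <- spinup(cfg, biology = FALSE)
  run <- run_commitment(cfg, spinup_state = sp, biology = FALSE)
  i <- seq_len(match(2100, run$series$year))
  expect_lt(max(abs(run$archive[i, , "o2"] - run$archive[i, , "abio_o2"])), 1e-9)
})

test_that("the calibrated run declines monotonically through the committed phase", {
  run <- cached_run()
  s <- run$series
  phase <- s$o2_pmol[s$year >= 1900 & s$year <= 2650]
  expect_true(all(diff(phase) < 0))
  # committed loss more than three times the realized loss
  g <- glance(run)
  expect_gt(g$ratio_committed_realized, 3)
})

test_that("runs are deterministic for identical configuration", {
  run1 <- cached_run()
  run2 <- run_commitment(spinup_state = cached_spinup())
  expect_identical(run1$series, run2$series)
  expect_identical(run1$archive, run2$archive)
  expect_identical(run1$provenance$config_hash, run2$provenance$config_hash)
})

test_that("pre-industrial equilibrium surface boxes sit near oxygen saturation", {
  sp <- cached_spinup()
  geom <- default_geometry()
  surf <- geom$boxes$is_surface
  sat <- o2_saturation(sp$state$tr[surf, "temp"],
                       default_config()$ocean$salinity_psu)
  expect_lt(max(abs(sp$state$tr[surf, "o2"] - sat) / sat), 0.02)
  expect_lt(max(abs(sp$state$tr[surf, "abio_o2"] - sat) / sat), 0.02)
})

test_that("box fields feed the shared diagnostics and CSV writers", {
  run <- cached_run()
  f <- box_field(run, 2020)
  expect_equal(sum(f$volume), sum(run$geometry$boxes$volume))
  cen <- volume_census(f)
  expect_equal(sum(cen$volume), sum(f$volume), tolerance = 1e-9)
  tab <- regional_depth_table(box_field(run, 1770), f)
  glob <- tab$d_o2_tmol[tab$region == "Global Ocean" & tab$depth_class == "all"]
  expect_equal(glob * 1e-3, -glance(run)$realized_pmol, tolerance = 1e-9)

  path <- withr::local_tempfile(fileext = ".csv")
  write_run_csv(run, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_true(all(c("year", "metric", "value") %in% names(back)))
  expect_equal(nrow(back), nrow(run$series) * (ncol(run$series) - 1))
})

test_that("the shipped YAML configuration matches the calibrated defaults", {
  path <- system.file("extdata", "default_config.yaml", package = "o2commit")
  expect_true(nzchar(path))
  cfg <- load_config(path)
  expect_equal(cfg, default_config(), tolerance = 1e-9)
})

test_that("tidy, glance and autoplot methods work on a run", {
  run <- cached_run()
  expect_s3_class(tidy(run), "tbl_df")
  g <- glance(run)
  expect_equal(nrow(g), 1)
  p <- autoplot(run)
  expect_s3_class(p, "ggplot")
  cen <- volume_census(generate_base_field(n_lat = 10, n_depth = 6, seed = 1))
  expect_s3_class(autoplot(cen), "ggplot")
  expect_s3_class(autoplot(generate_base_field(n_lat = 10, n_depth = 6, seed = 1)),
                  "ggplot")
})

test_that("committed deep respiratory tendencies are of order 0.01 mmol/m3/yr", {
  run <- cached_run()
  s <- run$series
  i1 <- match(2020, s$year); i2 <- match(2650, s$year)
  interior <- !run$geometry$boxes$is_surface
  resp <- run$archive[, , "o2"] - run$archive[, , "abio_o2"]
  tend <- (resp[i2, interior] - resp[i1, interior]) / (2650 - 2020)
  expect_lt(max(abs(tend)), 0.1)
  expect_gt(max(abs(tend)), 0.001)
})

test_that("committed metabolic-index decline is driven by oxygen, not warming", {
  run <- cached_run()
  f1 <- box_field(run, 2020)
  f2 <- box_field(run, 2650)
  t_only <- metabolic_index_map(f1, f2, hold_o2 = TRUE)$dphi
  o2_only <- metabolic_index_map(f1, f2, hold_t = TRUE)$dphi
  deep <- f1$depth2000 == "below 2000 m"
  w <- f1$volume[deep]
  expect_lt(abs(sum(t_only[deep] * w) / sum(w)),
            abs(sum(o2_only[deep] * w) / sum(w)))
  # in the Southern-sourced and Indo-Pacific deep boxes individually too
  sel <- f1$box %in% c("deep_ip", "bottom_so")
  expect_true(all(abs(t_only[sel]) < abs(o2_only[sel])))
  # and the full signal is a 10-25% decline there
  full <- metabolic_index_map(f1, f2)$dphi
  expect_true(all(full[sel] < -0.05 & full[sel] > -0.30))
})

test_that("solubility-driven oxygen change mirrors warming box by box", {
  run <- cached_run()
  s <- run$series
  i1 <- match(2020, s$year); i2 <- match(2650, s$year)
  yrs <- (i1 + 1):i2
  d_ab <- sweep(run$archive[yrs, , "abio_o2"], 2, run$archive[i1, , "abio_o2"])
  d_t <- sweep(run$archive[yrs, , "temp"], 2, run$archive[i1, , "temp"])
  mask <- abs(d_t) > 0.005
  expect_gt(mean((d_ab * d_t)[mask] < 0), 0.95)
})

test_that("committed export change stays moderate while warming continues", {
  run <- cached_run()
  g <- glance(run)
  expect_lt(abs(g$export_change_frac), 0.15)
  # ocean mean temperature keeps rising through the committed phase
  expect_gt(g$ocean_mean_t_eval, g$ocean_mean_t_stop)
  # surface air temperature stays within the configured plateau band
  s <- run$series
  post <- s$sat_anom[s$year >= 2020 & s$year <= 2650]
  expect_lt(max(abs(post - post[1])),
            run$config$climate$sat_plateau_tol_c)
})
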