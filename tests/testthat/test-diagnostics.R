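test_that("volume census bins are left-closed, right-open and conserve volume", {
  f <- tibble::tibble(o2 = c(5, 65, 250), volume = c(1, 2, 3) * 1e15)
  cen <- volume_census(f)
  expect_equal(cen$volume[cen$bin_left == 0], 1e15)
  expect_equal(cen$volume[cen$bin_left == 60], 2e15)
  expect_equal(cen$volume[cen$bin_left == 250], 3e15)
  expect_equal(sum(cen$volume), sum(f$volume))
  expect_equal(sum(cen$volume != 0), 3)
  # a value exactly on an edge goes to the upper bin
  cen70 <- volume_census(tibble::tibble(o2 = 70, volume = 1))
  expect_equal(cen70$volume[cen70$bin_left == 70], 1)
  expect_error(volume_census(tibble::tibble(o2 = -1, volume = 1)),
               class = "o2c_domain_error")
  expect_error(volume_census(tibble::tibble(o2 = 1, volume = 0)),
               class = "o2c_domain_error")
})

test_that("threshold volumes use strict inequalities and nest", {
  f <- tibble::tibble(o2 = c(4, 65, 250), volume = c(1, 2, 3) * 1e15)
  tv <- threshold_volumes(f)
  expect_equal(tv$volume[tv$threshold_name == "suboxic"], 1e15)
  expect_equal(tv$volume[tv$threshold_name == "hypoxic"], 3e15)
  # o2 exactly 5 is not suboxic; exactly 70 is not hypoxic
  tv2 <- threshold_volumes(tibble::tibble(o2 = c(5, 70), volume = c(1, 1)))
  expect_equal(tv2$volume, c(1, 0))
  tv3 <- threshold_volumes(tibble::tibble(o2 = c(80, 90), volume = c(1, 1)))
  expect_equal(tv3$volume, c(0, 0))
  # nesting for arbitrary fields, and consistency with a width-5 census
  set.seed(42)
  for (k in 1:20) {
    f <- tibble::tibble(o2 = runif(40, 0, 300), volume = runif(40, 1, 2) * 1e14)
    tv <- threshold_volumes(f)
    expect_lte(tv$volume[tv$threshold_name == "suboxic"],
               tv$volume[tv$threshold_name == "hypoxic"])
    cen5 <- volume_census(f, bin_width = 5)
    expect_equal(tv$volume[tv$threshold_name == "suboxic"],
                 sum(cen5$volume[cen5$bin_right <= 5]), tolerance = 1e-12)
    expect_equal(tv$volume[tv$threshold_name == "hypoxic"],
                 sum(cen5$volume[cen5$bin_right <= 70]), tolerance = 1e-12)
  }
})

test_that("commitment accounting reproduces the worked inventory example", {
  inv <- tibble::tibble(year = c(1770, 2020, 2650),
                        inventory = c(274, 269, 253.7))
  cs <- commitment_summary(inv)
  expect_equal(cs$realized, 5.0, tolerance = 1e-12)
  expect_equal(cs$total, 20.3, tolerance = 1e-12)
  expect_equal(cs$ratio_total_realized, 4.06, tolerance = 1e-12)
  expect_equal(cs$ratio_committed_realized, 3.06, tolerance = 1e-12)
  expect_equal(cs$fraction_realized, 5 / 20.3, tolerance = 1e-12)
  expect_lt(cs$fraction_realized, 0.25)
})

test_that("degenerate and identity commitment cases are flagged", {
  flat <- tibble::tibble(year = c(1770, 2020, 2650), inventory = 100)
  cs <- commitment_summary(flat)
  expect_true(cs$degenerate)
  expect_true(is.nan(cs$ratio_total_realized))
  # committed exactly three times realized gives a fourfold total
  inv <- tibble::tibble(year = c(1770, 2020, 2650), inventory = c(40, 38, 32))
  cs2 <- commitment_summary(inv)
  expect_equal(cs2$ratio_total_realized, 4, tolerance = 1e-12)
  expect_error(commitment_summary(flat[1:2, ]), class = "o2c_parameter_error")
})

test_that("the heat-oxygen ratio recovers a constructed linear relation", {
  heat <- seq(0, 3.6e24, length.out = 30)
  ser <- tibble::tibble(year = seq(1770, 2650, length.out = 30),
                        o2_pmol = 274 - 5.7 * heat * 1e-24,
                        heat_j = heat)
  r <- o2_heat_ratio(ser, window = c(1770, 2650))
  expect_equal(r$slope_nmol_j, 5.7, tolerance = 1e-9)
  expect_lt(r$se_nmol_j, 1e-9)
  expect_equal(r$endpoint_nmol_j, 5.7, tolerance = 1e-9)
  # warming accompanied by an oxygen gain flips the sign
  gain <- ser; gain$o2_pmol <- 274 + 5.7 * heat * 1e-24
  expect_lt(o2_heat_ratio(gain, c(1770, 2650))$slope_nmol_j, 0)
  expect_error(o2_heat_ratio(ser[1:2, ]), class = "o2c_parameter_error")
  const <- ser; const$heat_j <- 0
  expect_error(o2_heat_ratio(const), class = "o2c_parameter_error")
})

test_that("solubility share behaves at its limits", {
  ser <- tibble::tibble(year = c(1770, 2650), o2_pmol = c(274, 253.7),
                        abiotic_pmol = c(274, 268))
  expect_equal(solubility_share(ser), 6 / 20.3, tolerance = 1e-12)
  expect_gt(20.3 / 6, 3); expect_lt(20.3 / 6, 4)
  same <- ser; same$abiotic_pmol <- ser$o2_pmol
  expect_equal(solubility_share(same), 1)
  flat <- ser; flat$o2_pmol <- 274
  expect_error(solubility_share(flat), class = "o2c_parameter_error")
})

test_that("the regional depth table aggregates changes with a global row", {
  f0 <- tibble::tibble(
    region = c("A", "A", "B"), depth_class = c("0-1200 m", ">1200 m", ">1200 m"),
    volume = c(2, 1, 1) * 1e15, o2 = c(200, 150, 100)
  )
  f1 <- f0
  tab0 <- regional_depth_table(f0, f1)
  expect_true(all(tab0$d_o2_tmol == 0))
  # a uniform -1 mmol/m3 over a 1e15 m3 mask is exactly -1 Tmol
  f2 <- f0; f2$o2[2] <- f0$o2[2] - 1
  tab <- regional_depth_table(f0, f2)
  expect_equal(tab$d_o2_tmol[tab$region == "A" & tab$depth_class == ">1200 m"],
               -1, tolerance = 1e-12)
  # regional entries sum to the global row
  f3 <- f0; f3$o2 <- f0$o2 + c(-3, 2, -5)
  tab3 <- regional_depth_table(f0, f3)
  parts <- sum(tab3$d_o2_tmol[tab3$region != "Global Ocean"])
  glob <- tab3$d_o2_tmol[tab3$region == "Global Ocean" & tab3$depth_class == "all"]
  expect_equal(parts, glob, tolerance = 1e-12)
  f_bad <- f0[c(2, 1, 3), ]
  expect_error(regional_depth_table(f0, f_bad), class = "o2c_parameter_error")
})

test_that("the metabolic index change matches its closed form", {
  expect_equal(metabolic_index_change(0.1, 0.1, 283.15, 283.15,
                                      temp_unit = "kelvin"), 0)
  expect_equal(metabolic_index_change(0.05, 0.1, 10, 10), -0.5, tolerance = 1e-12)
  # one degree of warming at constant pO2 with E0 = 0.4 eV
  got <- metabolic_index_change(0.1, 0.1, 276.15, 275.15, temp_unit = "kelvin")
  expect_equal(got, -0.0593, tolerance = 2e-3)
  # independent evaluation of the exponent
  expected <- exp(0.4 / 8.617333e-5 * (1 / 276.15 - 1 / 275.15)) - 1
  expect_equal(got, expected, tolerance = 1e-12)
  # a negative E0 flips the sign of the temperature response
  expect_gt(metabolic_index_change(0.1, 0.1, 276.15, 275.15, e0 = -0.2,
                                   temp_unit = "kelvin"), 0)
  # scale invariance in pO2 units
  a <- metabolic_index_change(0.08, 0.1, 280.15, 278.15, temp_unit = "kelvin")
  b <- metabolic_index_change(0.08 * 37, 0.1 * 37, 280.15, 278.15,
                              temp_unit = "kelvin")
  expect_equal(a, b, tolerance = 1e-12)
  # Celsius inputs are converted internally
  expect_equal(metabolic_index_change(0.1, 0.1, 3, 2),
               metabolic_index_change(0.1, 0.1, 276.15, 275.15,
                                      temp_unit = "kelvin"), tolerance = 1e-12)
  expect_error(metabolic_index_change(0.1, 0, 280, 280, temp_unit = "kelvin"),
               class = "o2c_domain_error")
  expect_error(metabolic_index_change(0.1, 0.1, -5, 280, temp_unit = "kelvin"),
               class = "o2c_domain_error")
})
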