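stoich <- default_config()$biogeochem$stoich
bg <- default_config()$biogeochem

test_that("aerobic remineralization follows the fixed stoichiometry exactly", {
  v <- 1e15
  rem <- remineralize(1, o2 = 200, no3 = 30, volume = v, stoich = stoich)
  expect_identical(rem$p_remin, 1)
  expect_equal(rem$d_o2 * v / 1e3, -169.6)
  expect_equal(rem$d_no3 * v / 1e3, 16)
  expect_equal(rem$d_dic * v / 1e3, 112)
  expect_equal(rem$d_po4 * v / 1e3, 1)
  # Redfield ratios hold exactly for any aerobic event
  expect_identical(rem$d_dic / rem$d_po4, 112)
  expect_identical(rem$d_no3 / rem$d_po4, 16)
})

test_that("denitrification engages strictly below 5 mmol/m3 with net 119.68 NO3 per P", {
  v <- 1e15
  rem <- remineralize(1, o2 = 3, no3 = 30, volume = v, stoich = stoich)
  expect_equal(rem$d_o2, 0)
  expect_equal(rem$d_no3 * v / 1e3, -119.68)
  expect_equal(rem$d_po4 * v / 1e3, 1)
  # exactly at the threshold the aerobic pathway still runs
  rem_at <- remineralize(1, o2 = 5, no3 = 30, volume = v, stoich = stoich)
  expect_lt(rem_at$d_o2, 0)
  expect_gt(rem_at$d_no3, 0)
  # just below, it does not
  rem_below <- remineralize(1, o2 = 5 - 1e-9, no3 = 30, volume = v, stoich = stoich)
  expect_equal(rem_below$d_o2, 0)
})

test_that("remineralization halts when nitrate runs out and forwards the flux", {
  v <- 1e15
  rem <- remineralize(1, o2 = 3, no3 = 0, volume = v, stoich = stoich)
  expect_equal(rem$p_remin, 0)
  expect_equal(rem$p_residual, 1)
  expect_equal(rem$d_o2, 0)
  expect_equal(rem$d_no3, 0)
  expect_equal(rem$d_po4, 0)
})

test_that("oxygen and nitrate are never overdrawn; the remainder is forwarded", {
  v <- 1e12
  o2 <- 100 # amount = 1e11 mol O2 -> supports ~5.9e8 mol P
  rem <- remineralize(1e9, o2 = o2, no3 = 30, volume = v, stoich = stoich)
  expect_equal(rem$p_remin, o2 * 1e-3 * v / 169.6, tolerance = 1e-12)
  expect_equal(o2 + rem$d_o2, 0, tolerance = 1e-10)
  expect_equal(rem$p_remin + rem$p_residual, 1e9, tolerance = 1e-12)
  expect_error(remineralize(-1, 100, 30, v, stoich), class = "o2c_parameter_error")
})

test_that("export production is Michaelis-Menten in PO4 with a Q10 factor", {
  v <- 1e16
  expect_equal(export_production(0, 16, bg, v), 0)
  # at PO4 = K the uptake runs at half its maximal rate
  f_half <- export_production(bg$k_po4, bg$t_ref_c, bg, v)
  expect_equal(f_half, 0.5 * bg$max_uptake_yr * bg$k_po4 * 1e-3 * v)
  # Q10: +10 C doubles the rate at q10 = 2
  f_warm <- export_production(bg$k_po4, bg$t_ref_c + 10, bg, v)
  expect_equal(f_warm / f_half, bg$q10)
  # flux is limited to the available phosphate when a step is supplied
  expect_warning(
    f_cap <- export_production(5, 40, c(bg, list()), v, dt = 100),
    "limited"
  )
  expect_equal(f_cap, 5 * 1e-3 * v / 100)
})

test_that("vertical partitioning shoals with warming and conserves the flux", {
  fr <- c(thermo = 0.62, mid = 0.14, deep = 0.15, bottom = 0.09)
  ref <- vertical_partition(1, fr, delta_t = 0, shoaling_per_k = 0.01)
  expect_equal(unname(ref), unname(fr))
  warm <- vertical_partition(1, fr, delta_t = 1, shoaling_per_k = 0.01)
  expect_gt(warm[["thermo"]], ref[["thermo"]])
  expect_true(all(warm[c("mid", "deep", "bottom")] < ref[c("mid", "deep", "bottom")]))
  expect_equal(sum(warm), 1, tolerance = 1e-12)
  set.seed(1)
  for (k in 1:20) {
    flux <- runif(1, 0, 1e12)
    dt <- runif(1, -3, 3)
    out <- vertical_partition(flux, fr, dt, 0.02)
    expect_equal(sum(out), flux, tolerance = 1e-9 * max(flux, 1))
    expect_true(all(out >= 0))
  }
  expect_warning(vertical_partition(1, c(a = 0.9, b = 0.1), 100, 0.5), "clipped")
  expect_error(vertical_partition(1, c(a = 0.5, b = 0.2), 0, 0),
               class = "o2c_parameter_error")
})

test_that("phosphorus is conserved through export, partition and remineralization", {
  fr <- c(thermo = 0.62, mid = 0.14, deep = 0.15, bottom = 0.09)
  flux <- export_production(0.8, 18, bg, 2e16)
  parts <- vertical_partition(flux, fr, 0.5, bg$shoaling_per_k)
  total_back <- 0
  for (p in parts) {
    rem <- remineralize(p, o2 = 150, no3 = 25, volume = 5e16, stoich = stoich)
    total_back <- total_back + rem$p_remin + rem$p_residual
  }
  expect_equal(total_back, flux, tolerance = 1e-9 * flux)
})
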