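test_that("Gibbs-Thomson diameter matches direct substitution of the constants", {
  p <- gibbs_thomson_params()
  # 5 K depression: 4 * 273.15 * 0.0121 / (5 * 3.34e8) m = 7.917 nm
  expect_equal(gibbs_thomson_diameter(268.15, p), 7.917, tolerance = 1e-3)
  expect_equal(gibbs_thomson_temperature(7, p), 267.495, tolerance = 1e-3)
  expect_equal(gibbs_thomson_temperature(17, p) - 273.15, -2.328,
               tolerance = 1e-3)
  expect_error(gibbs_thomson_diameter(274, p), "below T0")
  expect_error(gibbs_thomson_diameter(273.15, p), "below T0")
  expect_error(gibbs_thomson_temperature(0, p), "positive")
})

test_that("D |dT| is constant and the inverse is exact (property sweep)", {
  p <- gibbs_thomson_params()
  const <- 4 * p$T0_K * p$gamma_mJ_m2 * 1e-3 /
    (p$rho_kg_m3 * p$Hf_J_g * 1000) * 1e9
  Tm <- withr::with_seed(1, stats::runif(500, 223, 273.14))
  D <- gibbs_thomson_diameter(Tm, p)
  expect_true(all(D > 0))
  expect_equal(D * (p$T0_K - Tm), rep(const, 500), tolerance = 1e-12)
  # monotone increasing in Tm
  ord <- order(Tm)
  expect_true(all(diff(D[ord]) > 0))
  # round trip at decades of pore size
  for (d in c(1, 10, 100)) {
    expect_equal(gibbs_thomson_diameter(gibbs_thomson_temperature(d, p), p),
                 d, tolerance = 1e-10)
  }
})

test_that("calibration offset is measured melting point minus T0", {
  expect_equal(calibration_offset(272.90), -0.25)
  expect_equal(calibration_offset(273.15), 0)
})

test_that("isotherm segmentation recovers planted step enthalpies within 1%", {
  p <- gibbs_thomson_params()
  proto <- default_thermo_protocol(p)
  expect_equal(proto[1:2], c(-5.655, -2.328), tolerance = 1e-3)
  tr <- dsc_truth(bins = data.frame(d_lo_nm = c(0, 7), d_hi_nm = c(7, 17),
                                    mass_mg = c(2, 3)),
                  bulk_water_mg = 5, nonfreezing_water_mg = 0, seed = 11L)
  trace <- synth_dsc_trace(tr, proto, p)
  steps <- segment_isotherms(trace, proto)
  # planted per-step enthalpies in J per g wet sample
  planted <- c(2, 3, 5) / 1000 * p$Hf_J_g / (trace$mass_wet_mg / 1000)
  expect_equal(steps$enthalpy_J_g, planted, tolerance = 0.01)
  # a zero-heat-flow trace yields zero enthalpy at every step
  flat <- dsc_trace(trace$data$time_s, trace$data$temp_C,
                    rep(0, nrow(trace$data)), trace$mass_wet_mg,
                    trace$mass_dry_mg)
  expect_true(all(segment_isotherms(flat, proto)$enthalpy_J_g == 0))
  # a never-reached protocol temperature is a protocol error
  expect_error(segment_isotherms(trace, c(proto, 40)), "never reached")
})

test_that("pore partition follows the enthalpy/Hf mass arithmetic", {
  # one step, 0.334 J total at 10 mg of water: 1 mg melted = 10%
  p <- gibbs_thomson_params()
  steps <- structure(data.frame(T_set_C = -5, T_set_K = 268.15,
                                enthalpy_J_g = 0.334 / (13 / 1000)),
                     class = c("isotherm_steps", "data.frame"))
  trace <- dsc_trace(0:10, rep(-5, 11), rep(0, 11),
                     mass_wet_mg = 13, mass_dry_mg = 3)
  pd <- pore_distribution(steps, trace, p)
  expect_equal(pd$bins$freezing_water_ratio, 10, tolerance = 1e-9)
  expect_equal(pd$bins$d_hi_nm, gibbs_thomson_diameter(268.15, p))
  expect_equal(pd$nonfreezing_pct, 90, tolerance = 1e-9)
  # melted mass exceeding total water is a mass-balance error
  steps_bad <- steps; steps_bad$enthalpy_J_g <- 0.334 * 40 / (13 / 1000)
  expect_error(pore_distribution(steps_bad, trace, p), "exceeds total water")
})

test_that("planted bin fractions are recovered and everything sums to 100%", {
  p <- gibbs_thomson_params()
  proto <- default_thermo_protocol(p)
  tr <- dsc_truth(bins = data.frame(d_lo_nm = c(0, 7), d_hi_nm = c(7, 17),
                                    mass_mg = c(2, 3)),
                  bulk_water_mg = 5, nonfreezing_water_mg = 0,
                  mass_dry_mg = 3, seed = 11L)
  trace <- synth_dsc_trace(tr, proto, p)
  pd <- pore_distribution(segment_isotherms(trace, proto), trace, p)
  expect_equal(pd$bins$freezing_water_ratio, c(20, 30), tolerance = 0.1)
  expect_equal(pd$bulk_pct, 50, tolerance = 0.12)
  expect_equal(sum(pd$bins$freezing_water_ratio) + pd$bulk_pct +
                 pd$nonfreezing_pct, 100, tolerance = 1e-9)
  # bin edges from ascending isotherms are strictly increasing
  expect_true(all(diff(c(pd$bins$d_lo_nm[1], pd$bins$d_hi_nm)) > 0))
})

test_that("the calibration offset shifts the computed bin edges", {
  p <- gibbs_thomson_params()
  steps <- structure(data.frame(T_set_C = c(-5.655, -2.328),
                                T_set_K = c(-5.655, -2.328) + 273.15,
                                enthalpy_J_g = c(1, 1)),
                     class = c("isotherm_steps", "data.frame"))
  trace <- dsc_trace(0:10, rep(0, 11), rep(0, 11), 13, 3)
  pd0 <- pore_distribution(steps, trace, p, calibration_offset_K = 0)
  pd1 <- pore_distribution(steps, trace, p, calibration_offset_K = -0.25)
  expect_equal(pd1$bins$d_hi_nm,
               gibbs_thomson_diameter(steps$T_set_K - 0.25, p))
  expect_true(all(pd1$bins$d_hi_nm < pd0$bins$d_hi_nm))
})

test_that("trace containers validate their inputs", {
  expect_error(dsc_trace(c(0, 1, 1), rep(0, 3), rep(0, 3), 10, 3),
               "strictly increasing")
  expect_error(dsc_trace(0:2, rep(0, 3), rep(0, 3), 3, 10), "mass_wet")
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_s = 0:5, temp_C = 0, heatflow_mW = 0),
                   path, row.names = FALSE)
  expect_error(read_dsc_trace(path, list(mass_wet_mg = 10)), "mass_dry_mg")
  tr <- read_dsc_trace(path, list(mass_wet_mg = 10, mass_dry_mg = 4))
  expect_s3_class(tr, "dsc_trace")
  expect_equal(tr$mass_dry_mg, 4)
})
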