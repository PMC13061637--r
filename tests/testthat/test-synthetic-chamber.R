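quiet_cfg <- function(...) {
  chamber_sim_config(dop_true = 0, scoc_true = 0, noise_sd = 0,
                     drift_rate = 0, initial_o2_sd = 0,
                     syringe_times = numeric(), ...)
}

test_that("a zero-rate, zero-noise chamber stays at its initial value", {
  sim <- simulate_chamber_series(quiet_cfg(seed = 3))
  expect_equal(unique(sim$series$o2_umol_l), 185.2)
  expect_equal(nrow(sim$series), 47 * 360 + 1)
})

test_that("identical seed and config give bit-identical series", {
  cfg <- chamber_sim_config(seed = 11)
  a <- simulate_chamber_series(cfg)
  b <- simulate_chamber_series(cfg)
  expect_identical(a$series$o2_umol_l, b$series$o2_umol_l)
  c <- simulate_chamber_series(chamber_sim_config(seed = 12))
  expect_false(identical(a$series$o2_umol_l, c$series$o2_umol_l))
})

test_that("undamped net rate converts to the hand-derived concentration slope", {
  # 5 mmol m-2 d-1 over 10 cm of water is 50 umol l-1 d-1
  cfg <- chamber_sim_config(dop_true = 5, scoc_true = 0, saturation_shape = 0,
                            noise_sd = 0, drift_rate = 0, initial_o2_sd = 0,
                            syringe_times = numeric(), stir_off_interval = 0,
                            chamber_area = 484, water_depth = 10, seed = 1)
  sim <- simulate_chamber_series(cfg)
  s <- sim$series
  slope_d <- coef(lm(o2_umol_l ~ I(time_h / 24), data = s))[[2]]
  expect_equal(slope_d, 50, tolerance = 1e-9)
})

test_that("the series is flat during the stirrer-off window only", {
  cfg <- chamber_sim_config(dop_true = 5, scoc_true = 0, saturation_shape = 0,
                            noise_sd = 0, drift_rate = 0, initial_o2_sd = 0,
                            syringe_times = numeric(), stir_off_interval = 2,
                            seed = 1)
  s <- simulate_chamber_series(cfg)$series
  off <- s$time_h <= 2
  expect_equal(max(abs(diff(s$o2_umol_l[off]))), 0)
  expect_true(all(diff(s$o2_umol_l[!off]) > 0))
})

test_that("the production maximum matches the generating integral", {
  # damped production starting from 185.2 reaching a max inside the
  # field-observed 201-819 umol l-1 envelope over 47 h
  cfg <- chamber_sim_config(noise_sd = 0, drift_rate = 0, initial_o2_sd = 0,
                            seed = 5)
  sim <- simulate_chamber_series(cfg)
  no_dil <- simulate_chamber_series(
    chamber_sim_config(noise_sd = 0, drift_rate = 0, initial_o2_sd = 0,
                       syringe_times = numeric(), seed = 5))
  expect_gt(no_dil$truth$clean_max, 201)
  expect_lt(no_dil$truth$clean_max, 819)
  expect_lt(abs((no_dil$truth$clean_max - no_dil$truth$initial_o2) -
                  no_dil$truth$integrated_net_umol_l), 0.1)
  expect_equal(sim$truth$initial_o2, 185.2)
})

test_that("dilution dips have exactly the mass-balance magnitude", {
  cfg <- chamber_sim_config(dop_true = 5, scoc_true = 0, saturation_shape = 0,
                            noise_sd = 0, drift_rate = 0, initial_o2_sd = 0,
                            syringe_times = c(28, 38), seed = 2)
  s <- simulate_chamber_series(cfg)$series
  v <- cfg$chamber_area * cfg$water_depth / 1000
  for (te in c(28, 38)) {
    i <- which(s$time_h == te)
    c_before_expected <- s$o2_umol_l[i - 1] +
      diff(s$o2_umol_l[(i - 2):(i - 1)]) # linear extrapolation to te
    step_expected <- (cfg$syringe_volume / 1000 / v) *
      (c_before_expected - cfg$ambient_o2)
    observed_drop <- c_before_expected - s$o2_umol_l[i]
    expect_equal(observed_drop, step_expected, tolerance = 1e-9)
  }
})

test_that("logging gaps remove samples without interpolation", {
  cfg <- quiet_cfg(gap_intervals = list(c(10, 12)), seed = 4)
  s <- simulate_chamber_series(cfg)$series
  expect_false(any(s$time_h >= 10 & s$time_h <= 12))
  expect_equal(nrow(s), (47 * 360 + 1) - sum(seq(0, 47, by = 10 / 3600) >= 10 &
                                               seq(0, 47, by = 10 / 3600) <= 12))
})

test_that("configs driving concentrations negative are rejected", {
  cfg <- chamber_sim_config(dop_true = 0, scoc_true = 200, saturation_shape = 0,
                            noise_sd = 0, drift_rate = 0, initial_o2_sd = 0,
                            syringe_times = numeric(), seed = 1)
  expect_error(simulate_chamber_series(cfg), "infeasible")
  expect_error(chamber_sim_config(syringe_volume = 1e6), "syringe_volume")
})
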