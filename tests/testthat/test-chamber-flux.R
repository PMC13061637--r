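flat_series <- function(value = 185.2, hours = 47) {
  s <- data.frame(time_h = seq(0, hours, by = 1 / 6))
  s$time_s <- s$time_h * 3600
  s$o2_umol_l <- value
  class(s) <- c("optode_series", "data.frame")
  s
}

test_that("schedule alignment re-zeroes time and flags segments", {
  s <- flat_series()
  s$time_h <- s$time_h + 1.5 # lander clock ahead of sealing
  al <- align_schedule(s, list(seal_h = 1.5, stir_off = c(0, 1),
                               syringe_times_h = c(28, 38, 47)))
  expect_equal(min(al$time_h), 0)
  expect_true(all(al$sealed))
  expect_false(any(al$stirred[al$time_h < 1]))
  expect_true(all(al$stirred[al$time_h >= 1]))
  ev <- attr(al, "events")
  expect_equal(ev$time_h[ev$event == "syringe"], c(28, 38, 47))
  expect_error(align_schedule(s, list(seal_h = 1000)), "outside")
})

test_that("flat series classify as neutral with zero change", {
  fr <- net_o2_change(flat_series(), chamber_experiment("flat", water_depth = 10))
  expect_equal(fr$delta_c, 0)
  expect_equal(fr$total_net_o2, 0)
  expect_equal(fr$classification, "neutral")
})

test_that("total net O2 follows delta-c times volume", {
  s <- flat_series(185.2)
  s$o2_umol_l <- 185.2 + (819 - 185.2) * s$time_h / 47
  # 2.0 l chamber: depth such that 484 cm2 * d / 1000 = 2 l
  exp2l <- chamber_experiment("v2", chamber_area = 484,
                              water_depth = 2000 / 484)
  fr <- net_o2_change(s, exp2l, initial_window_min = 0)
  expect_equal(fr$delta_c, 819 - 185.2, tolerance = 1e-9)
  expect_equal(fr$total_net_o2, 633.8 * 2.0, tolerance = 1e-6)
  # linear scaling with volume at fixed concentrations
  exp4l <- chamber_experiment("v4", chamber_area = 484,
                              water_depth = 4000 / 484)
  fr4 <- net_o2_change(s, exp4l, initial_window_min = 0)
  expect_equal(fr4$total_net_o2, 2 * fr$total_net_o2, tolerance = 1e-9)
})

test_that("volume-unknown chambers return flagged concentration-only results", {
  s <- flat_series()
  s$o2_umol_l <- 185.2 + s$time_h
  fr <- net_o2_change(s, chamber_experiment("nodoor", water_depth = NA))
  expect_false(fr$volume_known)
  expect_true(is.na(fr$total_net_o2))
  expect_true(is.na(fr$dop_rate))
  expect_false(is.na(fr$delta_c))
})

test_that("noise-free generator round trip recovers the net rate exactly", {
  cfg <- chamber_sim_config(dop_true = 5, scoc_true = 0, saturation_shape = 0,
                            noise_sd = 0, drift_rate = 0, initial_o2_sd = 0,
                            seed = 7)
  sim <- simulate_chamber_series(cfg)
  ser <- correct_dilution(sim$series, cfg$syringe_times,
                          sim$truth$water_volume_l, cfg$syringe_volume,
                          cfg$ambient_o2)
  fr <- net_o2_change(ser, chamber_experiment("rt", water_depth = 10))
  expect_equal(fr$dop_rate, 5, tolerance = 1e-9)
  expect_equal(fr$classification, "net producer")
})

test_that("dilution correction inverts the generator and composes over events", {
  cfg <- chamber_sim_config(dop_true = 5, scoc_true = 0, saturation_shape = 0,
                            noise_sd = 0, drift_rate = 0, initial_o2_sd = 0,
                            seed = 7)
  diluted <- simulate_chamber_series(cfg)
  undiluted <- simulate_chamber_series(
    chamber_sim_config(dop_true = 5, scoc_true = 0, saturation_shape = 0,
                       noise_sd = 0, drift_rate = 0, initial_o2_sd = 0,
                       syringe_times = numeric(), seed = 7))
  corrected <- correct_dilution(diluted$series, cfg$syringe_times,
                                diluted$truth$water_volume_l,
                                cfg$syringe_volume, cfg$ambient_o2)
  expect_equal(corrected$o2_umol_l, undiluted$series$o2_umol_l,
               tolerance = 1e-12)
  # ambient below chamber concentration: correction only raises values
  expect_gte(max(corrected$o2_umol_l), max(diluted$series$o2_umol_l))
  # ambient equal to the chamber concentration: correction is the identity
  quiet <- simulate_chamber_series(
    chamber_sim_config(dop_true = 0, scoc_true = 0, noise_sd = 0,
                       drift_rate = 0, initial_o2_sd = 0, seed = 3))
  same <- correct_dilution(quiet$series, c(28, 38), quiet$truth$water_volume_l,
                           50, ambient_o2 = 185.2)
  expect_equal(same$o2_umol_l, quiet$series$o2_umol_l, tolerance = 1e-12)
  expect_error(correct_dilution(quiet$series, 28, 4.84, 50, NULL), "ambient")
})

test_that("hand-derived mass balance: 400 umol/l diluted in a 2 l chamber", {
  # V = 2 l, v = 50 ml, ambient 185: C_after = (400*1.95 + 185*0.05)/2
  s <- data.frame(time_h = c(0, 1, 2, 3), o2_umol_l = c(400, 400, 394.625, 394.625))
  out <- correct_dilution(s, events = 2, water_volume = 2, syringe_volume = 50,
                          ambient_o2 = 185)
  expect_equal((400 * 1.95 + 185 * 0.05) / 2, 394.625)
  expect_equal(out$o2_umol_l, rep(400, 4), tolerance = 1e-12)
})

test_that("declining series yield positive SCOC with the hand unit conversion", {
  s <- flat_series(hours = 40)
  s$o2_umol_l <- 250 - 10 * s$time_h / 24 # -10 umol l-1 d-1
  scoc <- scoc_from_decline(s, chamber_experiment("c", water_depth = 10))
  expect_equal(scoc, 1.0, tolerance = 1e-9)
  expect_error(scoc_from_decline(flat_series(),
                                 chamber_experiment("f", water_depth = 10)),
               "no decline")
  # round trip against a consumption-only generator config
  cfg <- chamber_sim_config(dop_true = 0, scoc_true = 0.7, saturation_shape = 0,
                            noise_sd = 0, drift_rate = 0, initial_o2_sd = 0,
                            syringe_times = numeric(), stir_off_interval = 0,
                            seed = 2)
  sim <- simulate_chamber_series(cfg)
  expect_equal(scoc_from_decline(sim$series,
                                 chamber_experiment("s", water_depth = 10)),
               0.7, tolerance = 1e-9)
})

test_that("nodule densities convert chamber counts to per-square-metre", {
  expect_equal(nodule_density(0)$mean, 0)
  expect_equal(nodule_density(57)$mean, 57 / 0.0484, tolerance = 1e-12)
  nd <- nodule_density(c(50, 57, 62))
  expect_equal(nd$mean, mean(c(50, 57, 62) / 0.0484))
  expect_equal(nd$se, sd(c(50, 57, 62) / 0.0484) / sqrt(3))
  expect_error(nodule_density(5, chamber_area = 0), "positive")
})
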