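test_that("two-point calibration is exact at its own calibration points", {
  cal <- make_affine_calibration(temps = c(1.2, 7, 18, 30))
  model <- fit_two_point(cal$points, pressure_coeff = 0)
  for (i in seq_along(cal$temps)) {
    raw <- data.frame(
      time_s = c(0, 10),
      raw = c(cal$a, cal$a + cal$b * cal$ref100[i]),
      temp_c = cal$temps[i]
    )
    out <- apply_calibration(raw, model)
    expect_equal(out$o2_umol_l, c(0, cal$ref100[i]), tolerance = 1e-12)
  }
})

test_that("generating affine coefficients are recovered to 1e-10", {
  cal <- make_affine_calibration(a = 3.7, b = 0.0123)
  model <- fit_two_point(cal$points)
  expect_equal(model$raw0, rep(3.7, 4), tolerance = 1e-10)
  expect_equal(model$gain, rep(1 / 0.0123, 4), tolerance = 1e-10)
  expect_equal(model$temperature, c(1.2, 7, 18, 30))
})

test_that("calibration validation catches missing levels and bad gains", {
  cal <- make_affine_calibration()
  expect_error(fit_two_point(cal$points[cal$points$saturation_level == 1, ]),
               "lacks")
  expect_error(fit_two_point(cal$points[cal$points$temperature == 1.2, ]),
               ">= 2 temperatures")
  flipped <- cal$points
  flipped$raw_reading[flipped$saturation_level == 1] <- 0 # below the 0% reading
  expect_error(fit_two_point(flipped), "gain")
})

test_that("pressure correction is multiplicative and vanishes at P = 0", {
  cal <- make_affine_calibration()
  model <- fit_two_point(cal$points, pressure_coeff = 0.032)
  raw <- data.frame(time_s = 0, raw = cal$a + cal$b * 200, temp_c = 7,
                    pressure_dbar = 4000)
  out <- apply_calibration(raw, model)
  raw0 <- transform(raw, pressure_dbar = 0)
  out0 <- apply_calibration(raw0, model)
  expect_equal(out$o2_umol_l, out0$o2_umol_l * (1 + 0.032 * 4), tolerance = 1e-12)
  expect_equal(out$o2_umol_l / out0$o2_umol_l, 1.128, tolerance = 1e-12)
  expect_error(apply_calibration(raw[setdiff(names(raw), "pressure_dbar")],
                                 model), "pressure_dbar")
})

test_that("drift correction applies rate times elapsed days when enabled", {
  cal <- make_affine_calibration()
  model <- fit_two_point(cal$points, pressure_coeff = 0, drift_rate = 0.27,
                         calibration_epoch = 0)
  raw <- data.frame(time_s = 0, raw = cal$a + cal$b * 200, temp_c = 7)
  off <- apply_calibration(raw, model, drift_correction = FALSE)
  on <- apply_calibration(raw, model, drift_correction = TRUE,
                          time_origin_days = 10)
  expect_equal(off$o2_umol_l - on$o2_umol_l, 2.7, tolerance = 1e-12)
})

test_that("series temperatures outside the calibrated range are rejected", {
  cal <- make_affine_calibration()
  model <- fit_two_point(cal$points, pressure_coeff = 0)
  raw <- data.frame(time_s = 0, raw = 5, temp_c = 35)
  expect_error(apply_calibration(raw, model), "outside the calibrated range")
})

test_that("drift estimation returns zero for identical calibrations and the
           offset fixture rate otherwise", {
  cal <- make_affine_calibration()
  pre <- fit_two_point(cal$points)
  expect_equal(estimate_drift(pre, pre, elapsed_days = 42), 0)

  # post-cruise calibration whose readings imply +11.34 umol l-1 at the
  # reference condition after 42 d: drift must be 11.34 / 42 = 0.27
  shifted <- cal$points
  is100 <- shifted$saturation_level == 1
  # lower the 100% raw reading so a fixed raw input maps to a higher
  # concentration under the post calibration
  gain_post <- (cal$ref100 + 11.34) / (cal$ref100 * cal$b) # target gain per temp
  shifted$raw_reading[is100] <- cal$a + cal$ref100 / gain_post
  post <- fit_two_point(shifted)
  ref <- data.frame(raw = cal$a + cal$b * cal$ref100, temp_c = cal$temps)
  drift <- estimate_drift(pre, post, elapsed_days = 42, reference = ref)
  expect_equal(drift, 11.34 / 42, tolerance = 1e-9)
  expect_equal(drift, 0.27, tolerance = 1e-9)
  # sign convention: the post calibration reading higher means positive drift
  expect_gt(drift, 0)
  expect_error(estimate_drift(pre, post, elapsed_days = 0), "elapsed")
})
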