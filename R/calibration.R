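#' Build a two-point, multi-temperature calibration table
#'
#' One row per (temperature, saturation level): raw sensor reading against the
#' reference concentration (0 for the 0% bath; the air-saturation solubility
#' at the bath temperature and salinity for the 100% bath).
#'
#' @param temperature bath temperature, deg C
#' @param saturation_level 0 or 1
#' @param raw_reading sensor units
#' @param reference_o2 reference concentration, umol l-1; defaults to 0 for
#'   the 0% level and to [o2_saturation_concentration()] at `salinity` for the
#'   100% level
#' @param salinity bath salinity used for the default 100% reference
#' @return data.frame of calibration points
#' @export
calibration_points <- function(temperature, saturation_level, raw_reading,
                               reference_o2 = NULL, salinity = 35) {
  stopifnot(length(temperature) == length(saturation_level),
            length(temperature) == length(raw_reading))
  if (!all(saturation_level %in% c(0, 1)))
    stop("saturation_level must be 0 or 1")
  if (is.null(reference_o2)) {
    reference_o2 <- ifelse(
      saturation_level == 0, 0,
      o2_saturation_concentration(temperature, salinity)
    )
  }
  if (any((reference_o2 == 0) != (saturation_level == 0)))
    stop("reference_o2 must be 0 exactly for (and only for) the 0% level")
  data.frame(
    temperature = temperature, saturation_level = saturation_level,
    raw_reading = raw_reading, reference_o2 = reference_o2
  )
}

#' Fit a two-point multi-temperature optode calibration
#'
#' At each calibration temperature the raw-to-concentration map is affine and
#' exact at both points: the 0% reading maps to 0 and the 100% reading to its
#' reference solubility. Coefficients are interpolated linearly in temperature
#' when the model is applied. This affine abstraction preserves the two-point
#' calibration contract without the proprietary optode transfer function.
#'
#' @param points data.frame from [calibration_points()]
#' @param pressure_coeff multiplicative pressure correction, fraction per
#'   1000 dbar (default 0.032)
#' @param drift_rate sensor drift, umol l-1 d-1 (default 0; drift correction
#'   is off by default downstream)
#' @param calibration_epoch days-since-origin timestamp of the calibration
#' @return object of class `calibration_model`: per-temperature `raw0` (0%
#'   reading) and `gain` (umol l-1 per sensor unit), plus correction settings
#' @export
fit_two_point <- function(points, pressure_coeff = 0.032, drift_rate = 0,
                          calibration_epoch = 0) {
  req <- c("temperature", "saturation_level", "raw_reading", "reference_o2")
  stopifnot(all(req %in% names(points)))
  temps <- sort(unique(points$temperature))
  if (length(temps) < 2)
    stop("need calibration points at >= 2 temperatures")
  coefs <- lapply(temps, function(tt) {
    p <- points[points$temperature == tt, ]
    p0 <- p[p$saturation_level == 0, ]
    p1 <- p[p$saturation_level == 1, ]
    if (nrow(p0) < 1 || nrow(p1) < 1)
      stop(sprintf("temperature %g lacks a 0%% or 100%% point", tt))
    if (nrow(unique(p0[c("raw_reading")])) > 1 ||
        nrow(unique(p1[c("raw_reading", "reference_o2")])) > 1)
      stop(sprintf("conflicting duplicate points at temperature %g", tt))
    raw0 <- p0$raw_reading[1]
    gain <- p1$reference_o2[1] / (p1$raw_reading[1] - raw0)
    if (!is.finite(gain) || gain <= 0)
      stop(sprintf("non-positive gain at temperature %g", tt))
    c(raw0 = raw0, gain = gain)
  })
  model <- list(
    temperature = temps,
    raw0 = vapply(coefs, `[[`, numeric(1), "raw0"),
    gain = vapply(coefs, `[[`, numeric(1), "gain"),
    interpolation = "linear",
    pressure_coeff = pressure_coeff,
    drift_rate = drift_rate,
    calibration_epoch = calibration_epoch
  )
  structure(model, class = "calibration_model")
}

interp_coef <- function(model, temperature) {
  rng <- range(model$temperature)
  if (any(temperature < rng[1] - 1e-9 | temperature > rng[2] + 1e-9))
    stop("series temperature outside the calibrated range [",
         rng[1], ", ", rng[2], "] degC")
  list(
    raw0 = stats::approx(model$temperature, model$raw0, temperature,
                         rule = 2)$y,
    gain = stats::approx(model$temperature, model$gain, temperature,
                         rule = 2)$y
  )
}

#' Apply a calibration model to a raw optode series
#'
#' Concentration is the temperature-interpolated affine map of the raw signal,
#' multiplied by `1 + pressure_coeff * pressure / 1000`. Drift correction
#' (subtracting `drift_rate` times days since the calibration epoch) is
#' off by default because the field drift estimate was negligible.
#'
#' @param raw_series data.frame with columns `time_s`, `raw`, `temp_c` and,
#'   when the model's pressure coefficient is non-zero, `pressure_dbar`
#' @param model a [fit_two_point()] calibration
#' @param drift_correction apply the drift term?
#' @param time_origin_days experiment start, days since the calibration epoch
#' @return data.frame `time_s`, `o2_umol_l`, `temp_c` (class `optode_series`)
#' @export
apply_calibration <- function(raw_series, model, drift_correction = FALSE,
                              time_origin_days = 0) {
  stopifnot(inherits(model, "calibration_model"),
            all(c("time_s", "raw", "temp_c") %in% names(raw_series)))
  if (model$pressure_coeff != 0 && !("pressure_dbar" %in% names(raw_series)))
    stop("pressure_dbar column required when pressure_coeff is non-zero")
  cf <- interp_coef(model, raw_series$temp_c)
  conc <- cf$gain * (raw_series$raw - cf$raw0)
  if (model$pressure_coeff != 0) {
    conc <- conc * (1 + model$pressure_coeff * raw_series$pressure_dbar / 1000)
  }
  if (drift_correction) {
    days <- time_origin_days + raw_series$time_s / 86400 -
      model$calibration_epoch
    conc <- conc - model$drift_rate * days
  }
  out <- data.frame(
    time_s = raw_series$time_s, time_h = raw_series$time_s / 3600,
    o2_umol_l = conc, temp_c = raw_series$temp_c
  )
  class(out) <- c("optode_series", "data.frame")
  out
}

#' Estimate optode drift from pre- and post-deployment calibrations
#'
#' Evaluates both calibration models at a set of reference conditions (raw
#' reading, temperature) and returns the mean concentration discrepancy per
#' elapsed day. Positive when the later calibration reads higher.
#'
#' @param pre_cal,post_cal [fit_two_point()] models
#' @param elapsed_days days between the calibrations (> 0)
#' @param reference data.frame with `raw` and `temp_c`; defaults to the
#'   post-calibration 100% readings at the calibrated temperatures
#' @return drift in umol l-1 d-1
#' @export
estimate_drift <- function(pre_cal, post_cal, elapsed_days,
                           reference = NULL) {
  if (elapsed_days <= 0) stop("elapsed_days must be > 0")
  if (is.null(reference)) {
    # default reference: readings equivalent to 200 umol l-1 under the post
    # calibration, at each calibrated temperature
    reference <- data.frame(
      raw = post_cal$raw0 + 200 / post_cal$gain,
      temp_c = post_cal$temperature
    )
  }
  cpre <- {
    cf <- interp_coef(pre_cal, reference$temp_c)
    cf$gain * (reference$raw - cf$raw0)
  }
  cpost <- {
    cf <- interp_coef(post_cal, reference$temp_c)
    cf$gain * (reference$raw - cf$raw0)
  }
  mean(cpost - cpre) / elapsed_days
}
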