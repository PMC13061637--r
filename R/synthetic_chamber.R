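#' Configuration for a synthetic benthic chamber incubation
#'
#' Defines the generating model for one sealed-chamber optode trace. Defaults
#' emulate the structure of abyssal nodule-field incubations: initial O2 of
#' 185.2 +/- 2.9 umol l-1, a flat no-production window while stirrers are off,
#' a saturating net production trend, 50 ml dilution dips at the late syringe
#' samplings (28, 38, 47 h), 10-s logging, weak sensor noise and slow drift.
#'
#' @param initial_o2_mean mean starting O2, umol l-1
#' @param initial_o2_sd between-chamber SD of starting O2, umol l-1
#' @param scoc_true true areal O2 consumption, mmol m-2 d-1 (>= 0)
#' @param dop_true true areal dark O2 production, mmol m-2 d-1 (>= 0)
#' @param saturation_shape exponential damping rate of the net production
#'   trend, d-1; 0 gives a strictly linear trend
#' @param chamber_area chamber footprint, cm2
#' @param water_depth overlying water height, cm
#' @param stir_off_interval initial stirrer-off window, h (no production, flat
#'   trace apart from noise/drift)
#' @param syringe_times syringe sampling times producing dilution dips, h
#' @param syringe_volume volume entrained from outside per sampling, ml
#' @param ambient_o2 ambient bottom-water O2 outside the chamber, umol l-1
#' @param noise_sd additive iid Gaussian sensor noise SD, umol l-1
#' @param drift_rate linear sensor drift, umol l-1 d-1
#' @param duration total incubation length, h
#' @param log_interval optode logging cadence, s
#' @param gap_intervals list of c(start_h, end_h) windows where the optode
#'   failed to log (samples removed, not interpolated)
#' @param seed integer root seed; identical seed + config gives bit-identical
#'   output
#' @return object of class `chamber_sim_config`
#' @export
chamber_sim_config <- function(initial_o2_mean = 185.2,
                               initial_o2_sd = 2.9,
                               scoc_true = 0.7,
                               dop_true = 5,
                               saturation_shape = 0.5,
                               chamber_area = 484,
                               water_depth = 10,
                               stir_off_interval = 2,
                               syringe_times = c(28, 38, 47),
                               syringe_volume = 50,
                               ambient_o2 = 185.2,
                               noise_sd = 0.5,
                               drift_rate = 0.27,
                               duration = 47,
                               log_interval = 10,
                               gap_intervals = list(),
                               seed = 1L) {
  cfg <- list(
    initial_o2_mean = initial_o2_mean, initial_o2_sd = initial_o2_sd,
    scoc_true = scoc_true, dop_true = dop_true,
    saturation_shape = saturation_shape,
    chamber_area = chamber_area, water_depth = water_depth,
    stir_off_interval = stir_off_interval,
    syringe_times = syringe_times, syringe_volume = syringe_volume,
    ambient_o2 = ambient_o2, noise_sd = noise_sd, drift_rate = drift_rate,
    duration = duration, log_interval = log_interval,
    gap_intervals = gap_intervals, seed = as.integer(seed)
  )
  stopifnot(
    chamber_area > 0, water_depth > 0, noise_sd >= 0,
    scoc_true >= 0, dop_true >= 0, saturation_shape >= 0,
    duration > 0, log_interval > 0, initial_o2_sd >= 0
  )
  if (syringe_volume >= chamber_area * water_depth) # ml vs cm3
    stop("syringe_volume must be smaller than the chamber water volume")
  structure(cfg, class = "chamber_sim_config")
}

#' Derive a per-stream seed from a root seed
#'
#' Independent random streams (initial value, noise, ...) use seeds derived
#' deterministically from the root so that adding a stream never perturbs the
#' draws of another. Kept below 2^31 - 1.
#'
#' @param root integer root seed
#' @param stream small integer stream index
#' @return derived integer seed
#' @export
derive_seed <- function(root, stream) {
  as.integer((as.double(root) * 48271 + stream * 1000003) %% 2147483647)
}

#' Simulate a sealed benthic chamber optode series
#'
#' Generates the clean concentration trajectory implied by the configured net
#' rate (production minus consumption, converted to a volumetric rate by the
#' overlying water height), damped by exponential saturation, held flat during
#' the stirrer-off window, stepped down at each syringe event by the exact
#' mass-balance dilution with ambient water, then overlays linear drift and
#' Gaussian noise and removes samples falling in logging gaps.
#'
#' @param config a [chamber_sim_config()]
#' @return list with `series` (data.frame: time_s, time_h, o2_umol_l, temp_c)
#'   carrying event annotations as attribute `events`, and `truth` (the
#'   generating parameters plus the clean, noise-free trajectory summary:
#'   initial, clean max, integrated net production)
#' @export
simulate_chamber_series <- function(config) {
  stopifnot(inherits(config, "chamber_sim_config"))
  time_s <- seq(0, config$duration * 3600, by = config$log_interval)
  time_h <- time_s / 3600
  time_d <- time_h / 24

  set.seed(derive_seed(config$seed, 1L))
  c0 <- stats::rnorm(1, config$initial_o2_mean, config$initial_o2_sd)

  # net volumetric rate, umol l-1 d-1: (mmol m-2 d-1) / depth(m) = mmol m-3 d-1
  r0 <- (config$dop_true - config$scoc_true) / (config$water_depth / 100)
  s <- config$saturation_shape # d-1
  t_eff <- pmax(time_d - config$stir_off_interval / 24, 0)
  cum <- if (s > 0) r0 * (1 - exp(-s * t_eff)) / s else r0 * t_eff
  clean <- c0 + cum

  # mass-balance dilution at syringe events (applied to the clean trajectory;
  # production after an event continues from the diluted value, so later
  # samples inherit every earlier dip)
  v_l <- config$chamber_area * config$water_depth / 1000
  v_syr <- config$syringe_volume / 1000
  dil_b <- (v_l - v_syr) / v_l
  dil_a <- config$ambient_o2 * v_syr / v_l
  ev <- sort(config$syringe_times[config$syringe_times <= config$duration])
  for (te in ev) {
    after <- time_h >= te
    # dilution maps C -> b*C + a; subsequent accumulated production is
    # unaffected, so shift the post-event trajectory by the step it causes
    c_at <- clean[which(after)[1]]
    clean[after] <- clean[after] + (dil_b * c_at + dil_a - c_at)
  }

  if (any(!is.finite(clean)) || any(clean < 0))
    stop("config infeasible: simulated concentrations non-finite or negative")

  set.seed(derive_seed(config$seed, 2L))
  noise <- stats::rnorm(length(clean), 0, config$noise_sd)
  o2 <- clean + noise + config$drift_rate * time_d

  keep <- rep(TRUE, length(time_h))
  for (g in config$gap_intervals)
    keep <- keep & !(time_h >= g[1] & time_h <= g[2])

  series <- data.frame(
    time_s = time_s[keep], time_h = time_h[keep],
    o2_umol_l = o2[keep], temp_c = 1.6
  )
  events <- data.frame(
    event = c("seal", "stir_off",
              rep("syringe", length(ev)), "stir_on"),
    time_h = c(0, 0, ev, config$stir_off_interval)
  )
  attr(series, "events") <- events
  attr(series, "stir_off_interval_h") <- config$stir_off_interval
  class(series) <- c("optode_series", "data.frame")

  truth <- list(
    config = config, initial_o2 = c0,
    clean_max = max(clean), clean_final = clean[length(clean)],
    net_rate_true = config$dop_true - config$scoc_true,
    integrated_net_umol_l = max(cum),
    water_volume_l = v_l
  )
  list(series = series, truth = truth)
}
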