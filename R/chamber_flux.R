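#' Describe one benthic chamber incubation
#'
#' Geometry, treatment and bookkeeping for a single chamber deployment. The
#' water volume follows from the footprint and the post-recovery water depth
#' (mean of four measurements); when the chamber doors failed and the depth is
#' unknown, pass `water_depth = NA` and areal/total quantities are flagged
#' rather than computed.
#'
#' @param id experiment identifier
#' @param chamber_area footprint, cm2 (lander chambers are 484)
#' @param water_depth overlying water height, cm (NA if undetermined)
#' @param treatment one of "algal", "DIC+NH4", "filtered seawater", "control"
#' @param nodule_count nodules recovered from the chamber
#' @param nodule_areas planform nodule areas, cm2
#' @return object of class `chamber_experiment`
#' @export
chamber_experiment <- function(id, chamber_area = 484, water_depth = NA,
                               treatment = "control", nodule_count = 0,
                               nodule_areas = numeric()) {
  treatment <- match.arg(treatment,
                         c("algal", "DIC+NH4", "filtered seawater", "control"))
  stopifnot(chamber_area > 0, nodule_count >= 0)
  if (!is.na(water_depth) && water_depth <= 0)
    stop("water_depth must be positive or NA")
  structure(list(
    id = id, chamber_area = chamber_area, water_depth = water_depth,
    water_volume = if (is.na(water_depth)) NA_real_ else
      chamber_area * water_depth / 1000, # litres
    treatment = treatment, nodule_count = nodule_count,
    nodule_areas = nodule_areas
  ), class = "chamber_experiment")
}

#' Align an optode series to the lander schedule
#'
#' Re-indexes time so that zero is the moment the chamber sealed the sediment,
#' attaches the programmed events, and flags samples recorded before sealing
#' and during the initial stirrer-off window (the latter are excluded from
#' rate fits by default because no mixing means the optode does not see the
#' chamber-average concentration).
#'
#' @param series optode series with `time_s`/`time_h`
#' @param program list with `seal_h` (seal time on the series clock),
#'   `stir_off` (c(start, end) h after sealing) and `syringe_times_h`
#' @return the series with `time_h` re-zeroed and logical columns `sealed`,
#'   `stirred`; events stored in attribute `events`
#' @export
align_schedule <- function(series, program) {
  stopifnot(is.list(program), !is.null(program$seal_h))
  if (program$seal_h > max(series$time_h) ||
      program$seal_h < min(series$time_h) - 1e-9)
    stop("program seal time outside the series span")
  series$time_h <- series$time_h - program$seal_h
  series$time_s <- series$time_h * 3600
  series$sealed <- series$time_h >= 0
  so <- program$stir_off %||% c(0, 0)
  series$stirred <- !(series$time_h >= so[1] & series$time_h < so[2])
  syr <- program$syringe_times_h %||% numeric()
  attr(series, "events") <- data.frame(
    event = c("seal", rep("syringe", length(syr))),
    time_h = c(0, syr)
  )
  attr(series, "stir_off_interval_h") <- so[2]
  class(series) <- unique(c("optode_series", class(series)))
  series
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Undo syringe-sampling dilution steps in a chamber series
#'
#' Each syringe sampling entrains outside seawater, instantaneously mixing
#' `syringe_volume` of ambient water into the chamber:
#' `C_after = (C_before (V - v) + C_ambient v) / V`. The pre-event
#' concentration is recovered from the first post-event sample by inverting
#' that mass balance, and all later samples are shifted up by the step;
#' corrections compose cumulatively over events. On noise-free input the
#' corrected series has no dilution discontinuities.
#'
#' @param series optode series (`time_h`, `o2_umol_l`)
#' @param events syringe event times, h
#' @param water_volume chamber water volume, l
#' @param syringe_volume entrained volume, ml
#' @param ambient_o2 ambient O2, umol l-1 (required)
#' @param post_window_s average this many seconds of post-event samples when
#'   estimating the post-event level (0 = first sample only)
#' @return the corrected series
#' @export
correct_dilution <- function(series, events, water_volume, syringe_volume,
                             ambient_o2, post_window_s = 0) {
  if (missing(ambient_o2) || is.null(ambient_o2) || !is.finite(ambient_o2))
    stop("ambient_o2 is required for dilution correction")
  stopifnot(syringe_volume < 1000 * water_volume)
  b <- (water_volume - syringe_volume / 1000) / water_volume
  a <- ambient_o2 * (syringe_volume / 1000) / water_volume
  # estimate every step from the raw series (a dilution acts on the raw,
  # still-diluted trajectory), then apply the cumulative shifts
  raw <- series$o2_umol_l
  shift <- numeric(length(raw))
  for (te in sort(events)) {
    after <- series$time_h >= te
    if (!any(after) || all(after)) next
    idx <- which(after)
    sel <- idx[series$time_h[idx] <= te + post_window_s / 3600]
    if (length(sel) == 0) sel <- idx[1]
    c_after <- stats::median(raw[sel])
    c_before <- (c_after - a) / b
    shift[after] <- shift[after] + (c_before - c_after)
  }
  series$o2_umol_l <- raw + shift
  series
}

#' Net O2 change and areal rates for one chamber incubation
#'
#' The initial concentration is a robust (median) estimate over a short
#' window after sealing; the maximum is taken over the sealed segment. The
#' total net change is `delta_c * water_volume`. The headline areal rate
#' divides the concentration change by the water height and by the productive
#' time (time to maximum minus the stirrer-off window, during which nothing
#' is produced); a least-squares regression rate over the stirred sealed
#' segment up to the maximum is emitted alongside.
#'
#' @param series aligned optode series (columns `time_h`, `o2_umol_l`,
#'   optionally `sealed`, `stirred`)
#' @param experiment a [chamber_experiment()]
#' @param initial_window_min window for the robust initial estimate, minutes
#' @param neutral_tol |delta_c| below this is classified "neutral", umol l-1
#' @return object of class `flux_result`: initial, max, delta_c, total net O2
#'   (umol), max-based and regression areal rates (mmol m-2 d-1), time to
#'   max (h), classification, and `volume_known`
#' @export
net_o2_change <- function(series, experiment, initial_window_min = 5,
                          neutral_tol = 1e-6) {
  stopifnot(inherits(experiment, "chamber_experiment"))
  sealed <- series$sealed %||% rep(TRUE, nrow(series))
  stirred <- series$stirred %||% rep(TRUE, nrow(series))
  s <- series[sealed, ]
  if (nrow(s) == 0) stop("sealed segment is empty")
  win <- s$time_h <= s$time_h[1] + initial_window_min / 60
  initial <- stats::median(s$o2_umol_l[win])
  imax <- which.max(s$o2_umol_l)
  max_o2 <- s$o2_umol_l[imax]
  time_to_max <- s$time_h[imax] - s$time_h[1]
  delta_c <- max_o2 - initial

  stir_off_h <- attr(series, "stir_off_interval_h") %||% 0
  productive_h <- max(time_to_max - min(stir_off_h, time_to_max), 0)

  volume_known <- !is.na(experiment$water_volume)
  depth_m <- if (volume_known) experiment$water_depth / 100 else NA_real_

  rate_max <- if (volume_known && productive_h > 0)
    delta_c * depth_m / (productive_h / 24) else NA_real_

  fit_seg <- series[sealed & stirred &
                      series$time_h <= s$time_h[imax], , drop = FALSE]
  rate_reg <- if (volume_known && nrow(fit_seg) >= 3) {
    slope_d <- unname(stats::coef(
      stats::lm(o2_umol_l ~ I(time_h / 24), data = fit_seg))[2])
    slope_d * depth_m
  } else NA_real_

  classification <- if (abs(delta_c) <= neutral_tol) "neutral"
    else if (delta_c > 0) "net producer" else "net consumer"

  structure(list(
    id = experiment$id,
    initial_o2 = initial, max_o2 = max_o2, delta_c = delta_c,
    total_net_o2 = if (volume_known) delta_c * experiment$water_volume
      else NA_real_,
    dop_rate = rate_max, dop_rate_regression = rate_reg,
    time_to_max = time_to_max, classification = classification,
    volume_known = volume_known, treatment = experiment$treatment
  ), class = "flux_result")
}

#' @export
as.data.frame.flux_result <- function(x, ...) {
  data.frame(
    id = x$id, treatment = x$treatment, initial_o2 = x$initial_o2,
    max_o2 = x$max_o2, delta_c = x$delta_c, total_net_o2 = x$total_net_o2,
    dop_rate = x$dop_rate, dop_rate_regression = x$dop_rate_regression,
    time_to_max = x$time_to_max, classification = x$classification,
    volume_known = x$volume_known
  )
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf(
    "Chamber %s (%s): initial %.1f, max %.1f umol/l (dC %.1f) in %.1f h\n",
    x$id, x$treatment, x$initial_o2, x$max_o2, x$delta_c, x$time_to_max))
  if (x$volume_known) {
    cat(sprintf("  total net O2 %.1f umol; rate %.2f (max-based) / %.2f (regression) mmol m-2 d-1\n",
                x$total_net_o2, x$dop_rate, x$dop_rate_regression))
  } else {
    cat("  water volume unknown: concentration-only result\n")
  }
  cat("  classification:", x$classification, "\n")
  invisible(x)
}

#' Sediment community O2 consumption from a declining chamber series
#'
#' For incubations showing a constant linear O2 decline, SCOC is the
#' least-squares slope of concentration against time scaled by the water
#' height, sign-flipped to a positive consumption rate.
#'
#' @param series aligned optode series
#' @param experiment a [chamber_experiment()] with known water depth
#' @return SCOC in mmol m-2 d-1 (positive)
#' @export
scoc_from_decline <- function(series, experiment) {
  stopifnot(inherits(experiment, "chamber_experiment"),
            !is.na(experiment$water_depth))
  sealed <- series$sealed %||% rep(TRUE, nrow(series))
  stirred <- series$stirred %||% rep(TRUE, nrow(series))
  s <- series[sealed & stirred, ]
  if (nrow(s) < 3) stop("too few samples in the sealed stirred segment")
  slope_d <- unname(stats::coef(
    stats::lm(o2_umol_l ~ I(time_h / 24), data = s))[2]) # umol l-1 d-1
  if (slope_d >= -1e-9)
    stop("series shows no decline; use net_o2_change for net producers")
  -slope_d * experiment$water_depth / 100
}

#' Nodule density from chamber counts
#'
#' @param counts nodules per chamber (vector)
#' @param chamber_area chamber footprint, cm2
#' @return list: per-chamber densities (`density_m2`, nodules m-2), `mean`,
#'   `se`, `n`
#' @export
nodule_density <- function(counts, chamber_area = 484) {
  if (chamber_area <= 0) stop("chamber_area must be positive")
  stopifnot(all(counts >= 0))
  d <- counts / (chamber_area / 1e4)
  list(
    density_m2 = d, mean = mean(d),
    se = if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else 0,
    n = length(d)
  )
}
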