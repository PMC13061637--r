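#' Summarize duplicate Winkler titrations
#'
#' Each syringe sample is titrated twice; the per-sample concentration is the
#' duplicate mean and the per-sample error is the absolute duplicate
#' difference. The error summary is reported as mean +/- standard error with
#' the pair count, the convention used for cruise-level titration precision.
#'
#' @param samples data.frame with columns `experiment`, `time_h`,
#'   `titration_1`, `titration_2` (umol l-1)
#' @return list: `samples` (input plus `o2_mean`, `error`), `error_mean`,
#'   `error_se`, `n`, and a formatted `label` like "3.5 +/- 0.3 (n=71)"
#' @export
winkler_summary <- function(samples) {
  req <- c("experiment", "time_h", "titration_1", "titration_2")
  stopifnot(all(req %in% names(samples)), nrow(samples) >= 1)
  if (any(!is.finite(samples$titration_1)) ||
      any(!is.finite(samples$titration_2)))
    stop("every sample needs exactly two finite titration values")
  samples$o2_mean <- (samples$titration_1 + samples$titration_2) / 2
  samples$error <- abs(samples$titration_1 - samples$titration_2)
  n <- nrow(samples)
  m <- mean(samples$error)
  se <- if (n > 1) stats::sd(samples$error) / sqrt(n) else 0
  list(
    samples = samples, error_mean = m, error_se = se, n = n,
    label = format_mean_se(m, se, n)
  )
}

#' Format a mean +/- SE with its sample size
#'
#' @param mean,se,n summary values
#' @param digits digits after the decimal point
#' @return character like "3.5 ± 0.3 (n=71)"
#' @export
format_mean_se <- function(mean, se, n, digits = 1) {
  sprintf("%.*f ± %.*f (n=%d)", digits, mean, digits, se, as.integer(n))
}

#' Compare Winkler concentrations with optode readings at matched times
#'
#' For each Winkler sample the optode reading nearest in time (within a
#' tolerance window) is located and the percent difference
#' `100 * (optode - winkler) / optode` computed, so positive values mean the
#' Winkler concentration is lower (the expected sign when syringe samples
#' outgas during recovery).
#'
#' @param winkler data.frame with `time_h` and `o2_mean` (e.g. from
#'   [winkler_summary()]`$samples`)
#' @param series an optode series with `time_h` and `o2_umol_l`
#' @param window_s matching tolerance around each Winkler time, seconds
#' @return list: `pairs` (time, winkler, optode, pct_diff), `mean`, `se`, `n`,
#'   formatted `label`
#' @export
winkler_vs_optode <- function(winkler, series, window_s = 60) {
  stopifnot(all(c("time_h", "o2_mean") %in% names(winkler)),
            all(c("time_h", "o2_umol_l") %in% names(series)))
  pairs <- lapply(seq_len(nrow(winkler)), function(i) {
    dt <- abs(series$time_h - winkler$time_h[i]) * 3600
    j <- which.min(dt)
    if (dt[j] > window_s)
      stop(sprintf("no optode sample within %gs of Winkler time %g h",
                   window_s, winkler$time_h[i]))
    opt <- series$o2_umol_l[j]
    data.frame(
      time_h = winkler$time_h[i], winkler = winkler$o2_mean[i],
      optode = opt, pct_diff = 100 * (opt - winkler$o2_mean[i]) / opt
    )
  })
  pairs <- do.call(rbind, pairs)
  n <- nrow(pairs)
  m <- mean(pairs$pct_diff)
  se <- if (n > 1) stats::sd(pairs$pct_diff) / sqrt(n) else 0
  list(pairs = pairs, mean = m, se = se, n = n,
       label = format_mean_se(m, se, n, digits = 0))
}
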