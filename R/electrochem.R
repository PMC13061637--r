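#' Thermodynamic water-splitting potential from the Gibbs free energy
#'
#' `E = |dG| / (n F)` with F = 96485 C mol-1; for water electrolysis
#' (dG = 237.1 kJ mol-1, n = 2 electrons) this is the familiar 1.23 V.
#'
#' @param gibbs_free_energy |dG| in kJ mol-1
#' @param electrons electrons transferred (>= 1)
#' @return potential in V
#' @export
water_splitting_potential <- function(gibbs_free_energy = 237.1,
                                      electrons = 2) {
  if (electrons < 1) stop("electrons must be >= 1")
  abs(gibbs_free_energy) * 1000 / (electrons * 96485)
}

#' Background-correct a voltage survey
#'
#' @param survey a [simulate_voltage_survey()] object or data.frame with a
#'   `volts` column
#' @param background_v background potential; defaults to the survey's stored
#'   `background_v` attribute
#' @return the survey with a `corrected_v` column
#' @export
background_correct <- function(survey, background_v = NULL) {
  stopifnot("volts" %in% names(survey))
  if (is.null(background_v)) background_v <- attr(survey, "background_v")
  if (is.null(background_v)) stop("no background potential supplied or stored")
  survey$corrected_v <- survey$volts - background_v
  survey
}

#' Box-whisker summary of a corrected voltage survey
#'
#' Order statistics in the convention of the field figure: whiskers at the
#' minimum and maximum, box at the lower/upper quartiles computed as Tukey
#' hinges (medians of the half-samples excluding the overall median), the
#' median line, the mean marker, and the replicate count.
#'
#' @param survey a background-corrected survey (needs `corrected_v`; falls
#'   back to `volts`)
#' @return named numeric: min, q1, median, mean, q3, max, n
#' @export
summarize_survey <- function(survey) {
  v <- survey$corrected_v %||% survey$volts
  if (is.null(v) || length(v) == 0) stop("empty survey")
  fn <- stats::fivenum(v) # min, lower hinge, median, upper hinge, max
  c(min = fn[1], q1 = fn[2], median = fn[3], mean = mean(v),
    q3 = fn[4], max = fn[5], n = length(v))
}

#' Assess oxygen-evolution-reaction feasibility from observed potentials
#'
#' Compares the maximum background-corrected potential observed across
#' surveys against the required voltage: the thermodynamic water-splitting
#' potential plus an overpotential, minus an optional reduction for the
#' lattice-oxygen-mediated mechanism ("several hundred millivolts",
#' magnitude a free parameter). Feasibility uses an inclusive boundary
#' (observed >= required).
#'
#' @param surveys a survey or list of surveys (each with `corrected_v` or
#'   `volts`)
#' @param thermodynamic_v thermodynamic potential, V
#' @param overpotential_v kinetic overpotential, V
#' @param mechanism "standard" or "lattice-oxygen"
#' @param mechanism_reduction_v requirement reduction under the
#'   lattice-oxygen-mediated mechanism, V
#' @return object of class `oer_assessment`: required, observed max, feasible
#' @export
assess_oer <- function(surveys,
                       thermodynamic_v = 1.23,
                       overpotential_v = 0.37,
                       mechanism = c("standard", "lattice-oxygen"),
                       mechanism_reduction_v = 0) {
  mechanism <- match.arg(mechanism)
  if (is.data.frame(surveys)) surveys <- list(surveys)
  if (length(surveys) == 0) stop("at least one survey required")
  obs <- max(vapply(surveys, function(s) {
    v <- s$corrected_v %||% s$volts
    max(v)
  }, numeric(1)))
  red <- if (mechanism == "lattice-oxygen") mechanism_reduction_v else 0
  required <- thermodynamic_v + overpotential_v - red
  structure(list(
    thermodynamic_v = thermodynamic_v, overpotential_v = overpotential_v,
    mechanism = mechanism, mechanism_reduction_v = red,
    required_v = required, observed_max_v = obs,
    feasible = obs >= required
  ), class = "oer_assessment")
}

#' @export
print.oer_assessment <- function(x, ...) {
  cat(sprintf(
    "OER requirement %.2f V (%.2f + %.2f - %.2f, %s mechanism); observed max %.2f V -> %s\n",
    x$required_v, x$thermodynamic_v, x$overpotential_v,
    x$mechanism_reduction_v, x$mechanism, x$observed_max_v,
    if (x$feasible) "feasible" else "infeasible"))
  invisible(x)
}
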