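# Unit bridge for Fick's-law flux:
#   J [mmol m-2 d-1] = phi * Ds[cm2 s-1] * dC/dz[umol l-1 mm-1] * 8640
# (1e-4 m2/cm2 * 1e3 mmol m-4 per umol l-1 mm-1 * 86400 s/d / 1e3)
FICK_UNIT_FACTOR <- 8640

#' Configuration for a synthetic porewater O2 microprofile
#'
#' The generated profile is a constant overlying-water segment above the
#' sediment-water interface, then a porewater segment whose near-surface
#' gradient equals `true_flux / (porosity * Ds * 8640)` by construction
#' (Fick's first law inverted), so the flux is recoverable exactly from
#' noise-free output. Below the linear near-surface zone the profile rolls
#' off quadratically to zero with continuous slope; in steady state the
#' depth of the oxic zone is set by the flux and the overlying concentration,
#' so the generator derives it rather than taking it as a free dial.
#'
#' @param true_flux diffusive O2 uptake, mmol m-2 d-1 (positive into sediment)
#' @param porosity sediment porosity, fraction in (0, 1)
#' @param diffusivity tortuosity-corrected effective diffusivity Ds, cm2 s-1
#' @param overlying_o2 bottom-water O2, umol l-1
#' @param surface_depth_offset water column above the interface in the
#'   recorded profile, mm
#' @param max_depth_below_surface cap on recorded porewater depth, mm
#' @param step depth increment, mm (field instrument used 0.05)
#' @param n_replicates replicate readings per depth (field instrument took 5)
#' @param noise_sd per-reading Gaussian noise SD, umol l-1
#' @param seed integer root seed
#' @return object of class `profile_sim_config`
#' @export
profile_sim_config <- function(true_flux = 0.7,
                               porosity = 0.8,
                               diffusivity = 8.16e-6,
                               overlying_o2 = 185.2,
                               surface_depth_offset = 2,
                               max_depth_below_surface = 25,
                               step = 0.05,
                               n_replicates = 5,
                               noise_sd = 0.5,
                               seed = 1L) {
  stopifnot(
    step > 0, porosity > 0, porosity < 1, diffusivity > 0,
    overlying_o2 > 0, surface_depth_offset >= 0, noise_sd >= 0,
    true_flux >= 0, n_replicates >= 1, max_depth_below_surface > 0
  )
  structure(list(
    true_flux = true_flux, porosity = porosity, diffusivity = diffusivity,
    overlying_o2 = overlying_o2, surface_depth_offset = surface_depth_offset,
    max_depth_below_surface = max_depth_below_surface, step = step,
    n_replicates = n_replicates, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "profile_sim_config")
}

#' Simulate a porewater O2 microprofile with replicate readings
#'
#' @param config a [profile_sim_config()]
#' @return list with `readings` (data.frame: depth_mm, rep_1..rep_k raw
#'   readings) and `truth` (generating parameters, true interface depth,
#'   true near-surface gradient in umol l-1 mm-1, linear-zone extent)
#' @export
simulate_microprofile <- function(config) {
  stopifnot(inherits(config, "profile_sim_config"))
  c0 <- config$overlying_o2
  grad <- if (config$true_flux == 0) 0 else
    config$true_flux / (config$porosity * config$diffusivity * FICK_UNIT_FACTOR)

  depth <- seq(0, config$surface_depth_offset + config$max_depth_below_surface,
               by = config$step)
  u <- depth - config$surface_depth_offset # depth below interface
  clean <- rep(c0, length(depth))
  if (grad > 0) {
    u1 <- c0 / (2 * grad)       # end of the exactly linear zone (C = c0/2)
    L <- 3 * c0 / (2 * grad)    # oxic depth: quadratic reaches 0, slope 0
    lin <- u > 0 & u <= u1
    quad <- u > u1 & u < L
    clean[lin] <- c0 - grad * u[lin]
    clean[quad] <- (c0 / 2) * (1 - (u[quad] - u1) / (L - u1))^2
    clean[u >= L] <- 0
  } else {
    u1 <- L <- Inf
  }

  set.seed(derive_seed(config$seed, 3L))
  k <- config$n_replicates
  reads <- matrix(
    rep(clean, each = k) + stats::rnorm(length(clean) * k, 0, config$noise_sd),
    ncol = k, byrow = TRUE
  )
  colnames(reads) <- paste0("rep_", seq_len(k))
  readings <- cbind(data.frame(depth_mm = depth), as.data.frame(reads))

  list(
    readings = readings,
    truth = list(
      config = config,
      surface_depth_mm = config$surface_depth_offset,
      gradient_true = grad,          # umol l-1 mm-1, magnitude
      linear_zone_mm = u1, oxic_depth_mm = L,
      flux_true = config$true_flux
    )
  )
}

#' Simulate a nodule-surface voltage survey
#'
#' Replicate open-circuit potentials measured at random positions on one
#' specimen, offset by a stored electrode/seawater background.
#'
#' @param n_sites number of replicate measurement positions (>= 1)
#' @param mean_v true mean specimen potential, V
#' @param sd_v between-position SD, V
#' @param background_v background seawater/electrode potential, V
#' @param seed integer seed
#' @param specimen specimen label
#' @return object of class `voltage_survey`: data.frame (site, volts) of raw
#'   readings with the background stored as attribute `background_v`
#' @export
simulate_voltage_survey <- function(n_sites, mean_v, sd_v, background_v,
                                    seed = 1L, specimen = "nodule") {
  stopifnot(n_sites >= 1, sd_v >= 0)
  set.seed(derive_seed(as.integer(seed), 4L))
  raw <- stats::rnorm(n_sites, mean_v, sd_v) + background_v
  out <- data.frame(site = seq_len(n_sites), volts = raw)
  attr(out, "background_v") <- background_v
  attr(out, "specimen") <- specimen
  class(out) <- c("voltage_survey", "data.frame")
  out
}

#' Simulate a taxon relative-abundance table with one DOP-correlated taxon
#'
#' Generates Dirichlet-distributed compositions (rows sum to 1) and reorders
#' whole rows so that the designated first taxon attains, in expectation, a
#' target Spearman rank correlation with the supplied per-sample DOP values;
#' the remaining taxa stay independent of DOP because row reordering does not
#' touch within-row structure.
#'
#' @param n_samples number of samples (must match `length(dop_values)`)
#' @param n_taxa number of taxa (>= 2)
#' @param correlated_taxon_rho target rank correlation in `[-1, 1]` between
#'   taxon_1 and `dop_values`
#' @param dop_values per-sample DOP rates used as the correlation anchor
#' @param seed integer seed
#' @return data.frame (sample, taxon, rel_abund) in long form; taxon_1 is the
#'   designated correlated taxon
#' @export
simulate_taxon_table <- function(n_samples, n_taxa, correlated_taxon_rho,
                                 dop_values, seed = 1L) {
  stopifnot(n_samples == length(dop_values), n_taxa >= 2,
            abs(correlated_taxon_rho) <= 1)
  set.seed(derive_seed(as.integer(seed), 5L))
  g <- matrix(stats::rgamma(n_samples * n_taxa, shape = 1), n_samples, n_taxa)
  tab <- g / rowSums(g)

  # reorder rows: latent score mixes the DOP rank signal with noise so the
  # designated taxon's ranks track rank(dop) with the target strength
  rho <- correlated_taxon_rho
  zr <- scale(rank(dop_values))[, 1]
  z <- rho * zr + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n_samples)
  tab_sorted <- tab[order(tab[, 1]), , drop = FALSE]
  tab <- tab_sorted[rank(z, ties.method = "first"), , drop = FALSE]

  data.frame(
    sample = rep(paste0("S", seq_len(n_samples)), times = n_taxa),
    taxon = rep(paste0("taxon_", seq_len(n_taxa)), each = n_samples),
    rel_abund = as.vector(tab)
  )
}
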