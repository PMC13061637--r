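# Independent oracles used across test files.

# Radiolytic O2 mass carrying Avogadro's number explicitly, step by step:
# moles -> atoms -> decayed atoms -> energy -> molecules -> moles -> grams.
oracle_radiolysis_g <- function(q_g, ea_ev, g_o2, a_g_mol, lambda, t_yr) {
  n_a <- 6.02214076e23
  atoms <- q_g / a_g_mol * n_a
  decayed <- atoms * (-expm1(-lambda * t_yr))
  energy_ev <- decayed * ea_ev
  molecules <- energy_ev * g_o2 / 100
  molecules / n_a * 31.998
}

# Textbook one-way ANOVA by explicit sums of squares.
oracle_anova_f <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- table(groups)
  ss_b <- sum(ns * (means - gm)^2)
  ss_w <- sum((values - means[groups])^2)
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  f <- (ss_b / df1) / (ss_w / df2)
  list(f = f, df = c(df1, df2), p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Exhaustive Spearman permutation p by filtering the full n^n grid down to
# permutations (deliberately different machinery from the package's
# recursive enumerator).
oracle_spearman_exact_p <- function(x, y) {
  n <- length(x)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  is_perm <- apply(grid, 1, function(r) length(unique(r)) == n)
  perms <- grid[is_perm, , drop = FALSE]
  rho_obs <- stats::cor(rank(x), rank(y))
  rhos <- apply(perms, 1, function(p) stats::cor(rank(x), rank(y[p])))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# Synthetic affine optode: raw = a + b * concentration at each temperature.
make_affine_calibration <- function(temps = c(1.2, 7, 18, 30),
                                    a = 10, b = 0.05, salinity = 35) {
  ref100 <- o2_saturation_concentration(temps, salinity)
  pts <- calibration_points(
    temperature = rep(temps, each = 2),
    saturation_level = rep(c(0, 1), length(temps)),
    raw_reading = as.vector(rbind(a + b * 0, a + b * ref100)),
    reference_o2 = as.vector(rbind(0, ref100))
  )
  list(points = pts, a = a, b = b, ref100 = ref100, temps = temps)
}
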