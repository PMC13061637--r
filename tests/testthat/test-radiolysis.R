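test_that("decayed fraction obeys the limits and the half-life identity", {
  expect_equal(decayed_fraction(1e-10, 0), 0)
  lam <- log(2) / 4.468e9
  expect_equal(decayed_fraction(lam, 4.468e9), 0.5, tolerance = 1e-12)
  # small-t linearization: lambda t ~ 8.49e-13 over 48 h for U238
  t48 <- 48 / 8766
  expect_equal(decayed_fraction(1.55e-10, t48), 1.55e-10 * t48,
               tolerance = 1e-6)
  expect_error(decayed_fraction(1e-10, -1), "negative")
  # monotone in t
  ts <- 10^seq(0, 10, by = 1)
  expect_true(all(diff(decayed_fraction(lam, ts)) > 0))
})

test_that("the kinetic expression agrees with the Avogadro-carrying oracle", {
  const <- radionuclide_constants()
  t_yr <- 48 / 8766
  for (i in seq_len(nrow(const))) {
    inv <- isotope_inventory(const$isotope[i], "nodule", q_g = 0.01,
                             ea_ev = 4.5e7, g_o2 = 0.5)
    got <- o2_from_inventory(inv, t_yr)
    want <- oracle_radiolysis_g(0.01, 4.5e7, 0.5, const$atomic_mass[i],
                                const$lambda_per_yr[i], t_yr)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("the expression is linear in Q and G and zero for empty inventories", {
  base <- isotope_inventory("U238", "seawater", 1e-5, 5.17e7, 0.5)
  dblq <- isotope_inventory("U238", "seawater", 2e-5, 5.17e7, 0.5)
  dblg <- isotope_inventory("U238", "seawater", 1e-5, 5.17e7, 1.0)
  t_yr <- 0.01
  expect_equal(o2_from_inventory(dblq, t_yr), 2 * o2_from_inventory(base, t_yr),
               tolerance = 1e-14)
  expect_equal(o2_from_inventory(dblg, t_yr), 2 * o2_from_inventory(base, t_yr),
               tolerance = 1e-14)
  zero <- isotope_inventory("U238", "seawater", 0, 5.17e7, 0.5)
  expect_equal(o2_from_inventory(zero, t_yr), 0)
})

test_that("inconsistent decay constants are rejected", {
  expect_error(
    isotope_inventory("U238", "nodule", 1, 5e7, 0.5, lambda_per_yr = 2e-10),
    "inconsistent"
  )
  # a value within 0.1% of the half-life-implied constant is accepted
  lam <- log(2) / 4.468e9
  inv <- isotope_inventory("U238", "nodule", 1, 5e7, 0.5,
                           lambda_per_yr = lam * 1.0005)
  expect_s3_class(inv, "isotope_inventory")
})

test_that("sediment O2 is half the H2 rate and flagged as an overestimate", {
  expect_equal(as.numeric(sediment_o2_from_h2(0)), 0)
  expect_equal(as.numeric(sediment_o2_from_h2(1.0)), 0.5)
  expect_equal(as.numeric(sediment_o2_from_h2(c(2, 4))), c(1, 2))
  expect_equal(attr(sediment_o2_from_h2(1), "flag"), "probable overestimate")
  expect_error(sediment_o2_from_h2(-1), "negative")
})

test_that("chamber totals are additive over inventories and convert units", {
  a <- isotope_inventory("U238", "seawater", 1.6e-5, 5.17e7, 0.5)
  b <- isotope_inventory("Th232", "nodule", 3.4e-2, 4.26e7, 0.5)
  t_yr <- 48 / 8766
  ra <- total_radiolytic_o2(list(a), volume_l = 4.84, t_yr = t_yr)
  rb <- total_radiolytic_o2(list(b), volume_l = 4.84, t_yr = t_yr)
  rab <- total_radiolytic_o2(list(a, b), volume_l = 4.84, t_yr = t_yr)
  expect_equal(rab$total_o2_g, ra$total_o2_g + rb$total_o2_g,
               tolerance = 1e-12)
  expect_equal(rab$concentration_umol_l,
               rab$total_o2_g / 31.998 / 4.84 * 1e6, tolerance = 1e-12)
  # sediment rate contributes rate x time
  rs <- total_radiolytic_o2(list(a), sediment_o2_g_per_yr = 1e-6,
                            volume_l = 4.84, t_yr = t_yr)
  expect_equal(rs$total_o2_g - ra$total_o2_g, 1e-6 * t_yr, tolerance = 1e-15)
  expect_error(total_radiolytic_o2(list(), volume_l = 1, t_yr = 1), "empty")
  expect_error(total_radiolytic_o2(list(a), volume_l = 0, t_yr = 1), "volume")
})

test_that("the packaged synthetic inventory loads and evaluates", {
  path <- system.file("extdata", "isotope_inventory_synthetic.csv",
                      package = "darkoxygen")
  invs <- load_inventories(path)
  expect_length(invs, 8)
  res <- total_radiolytic_o2(invs, volume_l = 4.84, t_yr = 48 / 8766)
  expect_gt(res$concentration_umol_l, 0)
  expect_equal(nrow(res$per_inventory), 8)
})
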