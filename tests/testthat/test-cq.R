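test_that("the stoichiometric ratio reproduces the printed benchmark and scales", {
  # 100 nM of tagged 8-mer reaches phi = 1 at about 16 g/l of pool
  expect_equal(stoichiometric_ratio(100e-9, 16, L = 8), 1, tolerance = 0.05)
  phi1 <- stoichiometric_ratio(100e-9, 10, L = 8)
  expect_equal(stoichiometric_ratio(100e-9, 20, L = 8), phi1 / 2)
  # 12-mers at 25 g/l: hand evaluation of the defining ratio
  expect_equal(stoichiometric_ratio(100e-9, 25, L = 12),
               100e-9 * 4^12 / (25 / (303.7 * 12 + 79)),
               tolerance = 1e-12)
  # a 12N pool cannot reach phi = 1 at laboratory concentrations
  expect_gt(stoichiometric_ratio(100e-9, 25, L = 12), 1)
  expect_error(stoichiometric_ratio(0, 16, 8), "positive")
})

test_that("cq specification derives phi and validates the pair", {
  pool <- solution_spec(8, c_mass = 16, na_molar = 0.15)
  cq <- cq_spec("ACAGTCCT", "AGGACTGT", 100e-9, pool)
  expect_equal(cq$phi, 1, tolerance = 0.05)
  expect_equal(cq$f_CG, 0.5)
  expect_error(cq_spec("ACAGTCCT", "ACAGTCCT", 1e-7, pool),
               "reverse complement")
  expect_error(cq_spec("ACAGTCCTAAAA", "TTTTAGGACTGT", 1e-7, pool),
               "pool length")
})

test_that("tagged-pair observables obey the structural identities", {
  pool <- solution_spec(8, c_mass = 16, na_molar = 0.15)
  cq <- cq_spec("ACAGTCCT", "AGGACTGT", 100e-9, pool)
  grid <- melting_grid(0, 90, 2)
  ab <- theta_ab(cq, grid)
  ecq <- theta_e_cq(cq, grid)
  expect_true(all(ab$theta >= 0 & ab$theta <= 1))
  expect_true(all(diff(ecq$theta) <= 1e-12))
  # the total is never below the exact-pair component
  expect_true(all(ecq$theta >= ab$theta - 1e-12))
  # substituting theta_e_cq into the share identity returns theta_ab
  share <- ab$theta / ecq$theta
  expect_true(all(share > 0 & share < 1))
  # theta_ab / theta_e_cq equals the weight share by construction
  f <- cq$f_CG
  lab <- log(cq$phi) + log(pool$c_molar) -
    dG(cq$fe_ab, grid) / (1.987204258e-3 * grid)
  S <- vapply(grid, function(T) attr(partition_sum(8, f, T, pool$c_molar,
    na_molar = pool$na_molar), "partition_sum"), numeric(1))
  expect_equal(share, exp(lab) / (exp(lab) + S), tolerance = 1e-6)
})

test_that("phi = 0 limit recovers the plain pool curve and theta_ab grows with phi", {
  grid <- melting_grid(0, 90, 2)
  # vanishing phi: spike the pair into an overwhelming pool
  pool_big <- solution_spec(8, c_mass = 25, na_molar = 1)
  cq_tiny <- cq_spec("ACAGTCCT", "AGGACTGT", 1e-18, pool_big)
  ecq <- theta_e_cq(cq_tiny, grid)
  plain <- theta_fcg(pool_big, 0.5, grid)
  expect_equal(ecq$theta, plain$theta, tolerance = 1e-6)
  expect_lt(max(theta_ab(cq_tiny, grid)$theta), 1e-6)
  # theta_ab increases monotonically with phi at fixed T
  phis <- 10^seq(-2, 2, 1)
  th15 <- vapply(phis, function(phi) {
    pool <- solution_spec(8, c_molar = 100e-9 * 4^8 / phi, na_molar = 1)
    theta_ab(cq_spec("ACAGTCCT", "AGGACTGT", 100e-9, pool),
             kelvin(c(15, 16)))$theta[1]
  }, numeric(1))
  expect_true(all(diff(th15) > 0))
})

test_that("large phi converges to the two-state curve of the isolated pair", {
  grid <- melting_grid(0, 90, 2)
  p <- nn_params(na_molar = 1)
  pool <- solution_spec(8, c_molar = 100e-9 * 4^8 / 1e6, na_molar = 1)
  cq <- cq_spec("ACAGTCCT", "AGGACTGT", 100e-9, pool)
  expect_equal(cq$phi, 1e6, tolerance = 1e-9)
  ecq <- theta_e_cq(cq, grid)
  pair <- pair_melting_curve("ACAGTCCT", "AGGACTGT", 100e-9, p, grid)
  expect_lt(max(abs(ecq$theta - pair$theta)), 1e-3)
  ab <- theta_ab(cq, grid)
  expect_lt(max(abs(ab$theta - pair$theta)), 1e-3)
})

test_that("fluorophore stabilization lifts the phi = 1 low-T yield to about 30%", {
  pool <- solution_spec(8, c_mass = 16, na_molar = 0.15)
  # documented terminal stabilization, dG37 about -0.9 kcal/mol, with an
  # uncertainty band of roughly +-0.6 around it
  cq <- cq_spec("ACAGTCCT", "AGGACTGT", 100e-9, pool,
                dG_offset = c(dH = -6, dS = -16.5),
                dG_band = list(c(dH = -3, dS = -7.5),
                               c(dH = -9, dS = -24)))
  ab <- theta_ab(cq, melting_grid(0, 20, 5))
  expect_gt(ab$theta[1], 0.2)
  expect_lt(ab$theta[1], 0.4)
  lo <- attr(ab, "theta_lower")
  hi <- attr(ab, "theta_upper")
  expect_true(all(lo <= ab$theta + 1e-12 & ab$theta <= hi + 1e-12))
  # the band brackets the 30% reading
  expect_lt(lo[1], 0.3)
  expect_gt(hi[1], 0.3)
})

test_that("ionic strength moves theta_ab(phi) by less than the energy uncertainty band", {
  pool <- solution_spec(8, c_mass = 16, na_molar = 0.15)
  phi_grid <- 10^seq(-1, 1.5, length.out = 6)
  band_off <- list(c(dH = -3, dS = -7.5), c(dH = -9, dS = -24))
  th <- function(na, off = c(dH = -6, dS = -16.5)) {
    vapply(phi_grid, function(phi) {
      p <- solution_spec(8, c_molar = 100e-9 * 4^8 / phi, na_molar = na)
      theta_ab(cq_spec("ACAGTCCT", "AGGACTGT", 100e-9, p,
                       dG_offset = off), kelvin(c(15, 16)))$theta[1]
    }, numeric(1))
  }
  spread <- abs(th(1.0) - th(0.15))
  band_width <- th(0.15, band_off[[2]]) - th(0.15, band_off[[1]])
  expect_true(all(spread < pmax(band_width, 0.02)))
  # the convenience wrapper reports the same spread
  cq <- cq_spec("ACAGTCCT", "AGGACTGT", 100e-9, pool,
                dG_offset = c(dH = -6, dS = -16.5))
  tab <- salt_sensitivity_ab(cq, T = kelvin(15), salts = c(0.15, 1.0),
                             phi_grid = phi_grid)
  expect_equal(abs(tab$theta_1M - tab$theta_0.15M), spread,
               tolerance = 1e-9)
  # contrast: the ensemble melting temperature shifts by several degrees
  grid <- melting_grid(0, 95, 2)
  tm1 <- melting_temperature(theta_ensemble(
    solution_spec(8, c_mass = 25, na_molar = 1), grid))
  tm015 <- melting_temperature(theta_ensemble(
    solution_spec(8, c_mass = 25, na_molar = 0.15), grid))
  expect_gt(tm1 - tm015, 5)
})

test_that("an alpha-dependent salt term breaks the cancellation (two-class toy)", {
  # toy with the tagged pair against one competing defect class: when the
  # salt correction acts equally on both weights it cancels exactly in the
  # share; making it act on the competitor only shifts the share with salt
  T <- kelvin(15)
  RT <- 1.987204258e-3 * T
  share <- function(na, competitor_stacks) {
    w_ab <- exp(-(-50 - T * (-140 + 0.368 * 7 * log(na)) / 1000) / RT)
    w_comp <- exp(-(-44 - T * (-124 + 0.368 * competitor_stacks *
                                 log(na)) / 1000) / RT)
    w_ab / (w_ab + w_comp)
  }
  # equal stack counts: exact cancellation
  expect_equal(share(1.0, 7), share(0.15, 7), tolerance = 1e-12)
  # alpha-dependent counts: the share moves with ionic strength
  expect_gt(abs(share(1.0, 3) - share(0.15, 3)), 0.05)
})
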