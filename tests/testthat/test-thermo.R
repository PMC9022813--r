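test_that("reverse complement matches the printed tagged pair and is an involution", {
  expect_identical(complement_sequence("ACAGTCCT"), "AGGACTGT")
  expect_identical(complement_sequence("AT"), "AT")
  set.seed(11)
  for (s in random_sequences(10, 12))
    expect_identical(complement_sequence(complement_sequence(s)), s)
  expect_error(complement_sequence("ACGX"), "unknown symbol")
})

test_that("NN free energy equals an independent hand summation of the unified table", {
  p <- nn_params()  # 1 M: no salt correction
  seqs <- c("ATCGCAGT", "ACAGTCCT", "GT")
  for (s in seqs) {
    fe <- nn_free_energy_pair(s, complement_sequence(s), p)
    hand <- hand_nn_sum(s)
    expect_equal(fe$dH, unname(hand["dH"]), tolerance = 1e-12)
    expect_equal(fe$dS, unname(hand["dS"]), tolerance = 1e-12)
  }
  # a 2-mer has exactly one stack plus two initiation terms
  fe2 <- nn_free_energy_pair("GT", "AC", p)
  u <- unified_literal()
  expect_equal(fe2$dH, u$dH[["GT"]] + u$init_dH[["strong"]] +
                 u$init_dH[["weak"]])
  # duplex symmetry: reading the duplex from the other strand is identical
  feA <- nn_free_energy_pair("ATCGCAGT", "ACTGCGAT", p)
  feB <- nn_free_energy_pair("ACTGCGAT", "ATCGCAGT", p)
  expect_equal(feA$dH, feB$dH)
  expect_equal(feA$dS, feB$dS)
  expect_error(nn_free_energy_pair("ACGT", "TTTT", p), "reverse complement")
})

test_that("composition-averaged stacks are the quartet expectation", {
  p <- nn_params()
  u <- unified_literal()
  # f = 0.5: unweighted mean over all 16 ordered quartets
  av <- averaged_nn_params(0.5, p)
  expect_equal(unname(av$stack["dH"]), mean(u$dH), tolerance = 1e-12)
  expect_equal(unname(av$stack["dS"]), mean(u$dS), tolerance = 1e-12)
  # f = 1 equals the CG-only quartet mean (the all-CG counterfactual)
  av1 <- averaged_nn_params(1, p)
  cg <- c("CC", "CG", "GC", "GG")
  expect_equal(unname(av1$stack["dH"]), mean(u$dH[cg]))
  expect_equal(unname(av1$stack["dH"]),
               unname(all_cg_params(p)$stack_override["dH"]))
  # stronger composition means a more stabilizing averaged stack at 37 C
  g37 <- vapply(seq(0, 1, 0.25), function(f) {
    a <- averaged_nn_params(f, p)
    a$stack[["dH"]] - kelvin(37) * a$stack[["dS"]] / 1000
  }, numeric(1))
  expect_true(all(diff(g37) < 0))
  expect_error(averaged_nn_params(1.2, p), "f_CG")
})

test_that("salt correction is entropy-only, vanishes at 1 M and is log-linear", {
  expect_identical(salt_correct(-150, 7, 1.0), -150)
  corr <- function(na) salt_correct(0, 7, na)
  expect_equal(corr(0.01) / corr(0.1), 2, tolerance = 1e-12)
  expect_error(salt_correct(-150, 7, 0), "positive")
  # lower salt destabilizes: Tm drops for any duplex
  p1 <- nn_params(na_molar = 1.0)
  p015 <- nn_params(na_molar = 0.15)
  s <- "ATCGCAGT"
  tm1 <- two_state_tm(nn_free_energy_pair(s, complement_sequence(s), p1),
                      1e-5)
  tm015 <- two_state_tm(nn_free_energy_pair(s, complement_sequence(s),
                                            p015), 1e-5)
  expect_lt(tm015, tm1)
})

test_that("parametrized defect energies follow the averaged-stack construction", {
  p <- nn_params()
  av <- averaged_nn_params(0.5, p)
  # alpha = 0: (L-1) averaged stacks plus initiation, nothing else
  fe <- delta_g_parametrized(8, c(0, 0, 0, 0), 0.5, params = p)
  expect_equal(fe$dH, 7 * av$stack[["dH"]] + av$init[["dH"]])
  expect_equal(fe$dS, 7 * av$stack[["dS"]] + av$init[["dS"]])
  # an internal mismatch strictly destabilizes at every temperature
  fe_mm <- delta_g_parametrized(8, c(0, 0, 0, 1), 0.5, params = p)
  Ts <- kelvin(seq(0, 100, 5))
  expect_true(all(dG(fe_mm, Ts) > dG(fe, Ts)))
  # so does a terminal mismatch and a shift
  fe_e <- delta_g_parametrized(8, c(0, 1, 0, 0), 0.5, params = p)
  fe_s <- delta_g_parametrized(8, c(1, 0, 0, 0), 0.5, params = p)
  expect_true(all(dG(fe_e, Ts) > dG(fe, Ts)))
  expect_true(all(dG(fe_s, Ts) > dG(fe, Ts)))
  expect_error(delta_g_parametrized(8, c(0, 4, 4, 0), 0.5, params = p),
               "invalid defect")
})

test_that("defect free energy grows with the total error count", {
  p <- nn_params()
  # representative motif ladder at fixed |alpha| built from terminal-type
  # errors; dG at 37 C must increase monotonically with |alpha|
  ladder <- list(c(0, 0, 0, 0), c(0, 1, 0, 0), c(0, 1, 1, 0),
                 c(1, 1, 1, 0), c(1, 1, 1, 1))
  g37 <- vapply(ladder, function(a)
    dG(delta_g_parametrized(12, a, 0.5, params = p), kelvin(37)),
    numeric(1))
  expect_true(all(diff(g37) > 0))
  # and roughly linearly: a straight-line fit in |alpha| captures almost
  # all the variation across the full defect ladder
  tot <- vapply(ladder, function(a) sum(abs(a)), numeric(1))
  fit <- stats::lm(g37 ~ tot)
  expect_gt(summary(fit)$r.squared, 0.9)
})

test_that("two-state pair curve has the right limits, Tm and closed form", {
  p <- nn_params()
  s <- "ATCGCAGTATCG"
  curve <- pair_melting_curve(s, complement_sequence(s), 5e-6, p,
                              melting_grid(0, 95, 0.5))
  expect_true(all(curve$theta >= 0 & curve$theta <= 1))
  expect_true(all(diff(curve$theta) <= 1e-12))
  fe <- nn_free_energy_pair(s, complement_sequence(s), p)
  expect_gt(curve$theta_fun(kelvin(-20)), 0.999)
  expect_lt(curve$theta_fun(kelvin(120)), 0.01)
  # analytic Tm agrees with the curve root
  tm_closed <- two_state_tm(fe, 5e-6)
  tm_root <- melting_temperature(curve)
  expect_equal(tm_root, tm_closed, tolerance = 0.02)
  # theta at the analytic Tm is exactly 1/2
  expect_equal(curve$theta_fun(tm_closed), 0.5, tolerance = 1e-9)
  # mass action: doubling the concentration raises Tm
  expect_gt(two_state_tm(fe, 1e-5), tm_closed)
  expect_error(two_state_curve(fe, 0), "positive")
})

test_that("dG is continuous and increasing in T for stabilizing duplexes", {
  fe <- free_energy(-60, -160)
  Ts <- kelvin(seq(0, 100, 1))
  expect_true(all(diff(dG(fe, Ts)) > 0))
  expect_equal(dG(fe, 300), -60 + 300 * 160 / 1000)
})
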