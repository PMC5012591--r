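test_that("lognormal sampling follows the noise decomposition", {
  spec <- noise_spec()
  # zero noise: every cell exactly at the mean
  s0 <- noise_spec(eta_int = setNames(rep(0, 6), names(spec$means)),
                   eta_ext = setNames(rep(0, 6), names(spec$means)))
  x <- sample_protein_numbers(s0, 10, seed = 1)
  expect_equal(unname(x[1, ]), unname(spec$means), tolerance = 1e-12)
  expect_equal(max(apply(x, 2, sd)), 0)

  # ln-space SD adds in quadrature: sqrt(0.26^2 + 0.125^2) for CheR/CheB
  x2 <- sample_protein_numbers(spec, 100000, seed = 2)
  for (pr in c("CheR", "CheB"))
    expect_equal(sd(log(x2[, pr])), sqrt(0.26^2 + 0.125^2),
                 tolerance = 0.01)
  # reduced noise for the others
  expect_equal(sd(log(x2[, "CheY"])), 0.1 * sqrt(0.26^2 + 0.125^2),
               tolerance = 0.01)

  # pure extrinsic noise: operon partners perfectly rank-correlated
  s1 <- noise_spec(eta_int = setNames(rep(0, 6), names(spec$means)))
  x3 <- sample_protein_numbers(s1, 2000, seed = 3)
  expect_equal(cor(x3[, "CheR"], x3[, "CheB"], method = "spearman"), 1)
  # ...but independent of the other operon
  expect_lt(abs(cor(log(x3[, "CheR"]), log(x3[, "CheA"]))), 0.08)

  # determinism
  expect_identical(sample_protein_numbers(spec, 50, seed = 9),
                   sample_protein_numbers(spec, 50, seed = 9))
})

test_that("effective CheY-P averaging has the stated variance", {
  draws <- effective_Yp(rep(3, 10000), varYp = 0.04, n_eff = 8, seed = 5)
  expect_equal(var(draws$Yp), 0.04 / 8, tolerance = 0.05 * 0.04 / 8 * 20)
  expect_equal(mean(draws$Yp), 3, tolerance = 0.001)
  # n_eff -> infinity collapses onto the steady state
  d2 <- effective_Yp(3, 0.04, n_eff = 1e12, seed = 5)
  expect_equal(d2$Yp, 3, tolerance = 1e-4)
  # clipping at zero is counted
  d3 <- effective_Yp(rep(0.01, 2000), 1, 1, seed = 6)
  expect_gt(d3$n_clipped, 0)
  expect_true(all(d3$Yp >= 0))
})

test_that("population panels are deterministic and well-formed", {
  pop <- simulate_population_phenotypes(n_cells = 40, seed = 3,
                                        with_lna = TRUE)
  pop2 <- simulate_population_phenotypes(n_cells = 40, seed = 3,
                                         with_lna = TRUE)
  expect_identical(pop$tumble_bias, pop2$tumble_bias)
  expect_true(all(pop$tumble_bias >= 0 & pop$tumble_bias <= 1))
  expect_true(all(pop$N_R > 0 & pop$N_B > 0))
  expect_true(all(pop$n_eff >= 1))
  # no-LNA ablation with zero expression noise: all cells identical
  s0 <- noise_spec(eta_int = setNames(rep(0, 6), c("CheR", "CheB", "CheA",
                                                   "CheY", "CheZ", "T")),
                   eta_ext = setNames(rep(0, 6), c("CheR", "CheB", "CheA",
                                                   "CheY", "CheZ", "T")))
  pop0 <- simulate_population_phenotypes(spec = s0, n_cells = 5, seed = 1,
                                         with_lna = FALSE)
  expect_lt(diff(range(pop0$tumble_bias)), 1e-9)
})

test_that("variance-explained ratio matches a closed form", {
  spec <- noise_spec()
  # zero expression noise explains nothing
  s0 <- noise_spec(eta_int = setNames(rep(0, 6), names(spec$means)),
                   eta_ext = setNames(rep(0, 6), names(spec$means)))
  expect_equal(variance_explained(function(nr, nb) 0.2 + 0.01 * log10(nr),
                                  s0, n_cells = 500)$fraction, 0)
  # constant surface explains nothing
  expect_equal(variance_explained(function(nr, nb) rep(0.3, length(nr)),
                                  spec, n_cells = 500)$fraction, 0)
  # linear surface in log10(NR/NB): extrinsic part cancels, intrinsic
  # contributions add: var = beta^2 (2 eta_int^2) / ln(10)^2
  beta <- 0.08
  ve <- variance_explained(
    function(nr, nb) 0.2 + beta * log10(nr / nb), spec,
    observed_var = 0.093^2, n_cells = 200000, seed = 8)
  theo <- beta^2 * 2 * 0.125^2 / log(10)^2 / 0.093^2
  expect_equal(ve$fraction, theo, tolerance = 0.02)
  # affine rescaling of numerator and denominator leaves the ratio fixed
  ve2 <- variance_explained(
    function(nr, nb) 2 * (0.2 + beta * log10(nr / nb)) + 1, spec,
    observed_var = 4 * 0.093^2, n_cells = 200000, seed = 8)
  expect_equal(ve2$fraction, ve$fraction, tolerance = 1e-10)
})
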