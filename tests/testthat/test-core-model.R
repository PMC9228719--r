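# Equilibrium speciation, the coupling factor, the forward diffusion model,
# and the Stokes-Einstein complex-diffusivity estimator.

test_that("solve_equilibrium handles the no-binding and no-guest limits", {
  sp <- solve_equilibrium(composition(0.01, 0.01), k_assoc = 0)
  expect_identical(sp$complex, 0)
  expect_identical(sp$free_drug, 0.01)
  expect_identical(sp$free_carrier, 0.01)

  sp <- solve_equilibrium(composition(0, 0.007), k_assoc = 10)
  expect_identical(sp$complex, 0)
  expect_equal(sp$free_carrier, 0.007)

  expect_error(solve_equilibrium(composition(0.01, 0.01), -1),
               "non-negative")
  expect_error(composition(-0.01, 0.01), "non-negative")
})

test_that("closed-form speciation agrees with the fixed-point oracle", {
  # spot value used elsewhere in the suite
  sp <- solve_equilibrium(composition(0.0035, 0.0035), 10)
  expect_equal(sp$complex,
               speciation_fixed_point(0.0035, 0.0035, 10), tolerance = 1e-10)

  set.seed(101)
  for (i in 1:1000) {
    c1 <- stats::runif(1, 0, 0.05)
    c2 <- stats::runif(1, 0, 0.05)
    k <- stats::runif(1, 0, 500)
    sp <- solve_equilibrium(composition(c1, c2), k)
    expect_lt(abs(sp$complex - speciation_fixed_point(c1, c2, k)), 1e-10)
    # mass balances and the equilibrium relation
    expect_lt(abs(sp$free_drug + sp$complex - c1), 1e-12)
    expect_lt(abs(sp$free_carrier + sp$complex - c2), 1e-12)
    expect_lt(abs(k * sp$free_drug * sp$free_carrier - sp$complex), 1e-10)
    expect_true(all(c(sp$free_drug, sp$free_carrier, sp$complex) >= 0))
  }
})

test_that("r_factor reproduces hand evaluations and its algebraic bounds", {
  expect_identical(r_factor(composition(0.01, 0.02), 0), 1)
  expect_equal(r_factor(composition(0, 0.010), 10), 1 / 1.1,
               tolerance = 1e-12)
  expect_equal(r_factor(composition(0.0035, 0.0035), 10), 1.14^(-0.5),
               tolerance = 1e-12)

  set.seed(102)
  for (i in 1:500) {
    c1 <- stats::runif(1, 0, 0.05); c2 <- stats::runif(1, 0, 0.05)
    k <- stats::runif(1, 0, 500)
    r <- r_factor(composition(c1, c2), k)
    expect_gt(r, 0)
    expect_lte(r, 1)
    expect_gte(r, 1 / (1 + k * (c1 + c2)) - 1e-12)
  }
})

test_that("predict_dmatrix matches hand evaluation of the coupled model", {
  dm <- predict_dmatrix(composition(0.0035, 0.0035), beta_cd_sys(10))
  # hand evaluation: R = 1.14^(-1/2), bracket term = 1 at c1 = c2
  r <- 1.14^(-0.5)
  expect_equal(dm$d11, 0.5 * ((1.050 + 0.390) + (1.050 - 0.390) * r),
               tolerance = 1e-12)
  expect_equal(dm$d12, 0.5 * ((0.390 - 1.050) + (1.050 - 0.390) * r),
               tolerance = 1e-12)
  expect_equal(dm$d21, 0.5 * ((0.390 - 0.399) + (0.399 - 0.390) * r),
               tolerance = 1e-12)
  expect_equal(dm$d22, 0.5 * ((0.399 + 0.390) + (0.399 - 0.390) * r),
               tolerance = 1e-12)
  # rounded values
  expect_equal(round(dm$d11, 3), 1.029)
  expect_equal(round(dm$d12, 4), -0.0209)
  expect_equal(round(dm$d21, 6), -0.000285)
  expect_equal(round(dm$d22, 3), 0.399)
})

test_that("K = 0 gives an exactly diagonal matrix for every composition", {
  set.seed(103)
  sys0 <- binding_system(beta_cd_species(), 0)
  for (i in 1:200) {
    dm <- predict_dmatrix(random_composition(), sys0)
    expect_identical(dm$d12, 0)
    expect_identical(dm$d21, 0)
    expect_equal(dm$d11, 1.050)
    expect_equal(dm$d22, 0.399)
  }
})

test_that("tracer limit equals the fast-exchange average", {
  sys <- beta_cd_sys(10)
  dm <- predict_dmatrix(composition(0, 0.010), sys)
  expect_equal(dm$d11, (1.050 + 10 * 0.010 * 0.390) / (1 + 10 * 0.010),
               tolerance = 1e-12)
  expect_equal(round(dm$d11, 3), 0.990)
  set.seed(104)
  for (i in 1:100) {
    c2 <- stats::runif(1, 1e-4, 0.05); k <- stats::runif(1, 0, 100)
    dm <- predict_dmatrix(composition(0, c2), binding_system(beta_cd_species(), k))
    f <- k * c2 / (1 + k * c2)
    expect_lt(abs(dm$d11 - ((1 - f) * 1.050 + f * 0.390)), 1e-12)
  }
})

test_that("at c1 = c2 the cross-coefficient ratio collapses to species terms", {
  set.seed(105)
  for (i in 1:100) {
    c <- stats::runif(1, 1e-4, 0.05); k <- stats::runif(1, 0.1, 100)
    dm <- predict_dmatrix(composition(c, c), beta_cd_sys(k))
    expect_equal(dm$d12 / dm$d21, (1.050 - 0.390) / (0.399 - 0.390),
                 tolerance = 1e-9)
  }
})

test_that("Stokes-Einstein complex diffusivity behaves as volume additivity", {
  d <- complex_diffusivity_stokes_einstein(1.050, 0.399)
  expect_equal(d, (1.050^-3 + 0.399^-3)^(-1 / 3), tolerance = 1e-12)
  expect_lt(abs(d - 0.390) / 0.390, 0.01)  # published estimate, within 1%
  # symmetry, equal partners, vanishing partner
  expect_identical(d, complex_diffusivity_stokes_einstein(0.399, 1.050))
  expect_equal(complex_diffusivity_stokes_einstein(0.7, 0.7),
               0.7 * 2^(-1 / 3), tolerance = 1e-12)
  expect_equal(complex_diffusivity_stokes_einstein(1.0, 1e6), 1.0,
               tolerance = 1e-12)
  set.seed(106)
  for (i in 1:100) {
    a <- stats::runif(1, 0.1, 2); b <- stats::runif(1, 0.1, 2)
    expect_lt(complex_diffusivity_stokes_einstein(a, b), min(a, b))
  }
  expect_error(complex_diffusivity_stokes_einstein(-1, 1), "positive")
  expect_error(complex_diffusivity_stokes_einstein(1, 0), "positive")
})

test_that("counter-transport maxima use only counter-current rows", {
  tab <- beta_cd_table()
  ct <- countertransport_ratios(tab)
  expect_equal(round(ct$max_drug_per_carrier, 2), 0.21)
  expect_equal(round(ct$max_carrier_per_drug, 2), 0.03)
  expect_equal(nrow(ct$per_row), 7L)
  # rows with positive cross coefficients are reported but excluded
  pos12 <- which(!ct$per_row$counter_current_12)
  expect_true(length(pos12) > 0)
  expect_true(all(tab$d12[pos12] >= 0))

  one <- data.frame(c1 = 0.01, c2 = 0.01, x1 = 0.5,
                    d11 = 1, sd11 = NA_real_, d12 = 0, sd12 = NA_real_,
                    d21 = 0, sd21 = NA_real_, d22 = 0.5, sd22 = NA_real_)
  ct0 <- countertransport_ratios(one)
  expect_identical(ct0$max_drug_per_carrier, 0)
  expect_identical(ct0$max_carrier_per_drug, 0)
  expect_error(countertransport_ratios(one[0, ]), "empty")
})
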