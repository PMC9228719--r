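# Association-constant fitting, bootstrap, solubilized fractions and regime
# classification.

test_that("solubilized fractions match the two-state relation exactly", {
  s1 <- solubilized_fraction(1.001, 1.168, 0.100)
  expect_equal(s1$s, (1.168 - 1.001) / (1.168 - 0.100), tolerance = 1e-12)
  expect_equal(round(s1$s, 3), 0.156)
  s2 <- solubilized_fraction(0.965, 1.168, 0.100)
  expect_equal(round(s2$s, 3), 0.190)
  # no attenuation, clipping, and domain errors
  expect_identical(solubilized_fraction(1.168, 1.168, 0.1)$s, 0)
  expect_warning(s3 <- solubilized_fraction(1.2, 1.168, 0.1), "clip")
  expect_identical(s3$s, 0)
  expect_error(solubilized_fraction(1.0, 0.1, 1.168), "exceed")
})

test_that("solubilized fraction is monotone and scale invariant", {
  s <- sapply(seq(0.2, 1.1, by = 0.1), function(d11)
    solubilized_fraction(d11, 1.168, 0.100)$s)
  expect_true(all(diff(s) < 0))  # strictly decreasing in the tracer D
  for (f in c(0.5, 2, 10)) {
    expect_equal(solubilized_fraction(1.001 * f, 1.168 * f, 0.100 * f)$s,
                 solubilized_fraction(1.001, 1.168, 0.100)$s,
                 tolerance = 1e-12)
  }
})

test_that("deviation percentages reproduce the published diagnostics", {
  expect_equal(deviation_percent(mean(c(1.011, 1.023)), 1.168), 12.92808,
               tolerance = 1e-5)
  expect_equal(round(deviation_percent(mean(c(1.011, 1.023)), 1.168)), 13)
  expect_equal(round(deviation_percent(0.965, 1.168)), 17)
  expect_identical(deviation_percent(1.05, 1.05), 0)
})

test_that("equilibrium bound fraction matches its closed form", {
  expect_equal(bound_fraction_equilibrium(0.010, 10), 0.1 / 1.1,
               tolerance = 1e-12)
  expect_identical(bound_fraction_equilibrium(0.010, 0), 0)
  expect_error(bound_fraction_equilibrium(-0.1, 10), "non-negative")
})

test_that("concentration regimes are classified with the boundary above", {
  expect_identical(classify_regime(composition(0, 0.004), 0.0083),
                   "below_cmc")
  expect_identical(classify_regime(composition(0, 0.020), 0.0083),
                   "above_cmc")
  expect_identical(classify_regime(composition(0, 0.0083), 0.0083),
                   "above_cmc")
  expect_identical(classify_regime(composition(0, 0.004)), "non_micellar")
})

test_that("fit_k recovers the generating K from a noiseless table", {
  sp <- beta_cd_species()
  des <- synthetic_design(true_system = binding_system(sp, 5),
                          noise_main = 0, noise_cross = 0, seed = 1)
  tab <- generate_dtable(des)
  fit <- fit_k(tab, sp, n_boot = 0)
  expect_equal(fit$k_hat, 5, tolerance = 1e-6)
  expect_lt(fit$weighted_sse, 1e-15)
  expect_true(all(abs(fit$residuals) < 1e-12))
})

test_that("fit_k objective agrees with a brute-force re-evaluation", {
  # independent inline implementation of the coupled-diffusion equations
  brute_sse <- function(k, tab, df, dcar, dc, sd_main, sd_cross) {
    tot <- 0
    for (i in seq_len(nrow(tab))) {
      c1 <- tab$c1[i]; c2 <- tab$c2[i]
      r <- ((1 + k * (c2 - c1))^2 + 4 * k * c1)^(-1 / 2)
      br <- (1 - k * (c2 - c1)) * r
      m11 <- ((df + dc) + (df - dc) * br) / 2
      m12 <- ((dc - df) + (df - dc) * br) / 2
      m21 <- ((dc - dcar) + (dcar - dc) * br) / 2
      m22 <- ((dcar + dc) + (dcar - dc) * br) / 2
      tot <- tot + ((tab$d11[i] - m11) / sd_main)^2 +
        ((tab$d12[i] - m12) / sd_cross)^2 +
        ((tab$d21[i] - m21) / sd_cross)^2 +
        ((tab$d22[i] - m22) / sd_main)^2
    }
    tot
  }
  tab <- beta_cd_table()
  sp <- beta_cd_species()
  set.seed(108)
  for (k in stats::runif(50, 0, 100)) {
    expect_equal(ternadiff:::.kfit_sse(k, tab, ternadiff:::.fit_sds(tab, "class"),
                                       sp, c("d11", "d12", "d21", "d22")),
                 brute_sse(k, tab, 1.050, 0.399, 0.390, 0.02, 0.05),
                 tolerance = 1e-10)
  }
})

test_that("the fitted K sits at a local minimum of the grid objective", {
  tab <- beta_cd_table()
  sp <- beta_cd_species()
  fit <- fit_k(tab, sp, n_boot = 0)
  sds <- ternadiff:::.fit_sds(tab, "class")
  f <- function(k) ternadiff:::.kfit_sse(k, tab, sds, sp, fit$coefficients)
  expect_lte(fit$weighted_sse, f(fit$k_hat + 0.1))
  expect_lte(fit$weighted_sse, f(max(fit$k_hat - 0.1, 0)))
  expect_equal(fit$weighted_sse, f(fit$k_hat), tolerance = 1e-12)
})

test_that("regime filtering selects the fit rows for micellar carriers", {
  tab <- sds_table()
  sp <- sds_species()
  fit <- fit_k(tab, sp, cmc = 0.0083, n_boot = 0)
  expect_identical(sum(fit$rows_used), 3L)
  expect_true(all(tab$c2[fit$rows_used] >= 0.0083))
  expect_identical(fit$regime[1], "below_cmc")
  fit_all <- fit_k(tab, sp, cmc = 0.0083, regime = "all", n_boot = 0)
  expect_identical(sum(fit_all$rows_used), 7L)
  expect_error(fit_k(tab[1:2, ], sp, cmc = 0.0083, n_boot = 0),
               "at least 2 rows")
})

test_that("printed-SD weighting is available and changes the estimate", {
  tab <- beta_cd_table()
  sp <- beta_cd_species()
  f_class <- fit_k(tab, sp, weights = "class", n_boot = 0)
  f_printed <- fit_k(tab, sp, weights = "printed", n_boot = 0)
  expect_false(isTRUE(all.equal(f_class$k_hat, f_printed$k_hat)))
})

test_that("bootstrap interval is degenerate for a noiseless table", {
  sp <- beta_cd_species()
  des <- synthetic_design(true_system = binding_system(sp, 5),
                          noise_main = 0, noise_cross = 0, seed = 1)
  tab <- generate_dtable(des)
  expect_warning(ci <- bootstrap_k_ci(tab, sp, n_boot = 100, seed = 1),
                 "zero width")
  expect_identical(ci[1], ci[2])
})

test_that("bootstrap interval contains the estimate and is deterministic", {
  tab <- beta_cd_table()
  sp <- beta_cd_species()
  fit <- fit_k(tab, sp, n_boot = 0)
  ci1 <- bootstrap_k_ci(tab, sp, n_boot = 200, seed = 42)
  ci2 <- bootstrap_k_ci(tab, sp, n_boot = 200, seed = 42)
  expect_identical(ci1, ci2)
  expect_lte(ci1[1], fit$k_hat)
  expect_gte(ci1[2], fit$k_hat)
})

test_that("replicating the table shrinks the bootstrap interval", {
  sp <- beta_cd_species()
  des <- synthetic_design(true_system = binding_system(sp, 10), seed = 11)
  tab <- generate_dtable(des)
  tab4 <- do.call(rbind, list(tab, tab, tab, tab))
  ci1 <- bootstrap_k_ci(tab, sp, n_boot = 300, seed = 5)
  ci4 <- bootstrap_k_ci(tab4, sp, n_boot = 300, seed = 5)
  expect_lt(diff(ci4), diff(ci1))
})

test_that("bootstrap intervals cover the generating K in most replicates", {
  # scaled-down coverage check: 30 outer replicates, 150 bootstrap draws
  sp <- beta_cd_species()
  hits <- sum(sapply(1:30, function(s) {
    des <- synthetic_design(true_system = binding_system(sp, 10),
                            seed = 5000 + s)
    ci <- bootstrap_k_ci(generate_dtable(des), sp, n_boot = 150, seed = 42)
    ci[1] <= 10 && 10 <= ci[2]
  }))
  expect_gte(hits, 24)  # >= 80% at this replicate count
})
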