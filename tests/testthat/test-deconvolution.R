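# Intensity histograms, basis transformation and reduced chi-squared
# mixture fitting.

test_that("histograms tally and conserve counts", {
  h <- build_histogram(c(5, 5, 5), n_bins = 1, range = c(0, 10))
  expect_equal(h$counts, 3)
  x <- gen_monomer_intensities(10000, monomer_model(), seed = 1)
  h <- build_histogram(x, n_bins = 50)
  expect_equal(sum(h$counts), 10000)
  expect_equal(h$n_total, 10000)
  expect_error(build_histogram(numeric()), "non-empty")
  expect_error(build_histogram(c(1, -2)), "positive")
})

test_that("histogram CDF matches the empirical CDF at bin edges", {
  x <- gen_monomer_intensities(2000, monomer_model(), seed = 2)
  h <- build_histogram(x, n_bins = 40, range = c(0, max(x)))
  ecdf_x <- stats::ecdf(x)
  at_edges <- smolsensor:::hist_cdf(h, h$bin_edges)
  expect_lt(max(abs(at_edges - ecdf_x(h$bin_edges))), 1 / 2000 + 1e-12)
})

test_that("basis derivation is the identity at M = 1 in both modes", {
  x <- gen_monomer_intensities(3000, monomer_model(), seed = 3)
  rho1 <- build_histogram(x)
  for (mode in c("scale", "convolve")) {
    b <- derive_basis(rho1, M = 1, mode = mode)
    expect_equal(b$rho[, 1], rho1$counts / rho1$n_total, tolerance = 1e-12)
    expect_equal(b$bin_edges, rho1$bin_edges)
  }
  expect_error(derive_basis(rho1, M = 0), ">= 1")
})

test_that("scale mode doubles the mean; convolve mode doubles the variance", {
  x <- gen_monomer_intensities(5000, monomer_model(), seed = 4)
  rho1 <- build_histogram(x)
  half_bin <- diff(rho1$bin_edges[1:2]) / 2
  bs <- derive_basis(rho1, M = 2, mode = "scale")
  m1 <- smolsensor:::hist_mean(smolsensor:::basis_component_histogram(bs, 1))
  m2 <- smolsensor:::hist_mean(smolsensor:::basis_component_histogram(bs, 2))
  expect_lt(abs(m2 - 2 * m1), half_bin)
  bc <- derive_basis(rho1, M = 2, mode = "convolve")
  v1 <- smolsensor:::hist_var(smolsensor:::basis_component_histogram(bc, 1))
  v2 <- smolsensor:::hist_var(smolsensor:::basis_component_histogram(bc, 2))
  expect_lt(abs(v2 / (2 * v1) - 1), 0.03)
  # the two transformations genuinely diverge at order 2
  vs2 <- smolsensor:::hist_var(smolsensor:::basis_component_histogram(bs, 2))
  expect_gt(vs2 / v2, 1.5)
})

test_that("model histograms are reproducible and handle n = 0", {
  rho1 <- build_histogram(gen_monomer_intensities(2000, monomer_model(),
                                                  seed = 5))
  b <- derive_basis(rho1, M = 3)
  h0 <- simulate_model_histogram(b, c(0.5, 0.3, 0.2), 0)
  expect_true(all(h0$counts == 0))
  h1 <- simulate_model_histogram(b, c(0.5, 0.3, 0.2), 1000, seed = 9)
  h2 <- simulate_model_histogram(b, c(0.5, 0.3, 0.2), 1000, seed = 9)
  expect_identical(h1$counts, h2$counts)
})

test_that("pure-monomer draws are chi-squared consistent with the basis", {
  rho1 <- build_histogram(gen_monomer_intensities(4000, monomer_model(),
                                                  seed = 6))
  b <- derive_basis(rho1, M = 1)
  h <- simulate_model_histogram(b, 1, 20000, seed = 10)
  stat <- reduced_chi2(h$counts, 20000 * b$rho[, 1])
  expect_gt(stat, 0.7)
  expect_lt(stat, 1.3)
})

test_that("reduced chi-squared matches hand arithmetic", {
  expect_equal(as.numeric(reduced_chi2(c(10, 20, 30), c(10, 20, 30))), 0)
  # 3 bins, no pooling: (10-15)^2/15 + (20-15)^2/15 = 10/3; dof = 2
  s <- reduced_chi2(c(10, 20, 30), c(15, 15, 30))
  expect_equal(as.numeric(s), (10 / 3) / 2)
  expect_equal(attr(s, "dof"), 2L)
  # doubling the expected counts changes the statistic per the formula
  s2 <- reduced_chi2(c(10, 20, 30), c(30, 30, 60))
  expect_equal(as.numeric(s2),
               (400 / 30 + 100 / 30 + 900 / 60) / 2)
  # underfull bins are pooled: (1,1,1,1,1) -> one group of 5
  s3 <- reduced_chi2(c(2, 1, 0, 1, 1, 12), c(1, 1, 1, 1, 1, 10))
  expect_equal(attr(s3, "n_bins"), 2L)
  expect_equal(as.numeric(s3), ((5 - 5)^2 / 5 + (12 - 10)^2 / 10) / 1)
  expect_error(reduced_chi2(c(10, 10), c(10, 10), n_free_params = 1),
               "dof")
})

test_that("chi-squared of a Poisson resample is near one", {
  set.seed(11)
  expected <- rep(50, 45)
  obs <- stats::rpois(45, expected)
  stat <- reduced_chi2(obs, expected)
  expect_gt(stat, 0.7)
  expect_lt(stat, 1.3)
})

test_that("mixture fits return a valid simplex and refuse thin data", {
  rho1 <- build_histogram(gen_monomer_intensities(3000, monomer_model(),
                                                  seed = 12))
  b <- derive_basis(rho1, M = 3)
  h <- simulate_model_histogram(b, c(0.6, 0.3, 0.1), 2000, seed = 13)
  fit <- fit_mixture(h, b, seed = 14)
  expect_equal(sum(fit$fractions), 1, tolerance = 1e-12)
  expect_true(all(fit$fractions >= 0))
  thin <- simulate_model_histogram(b, c(1, 0, 0), 50, seed = 15)
  expect_error(fit_mixture(thin, b), "at least 100")
})

test_that("a pure monomer population fits as nearly all monomer", {
  rho1 <- build_histogram(gen_monomer_intensities(5000, monomer_model(),
                                                  seed = 16))
  b <- derive_basis(rho1, M = 3)
  h <- simulate_model_histogram(b, c(1, 0, 0), 5000, seed = 17)
  fit <- fit_mixture(h, b, seed = 18)
  expect_gte(fit$fractions[1], 0.95)
  expect_gt(fit$chi2_red, 0.5)
  expect_lt(fit$chi2_red, 1.5)
})

test_that("monomer fractions are recovered across the mixing grid", {
  # mean absolute error of the monomer fraction < 0.03 over
  # {1.0, 0.981, 0.9, 0.7, 0.5} x 20 seeds, with dimer balance
  errs <- c()
  chi2s <- c()
  for (f1 in c(1.0, 0.981, 0.9, 0.7, 0.5)) {
    fr <- c(f1, (1 - f1) * 0.7, (1 - f1) * 0.3)
    for (s in 1:20) {
      rho1 <- build_histogram(
        gen_monomer_intensities(5000, monomer_model(), seed = 600 + s))
      b <- derive_basis(rho1, M = 3)
      h <- simulate_model_histogram(b, fr, 5000, seed = 700 + s)
      fit <- fit_mixture(h, b, seed = 800 + s)
      errs <- c(errs, abs(fit$fractions[1] - f1))
      chi2s <- c(chi2s, fit$chi2_red)
    }
  }
  expect_lt(mean(errs), 0.03)
  # fit-quality calibration: generating model is in the basis
  expect_gt(stats::median(chi2s), 0.7)
  expect_lt(stats::median(chi2s), 1.4)
})

test_that("recovered fractions are stable under rebinning", {
  m <- monomer_model()
  mono <- function(s) {
    mix <- gen_multimer_mixture(5000, c(0.981, 0.019, 0), m,
                                mode = "scale", seed = 20)
    rho1 <- build_histogram(gen_monomer_intensities(5000, m, seed = 21),
                            n_bins = s)
    b <- derive_basis(rho1, M = 3)
    eh <- build_histogram(mix$intensity, n_bins = 3 * s,
                          range = range(b$bin_edges))
    fit_mixture(eh, b, seed = 22)$fractions[1]
  }
  expect_lt(abs(mono(50) - mono(100)), 0.02)
})
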