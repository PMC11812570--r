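# Two-phase cooperative kinetics: model evaluation, fitting, rates,
# bootstrap intervals and trace normalizations.

test_that("model evaluation honours the piecewise definition", {
  kp <- kinetic_params(2, 2, 1, 2, 5, F0 = 0.7)
  expect_equal(model_eval(kp, -1), 0.7)
  # half-maximum of the synthesis phase when degradation is negligible
  kp2 <- kinetic_params(1, 2, 1, 2, 1e6)
  expect_equal(model_eval(kp2, 1), 0.5, tolerance = 1e-6)
  # both Hill terms saturate at long times and the difference vanishes
  kp3 <- kinetic_params(3, 2, 0.9, 2, 2)
  expect_lt(abs(model_eval(kp3, 100 * 2)), 1e-3 * 3)
  expect_error(kinetic_params(1, 2, -1, 2, 1), "> 0")
})

test_that("the noiseless model peaks once and decays to zero", {
  kp <- kinetic_params(1, 2, 0.9, 2, 4)
  t <- seq(0.01, 60, 0.01)
  f <- model_eval(kp, t)
  d <- diff(f)
  flips <- sum(diff(sign(d[d != 0])) != 0)
  expect_equal(flips, 1)            # exactly one interior maximum
  expect_lt(abs(f[length(f)]), 5e-3)
  expect_gt(max(f), 0)
})

test_that("noiseless fits recover the generating parameters", {
  kp <- recovery_params()
  tc <- gen_timecourse(kp, recovery_grid(), noise_sd = 0)
  init <- kinetic_params(kp$F_max * 1.2, kp$n_syn * 0.8,
                         kp$tau_syn * 1.2, kp$n_deg * 1.2,
                         kp$tau_deg * 0.8)
  fit <- fit_timecourse(tc, init = init)
  expect_true(fit$converged)
  for (p in c("F_max", "n_syn", "tau_syn", "n_deg", "tau_deg"))
    expect_lt(abs(fit$params[[p]] / kp[[p]] - 1), 1e-4)
})

test_that("rate constants are exact reciprocals of the timescales", {
  expect_equal(rate_constants(kinetic_params(1, 2, 1, 2, 1))$k_syn, 1)
  expect_equal(rate_constants(kinetic_params(1, 2, 1 / 1.02, 2, 1))$k_syn,
               1.02)
  expect_equal(rate_constants(kinetic_params(1, 2, 1, 2, 1 / 0.34))$k_deg,
               0.34)
})

test_that("rate estimates sharpen as noise shrinks", {
  kp <- recovery_params()
  tg <- recovery_grid()
  med_err <- vapply(c(0.10, 0.05, 0.01), function(sig) {
    errs <- vapply(1:25, function(i) {
      tc <- gen_timecourse(kp, tg, noise_sd = sig, seed = 3000 + i)
      fit <- fit_timecourse(tc)
      if (!fit$converged) return(NA_real_)
      abs(fit$rates$k_syn - 1.09)
    }, numeric(1))
    stats::median(errs, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("fitting in tau agrees with fitting directly in rate constants", {
  tc <- gen_timecourse(recovery_params(), recovery_grid(),
                       noise_sd = 0.05, seed = 77)
  fit <- fit_timecourse(tc)
  # independent route: same bounded least squares parameterized in k = 1/tau
  y <- tc$F[tc$t >= 0]
  t <- tc$t[tc$t >= 0]
  mk <- function(t, F_max, n_syn, k_syn, n_deg, k_deg)
    F_max * (t^n_syn / (t^n_syn + (1 / k_syn)^n_syn) -
               t^n_deg / (t^n_deg + (1 / k_deg)^n_deg))
  kfit <- minpack.lm::nlsLM(
    y ~ mk(t, F_max, n_syn, k_syn, n_deg, k_deg),
    start = list(F_max = fit$params$F_max, n_syn = fit$params$n_syn,
                 k_syn = fit$rates$k_syn, n_deg = fit$params$n_deg,
                 k_deg = fit$rates$k_deg),
    lower = c(0, 0.5, 0.01, 0.5, 0.01), upper = c(10, 8, 20, 8, 20))
  # the surface is locally flat in correlated directions, so the two
  # routes agree on the objective tightly and on the rates to ~optimizer
  # step size
  expect_lt(abs(sum(residuals(kfit)^2) / fit$rss - 1), 0.005)
  expect_lt(abs(coef(kfit)[["k_syn"]] / fit$rates$k_syn - 1), 0.02)
  expect_lt(abs(coef(kfit)[["k_deg"]] / fit$rates$k_deg - 1), 0.02)
})

test_that("bootstrap intervals degenerate on noiseless data and bracket the fit", {
  tc <- gen_timecourse(recovery_params(), recovery_grid(), noise_sd = 0)
  ci <- bootstrap_ci(tc, n_boot = 100, seed = 1)
  expect_lt(ci["k_syn", "upper"] - ci["k_syn", "lower"],
            1e-3 * ci["k_syn", "estimate"])
  tc2 <- gen_timecourse(recovery_params(), recovery_grid(),
                        noise_sd = 0.05, seed = 2)
  ci2 <- bootstrap_ci(tc2, n_boot = 120, seed = 3)
  expect_true(all(ci2$lower <= ci2$estimate & ci2$estimate <= ci2$upper))
  expect_error(bootstrap_ci(tc2, n_boot = 50), "at least 100")
})

test_that("peak normalization maps baseline to 0, peak to 1, idempotently", {
  tc <- time_course(seq(-2, 10, 0.5),
                    c(rep(10, 4), 10 + 20 * sin(seq(0, pi,
                                                    length.out = 21))))
  nz <- normalize_to_max(tc)
  expect_equal(max(nz$F), 1)
  expect_equal(mean(nz$F[nz$t < 0]), 0)
  expect_equal(normalize_to_max(nz)$F, nz$F, tolerance = 1e-12)
  expect_equal(which.max(nz$F), which.max(tc$F))
  expect_error(normalize_to_max(time_course(-2:2, rep(5, 5))),
               "no response")
})

test_that("fold change over baseline follows its definition", {
  flat <- time_course(seq(-2, 5, 0.5), rep(4, 15))
  expect_equal(fold_change_over_baseline(flat), 0)
  tc <- time_course(c(-2, -1, 0, 1, 2), c(3, 3, 4, 6, 5))
  expect_equal(fold_change_over_baseline(tc), 100)
  # a generator set to a 7x peak gives the 600% fold change
  tc7 <- time_course(c(-2, -1, 0, 1), c(1, 1, 3, 7))
  expect_equal(fold_change_over_baseline(tc7), 600)
  expect_error(fold_change_over_baseline(time_course(0:3, 1:4)),
               "pre-stimulus")
})
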