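test_that("S(0) = 1, S is non-increasing and vanishes at infinity for every family", {
  grid <- c(seq(0, 60, by = 0.25), seq(61, 600, by = 7))
  for (m in family_zoo()) {
    s <- survival_prob(m, grid)
    expect_equal(s[1], 1, info = m$family)
    expect_true(all(diff(s) <= 1e-12), info = m$family)
    expect_true(all(s >= 0 & s <= 1), info = m$family)
    expect_lt(survival_prob(m, 1e8), 1e-8)
  }
  expect_lt(survival_prob(parametric_survival("loglogistic", 1.941, 0.06522),
                          1e6), 1e-9)
  expect_error(survival_prob(family_zoo()$weibull, -1), "0")
})

test_that("closed-form medians agree with a root-finding oracle", {
  for (m in c(family_zoo(), table1_models())) {
    expect_equal(median_time(m), median_by_root(m), tolerance = 1e-7,
                 info = m$family)
    expect_equal(survival_prob(m, median_time(m)), 0.5, tolerance = 1e-7)
  }
  expect_equal(median_time(parametric_survival("loglogistic", 1, 1)), 1)
})

test_that("base-case log-logistic medians land on the clinically reported months", {
  m <- table1_models()
  # (1/lambda)^(1/gamma), cross-checked by root-finding in the oracle test
  expect_equal(median_time(m$lp_pfs), 6.7, tolerance = 0.01)
  expect_equal(median_time(m$lp_os), 16.2, tolerance = 0.01)
  expect_equal(median_time(m$chemo_pfs), 4.1, tolerance = 0.01)
  expect_equal(median_time(m$chemo_os), 11.8, tolerance = 0.01)
})

test_that("quantile and survival functions are mutual inverses", {
  for (m in family_zoo()) {
    p <- c(0.05, 0.25, 0.5, 0.9)
    expect_equal(1 - survival_prob(m, survival_quantile(m, p)), p,
                 tolerance = 1e-7, info = m$family)
  }
})

test_that("Kaplan-Meier estimate is the product-limit estimator", {
  km <- km_estimate(pseudo_ipd(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(km$time, c(0, 1, 2, 3))
  expect_equal(km$survival, c(1, 2/3, 1/3, 0))

  # censoring shrinks the risk set without a step
  km2 <- km_estimate(pseudo_ipd(c(1, 1.5, 2), c(1, 0, 1)))
  expect_equal(km2$time, c(0, 1, 2))
  expect_equal(km2$survival, c(1, 2/3, 0))

  all_cens <- km_estimate(pseudo_ipd(c(1, 2, 3), c(0, 0, 0)))
  expect_true(all(all_cens$survival == 1))
  expect_error(km_estimate(pseudo_ipd(numeric(0), integer(0))))
})

test_that("KM of a large simulated cohort stays inside the Greenwood band around truth", {
  m <- family_zoo()$loglogistic
  ipd <- generate_pseudo_ipd(sim_spec(m, 1000, admin_censor_time = 60,
                                      random_censor_rate = 0.1, seed = 42))
  km <- km_estimate(ipd)
  probe <- c(3, 6, 12, 24, 48)
  est <- km_survival_at(km, probe)
  se <- km$std_err[findInterval(probe, km$time)]   # step lookup, like S itself
  truth <- survival_prob(m, probe)
  # 99% pointwise band: five probes at 95% each would be expected to
  # produce an occasional excursion even for a correct estimator
  expect_true(all(abs(est - truth) <= 2.576 * se))
})

test_that("exponential fit reproduces the closed-form censored MLE", {
  ipd <- pseudo_ipd(c(2, 5, 7, 1.5, 9, 3), c(1, 1, 0, 1, 0, 1))
  f <- fit_parametric(ipd, "exponential")
  expect_equal(f$model$scale, sum(ipd$event) / sum(ipd$time),
               tolerance = 1e-10)
  expect_equal(f$k, 1L)
  # log-likelihood identity for the exponential law
  ll <- sum(ipd$event * log(f$model$scale)) - f$model$scale * sum(ipd$time)
  expect_equal(f$log_likelihood, ll, tolerance = 1e-10)
})

test_that("AIC and BIC identities hold for every fitted family", {
  ipd <- generate_pseudo_ipd(sim_spec(family_zoo()$weibull, 200,
                                      admin_censor_time = 80, seed = 3))
  for (f in fit_all_families(ipd)) {
    expect_equal(f$aic, 2 * f$k - 2 * f$log_likelihood)
    expect_equal(f$bic, f$k * log(f$n) - 2 * f$log_likelihood)
    expect_equal(f$n, 200L)
  }
})

test_that("log-logistic parameters are recovered within 5% from large uncensored samples", {
  # the scale lambda = b^-gamma has a sampling sd of ~7% even at
  # n = 5000 (shape error is amplified through the exponent), so the
  # 5% accuracy check is applied to the shape per fit and to the
  # replicate mean of the scale
  truth <- table1_models()$lp_os
  scales <- vapply(1:10, function(r) {
    ipd <- generate_pseudo_ipd(sim_spec(truth, 5000, admin_censor_time = 1e7,
                                        random_censor_rate = 0, seed = r))
    f <- fit_parametric(ipd, "loglogistic")
    expect_true(all(ipd$event == 1))
    expect_lt(abs(f$model$shape - truth$shape) / truth$shape, 0.05)
    f$model$scale
  }, numeric(1))
  expect_lt(abs(mean(scales) - truth$scale) / truth$scale, 0.05)
})

test_that("model selection uses AIC, then BIC, then family order", {
  mk <- function(fam, ll, k = 2L, n = 100L, id = "a") {
    f <- psmcea:::new_fit_result(family_zoo()[[fam]], ll, n, k, id)
    f
  }
  single <- mk("weibull", -100)
  expect_identical(select_model(list(single)), single)

  # equal AIC (same k, same ll) -> equal BIC -> family enum order wins
  a <- mk("lognormal", -100); b <- mk("weibull", -100)
  expect_identical(select_model(list(a, b))$model$family, "weibull")

  # equal AIC, different BIC via k/ll trade-off: 2k - 2ll equal,
  # bic = k log(n) - 2 ll differs -> lower bic (smaller k) wins
  c1 <- mk("gamma", -100, k = 2L)           # aic 204, bic ~ 209.2
  c2 <- mk("exponential", -101, k = 1L)     # aic 204, bic ~ 206.6
  expect_equal(c1$aic, c2$aic)
  expect_identical(select_model(list(c1, c2))$model$family, "exponential")

  expect_error(select_model(list(mk("weibull", -1, id = "a"),
                                 mk("gamma", -1, id = "b"))),
               "different datasets")
})

test_that("selection identifies the generating family from a large log-logistic sample", {
  truth <- table1_models()$lp_os
  ipd <- generate_pseudo_ipd(sim_spec(truth, 5000, admin_censor_time = 1e7,
                                      random_censor_rate = 0, seed = 21))
  best <- select_model(suppressWarnings(fit_all_families(ipd)))
  expect_identical(best$model$family, "loglogistic")
})

test_that("parameter recovery under 20% censoring holds across families and replicates", {
  # for each family: simulate at n = 5000 with ~20% administrative
  # censoring (horizon at the 80th percentile), refit, and require both
  # parameters within 10% of truth in >= 90% of 50 seeded replicates
  for (fam in surv_families()) {
    truth <- family_zoo()[[fam]]
    cens_at <- survival_quantile(truth, 0.8)
    ok <- logical(50)
    for (r in seq_len(50)) {
      ipd <- generate_pseudo_ipd(sim_spec(truth, 5000,
                                          admin_censor_time = cens_at,
                                          random_censor_rate = 0,
                                          seed = 5000 + r))
      f <- fit_parametric(ipd, fam)
      ok[r] <- abs(f$model$shape - truth$shape) <= 0.1 * abs(truth$shape) &&
        abs(f$model$scale - truth$scale) <= 0.1 * truth$scale
    }
    expect_gte(mean(ok), 0.9)
  }
})

test_that("IPD round-trips through CSV", {
  ipd <- generate_pseudo_ipd(sim_spec(family_zoo()$gamma, 50, seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ipd(ipd, path)
  back <- read_ipd(path)
  expect_equal(back$time, ipd$time)
  expect_equal(back$event, ipd$event)
})
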