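tis_os <- loglogistic_params(0.00927, 1.46070)
doc_os <- loglogistic_params(0.01092, 1.61683)
doc_pfs <- loglogistic_params(0.05747, 1.96409)

test_that("log-logistic survival matches its closed form", {
  expect_equal(loglogistic_survival(tis_os, 0), 1)
  expect_equal(loglogistic_survival(tis_os, 1), 1 / 1.00927)
  expect_equal(loglogistic_survival(tis_os, (1 / 0.00927)^(1 / 1.46070)), 0.5)
  expect_error(loglogistic_survival(tis_os, -1), "non-negative")
  expect_error(loglogistic_params(-0.1, 1), "positive")
})

test_that("median time matches trial scale", {
  expect_equal(median_time(tis_os), (1 / 0.00927)^(1 / 1.46070))
  # ~17 months for the PD-1 arm, ~11 for chemotherapy (21-day cycles)
  expect_equal(median_time(tis_os) * 21 / 30.4375, 17.0, tolerance = 0.01)
  expect_equal(median_time(doc_os) * 21 / 30.4375, 11.3, tolerance = 0.01)
  expect_equal(median_time(loglogistic_params(1, 2.3)), 1)
})

test_that("per-cycle transition probabilities follow 1 - S(t)/S(t-1)", {
  expect_equal(cycle_transition_prob(tis_os, 1), 0.00927 / 1.00927)
  expect_equal(cycle_transition_prob(doc_pfs, 1), 0.05747 / 1.05747)
  expect_error(cycle_transition_prob(tis_os, 0), ">= 1")
  # near-flat curve gives near-zero transition probability
  expect_lt(cycle_transition_prob(loglogistic_params(1e-12, 0.01), 5), 1e-12)
})

test_that("transition probabilities telescope back to the survival curve", {
  for (p in list(tis_os, doc_os, doc_pfs, loglogistic_params(0.2, 0.8))) {
    tp <- cycle_transition_prob(p, 1:100)
    expect_true(all(tp >= 0 & tp <= 1))
    expect_equal(1 - prod(1 - tp), 1 - loglogistic_survival(p, 100),
                 tolerance = 1e-12)
  }
})

test_that("hazard-ratio adjustment obeys identity, power and composition laws", {
  ref <- as_survival_curve(tis_os)
  grid <- c(0, 0.5, 1, 5, 20, 100)

  expect_equal(surv_prob(apply_hazard_ratio(ref, 1), grid),
               surv_prob(ref, grid))
  t_med <- median_time(tis_os)
  expect_equal(surv_prob(apply_hazard_ratio(ref, 1.170), t_med), 0.5^1.170)
  expect_equal(surv_prob(apply_hazard_ratio(ref, 2), t_med), 0.25)
  expect_equal(surv_prob(apply_hazard_ratio(ref, 2), grid),
               surv_prob(ref, grid)^2)

  ab <- apply_hazard_ratio(apply_hazard_ratio(ref, 1.3), 0.7)
  expect_equal(surv_prob(ab, grid), surv_prob(apply_hazard_ratio(ref, 1.3 * 0.7), grid))

  # hr > 1 can only lower survival
  expect_true(all(surv_prob(apply_hazard_ratio(ref, 1.170), grid) <=
                    surv_prob(ref, grid)))
  expect_error(apply_hazard_ratio(ref, 0), "positive")
  expect_error(apply_hazard_ratio(ref, -1), "positive")

  # accelerated-failure-time variant rescales time instead
  aft <- apply_hazard_ratio(ref, 2, method = "aft")
  expect_equal(surv_prob(aft, grid), surv_prob(ref, 2 * grid))
})

test_that("every family yields a proper survival function", {
  curves <- list(
    survival_curve("loglogistic", list(theta = 0.05, kappa = 1.5)),
    survival_curve("exponential", list(rate = 0.05)),
    survival_curve("weibull", list(shape = 1.3, scale = 20)),
    survival_curve("lognormal", list(meanlog = 3, sdlog = 0.8)),
    survival_curve("gompertz", list(shape = 0.02, rate = 0.01)),
    apply_hazard_ratio(tis_os, 1.235))
  grid <- seq(0, 100, by = 0.5)
  for (cv in curves) {
    s <- surv_prob(cv, grid)
    expect_equal(s[1], 1, info = cv$family)
    expect_true(all(diff(s) < 0), info = cv$family)
    expect_true(all(s > 0 & s <= 1), info = cv$family)
    tp <- cycle_transition_prob(cv, 1:50)
    expect_true(all(tp >= 0 & tp <= 1), info = cv$family)
  }
})

test_that("maximum likelihood fitting recovers known parameters", {
  # uncensored exponential data have the closed-form MLE rate = 1/mean
  set.seed(41)
  times <- rexp(800, 0.07)
  ipd <- data.frame(time = times, event = 1L)
  fit <- fit_parametric(ipd, "exponential")
  expect_equal(fit$params$rate, 1 / mean(times), tolerance = 1e-4)
  expect_equal(fit$n_events, 800L)
  expect_equal(fit$aic, 2 * 1 - 2 * fit$loglik)
  expect_equal(fit$bic, log(800) - 2 * fit$loglik)

  # log-logistic parameter recovery at n = 5000, no censoring
  ipd <- simulate_ipd(tis_os, 5000, admin_censor_time = 1e6, seed = 7)
  fit <- fit_parametric(ipd, "loglogistic")
  expect_equal(fit$params$theta, 0.00927, tolerance = 0.05)
  expect_equal(fit$params$kappa, 1.46070, tolerance = 0.05)

  # the fitter's log-likelihood agrees with a direct computation and is a
  # local maximum of the censored likelihood
  ipd <- simulate_ipd(tis_os, 400, admin_censor_time = 30, seed = 11)
  fit <- fit_parametric(ipd, "loglogistic")
  th <- fit$params$theta; ka <- fit$params$kappa
  expect_equal(ll_loglik(th, ka, ipd), fit$loglik, tolerance = 1e-6)
  for (eps in c(0.95, 1.05)) {
    expect_lt(ll_loglik(th * eps, ka, ipd), fit$loglik)
    expect_lt(ll_loglik(th, ka * eps, ipd), fit$loglik)
  }

  expect_error(fit_parametric(data.frame(time = 1:5, event = 0L)), "events")
  expect_error(fit_parametric(data.frame(time = c(-1, 2), event = 1L)), "> 0")
})

test_that("parameter recovery bias shrinks as the sample grows", {
  err <- vapply(c(200, 1000, 5000), function(n) {
    ipd <- simulate_ipd(tis_os, n, admin_censor_time = 1e6, seed = 101)
    fit <- fit_parametric(ipd, "loglogistic")
    abs(fit$params$kappa - 1.46070) / 1.46070
  }, numeric(1))
  expect_lt(err[3], 0.05)
  expect_lt(err[3], err[1])
})

test_that("information-criterion ranking prefers the generating family", {
  ipd <- simulate_ipd(tis_os, 3000, admin_censor_time = 60, seed = 23)
  sel <- select_best_fit(ipd)
  expect_equal(sel$table$family[1], "loglogistic")
  expect_true(all(diff(sel$table$aic) >= 0))
  expect_equal(sel$table$rank, seq_len(nrow(sel$table)))

  single <- select_best_fit(ipd, families = "weibull")
  expect_equal(single$table$family, "weibull")
})
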