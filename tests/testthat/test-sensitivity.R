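test_that("parameter draws match their moment-matched distributions", {
  set.seed(17)
  u <- base_cfg$settings$utilities$pfs            # beta 0.856 (0.718-0.994)
  draws <- replicate(1e5, sample_distribution(u))
  expect_equal(mean(draws), 0.856, tolerance = 0.01)
  expect_equal(sd(draws), (0.994 - 0.718) / 3.92, tolerance = 0.1)
  expect_true(all(draws > 0 & draws < 1))

  price <- get_strategy(base_cfg, "tislelizumab")$dosing$unit_price  # gamma
  g <- replicate(2e4, sample_distribution(price))
  expect_true(all(g >= 0))
  expect_equal(mean(g), 675.84, tolerance = 0.02)

  hr <- get_strategy(base_cfg, "nivolumab")$os$hr  # log-scale normal
  h <- replicate(2e4, sample_distribution(hr))
  expect_true(all(h > 0))
  expect_equal(median(h), 1.170, tolerance = 0.03)
  expect_equal(sd(log(h)), (log(2.683) - log(0.509)) / 3.92, tolerance = 0.05)

  w <- replicate(2e4, sample_distribution(base_cfg$settings$body_weight_kg))
  expect_true(all(w > 0))
  expect_equal(mean(w), 65, tolerance = 0.02)

  # fixed tags always return the baseline
  expect_equal(replicate(5, sample_distribution(
    base_cfg$settings$discount_rate_annual)), rep(0.05, 5))

  # infeasible beta moments fall back to uniform on the printed range
  bad <- ranged_value(0.01, 0, 1, "beta")  # se^2 = 0.065 > mean(1-mean)
  expect_warning(v <- sample_distribution(bad), "infeasible")
  expect_true(v >= 0 && v <= 1)
})

test_that("PSA with point-mass distributions collapses to the base case", {
  cfg <- short_cfg
  pt <- param_table(cfg)
  for (id in pt$id) {             # degenerate every range to the baseline
    cfg <- local({
      entries <- nsclcCEA:::param_registry(cfg)
      e <- entries[[which(vapply(entries, `[[`, character(1), "id") == id)]]
      v <- nsclcCEA:::config_get(cfg, e$path)
      if (e$kind == "hazard_ratio") {
        v$ci_low <- v$ci_high <- v$mean
      } else {
        v$low <- v$high <- v$mean
        v$distribution <- "fixed"
      }
      nsclcCEA:::config_set(cfg, e$path, v)
    })
  }
  psa <- run_psa(cfg, n_iter = 2, seed = 3)
  bc <- run_base_case(short_cfg)
  cmp <- compare_strategies(bc$summary, "tislelizumab",
                            short_cfg$settings$wtp_per_qaly)
  for (cm in c("docetaxel", "nivolumab")) {
    got <- psa$samples[psa$samples$comparator == cm, ]
    want_dc <- -cmp[cmp$strategy == cm, "delta_cost"]
    want_dq <- -cmp[cmp$strategy == cm, "delta_qaly"]
    expect_equal(got$delta_cost, rep(want_dc, 2), info = cm)
    expect_equal(got$delta_qaly, rep(want_dq, 2), info = cm)
  }
})

test_that("PSA is bit-reproducible under a fixed seed", {
  a <- run_psa(short_cfg, n_iter = 5, seed = 7)
  b <- run_psa(short_cfg, n_iter = 5, seed = 7)
  expect_identical(a$samples, b$samples)
  expect_identical(a$summary, b$summary)
})

test_that("acceptability curves are consistent with the sample flags", {
  psa <- run_psa(short_cfg, n_iter = 40, seed = 19)
  # at the run's own threshold the curve equals the summary proportion
  cv <- ceac(psa, psa$wtp)
  for (cm in psa$summary$comparator) {
    expect_equal(cv[cv$comparator == cm, "prop_cost_effective"],
                 psa$summary[psa$summary$comparator == cm,
                             "prop_cost_effective"], info = cm)
  }
  # lambda = 0: cost-effective means cheaper
  cv0 <- ceac(psa, 0)
  for (cm in cv0$comparator) {
    sub <- psa$samples[psa$samples$comparator == cm, ]
    expect_equal(cv0[cv0$comparator == cm, "prop_cost_effective"],
                 mean(sub$delta_cost < 0), info = cm)
  }
  # lambda -> infinity: cost-effective means more effective
  cvL <- ceac(psa, 1e12)
  for (cm in cvL$comparator) {
    sub <- psa$samples[psa$samples$comparator == cm, ]
    expect_equal(cvL[cvL$comparator == cm, "prop_cost_effective"],
                 mean(sub$delta_qaly > 0), info = cm)
  }
})

test_that("one-way DSA sweeps bounds and the identity sweep is null", {
  out <- outcome_icer("tislelizumab", "docetaxel")
  base_icer <- out(short_cfg)$value

  # a degenerate range (low = high = baseline) must not move the outcome
  cfg <- short_cfg
  cfg$strategies$tislelizumab$ae_cost$low <- 89.36
  cfg$strategies$tislelizumab$ae_cost$high <- 89.36
  ent <- dsa_one_way(cfg, "ae_cost_tislelizumab", out)
  expect_equal(ent$width, 0)
  expect_equal(ent$outcome_low, base_icer)
  expect_equal(ent$outcome_high, base_icer)

  # discount swept over its guideline range produces two distinct outcomes
  ds <- dsa_one_way(short_cfg, "discount_rate", out)
  expect_gt(ds$width, 0)
  expect_false(ds$dominance_low || ds$dominance_high)

  # the drug price of the intervention moves the ICER in its own direction
  pr <- dsa_one_way(short_cfg, "price_tislelizumab", out)
  expect_lt(pr$outcome_low, base_icer)
  expect_gt(pr$outcome_high, base_icer)

  expect_error(dsa_one_way(short_cfg, "nope", out), "valid names")
})

test_that("tornado ranking orders by width with name tie-breaks", {
  entries <- data.frame(parameter = c("a", "b", "c"),
                        low = 0, high = 1,
                        outcome_low = c(0, 0, 0),
                        outcome_high = c(5, 1, 3),
                        width = c(5, 1, 3),
                        dominance_low = FALSE, dominance_high = FALSE)
  expect_equal(tornado_top(entries)$parameter, c("a", "c", "b"))
  expect_equal(nrow(tornado_top(entries, k = 2)), 2)
  expect_equal(tornado_top(entries, k = 99)$parameter, c("a", "c", "b"))

  ties <- entries
  ties$width <- c(2, 2, 2)
  expect_equal(tornado_top(ties)$parameter, c("a", "b", "c"))
})
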