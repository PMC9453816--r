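test_that("drug cycle costs round doses up to whole pricing units", {
  doc <- get_strategy(base_cfg, "docetaxel")$dosing
  tis <- get_strategy(base_cfg, "tislelizumab")$dosing
  niv <- get_strategy(base_cfg, "nivolumab")$dosing
  anl <- base_cfg$settings$anlotinib$dosing

  # 75 mg/m2 x 1.72 m2 = 129 mg -> two 75 mg vials
  expect_equal(cycle_drug_cost(doc, 65, 1.72), 2 * 39.53)
  # flat 200 mg in a 200 mg vial
  expect_equal(cycle_drug_cost(tis, 65, 1.72), 675.84)
  # 3 mg/kg x 65 kg = 195 mg in 3 mg units, 1.5 administrations per cycle
  expect_equal(cycle_drug_cost(niv, 65, 1.72), 65 * 43.02 * 1.5)
  # one 168 mg pack per cycle, no wastage
  expect_equal(cycle_drug_cost(anl, 65, 1.72), 665.92)

  # wastage: any dose fraction above a unit buys a whole extra unit
  expect_equal(cycle_drug_cost(doc, 65, 2.01), 3 * 39.53)
  expect_error(cycle_drug_cost(niv, 0, 1.72), "positive")
  expect_error(dosing_rule(39.53, 75, "per_m2", -5), "positive")
})

test_that("discount factors follow the annualized cycle convention", {
  expect_equal(discount_factor(base_cfg, 0), 1)
  expect_equal(discount_factor(base_cfg, 365.25 / 21), 1 / 1.05)
  cfg0 <- apply_override(base_cfg, "discount_rate", 0)
  expect_equal(discount_factor(cfg0, c(0, 10, 500)), c(1, 1, 1))
  expect_error(discount_factor(base_cfg, -1))
})

test_that("cost accrual matches a hand sum on a one-cycle trace", {
  tr <- one_cycle_trace()
  cfg <- base_cfg
  cfg$settings$palliative_cost_mode <- "per_cycle"
  costs <- accrue_costs(tr, cfg, "tislelizumab")
  expect_equal(costs$ae, 89.36)
  expect_equal(costs$drug, 675.84)
  expect_equal(costs$followup, 55.60)
  expect_equal(costs$bsc, 337.50)
  expect_equal(costs$palliative, 0)     # no end-stage occupancy
  expect_equal(costs$subsequent_therapy, 0)
  expect_equal(costs$total, 89.36 + 675.84 + 55.60 + 337.50)

  # terminal-care mode adds the palliative sum once, at the death cycle
  costs_d <- accrue_costs(tr, base_cfg, "tislelizumab")
  expect_equal(costs_d$palliative, 2627.80 * 1.05^(-21 / 365.25))
  expect_equal(costs_d$total, costs$total + costs_d$palliative)

  # an extinct cohort accrues only the entry adverse-event burden
  dead <- one_cycle_trace()
  dead[1, ] <- c(0, 0, 0, 0, 1)
  attr(dead, "deaths") <- 0
  costs0 <- accrue_costs(dead, cfg, "docetaxel")
  expect_equal(costs0$total, 1212.99)
})

test_that("QALY accrual weights occupancy by utility and cycle length", {
  tr <- one_cycle_trace()
  cfg0 <- apply_override(base_cfg, "discount_rate", 0)
  eff <- accrue_qalys(tr, cfg0, "tislelizumab")
  expect_equal(eff$pfs, 0.856 * 21 / 365.25)
  expect_equal(eff$total, 0.856 * 21 / 365.25 - 0.002)

  # docetaxel with an extinct cohort: only the AE disutility remains
  dead <- one_cycle_trace()
  dead[1, ] <- c(0, 0, 0, 0, 1)
  attr(dead, "deaths") <- 0
  # the impossible negative total is flagged
  expect_warning(eff0 <- accrue_qalys(dead, cfg0, "docetaxel"), "negative")
  expect_equal(eff0$total, -0.061)

  # utilities of one and no AE decrement: QALYs equal life-years
  cfg1 <- cfg0
  for (u in c("utility_pfs", "utility_pd", "utility_end_stage")) {
    cfg1 <- apply_override(cfg1, u, 1)
  }
  for (s in names(cfg1$strategies)) {
    cfg1 <- apply_override(cfg1, paste0("ae_disutility_", s), 0)
  }
  res <- evaluate_strategy(cfg1, "docetaxel")
  expect_equal(res$effects$total, res$effects$life_years, tolerance = 1e-12)
})

test_that("QALYs never exceed life-years and components sum to totals", {
  for (nm in names(short_cfg$strategies)) {
    res <- evaluate_strategy(short_cfg, nm)
    expect_lte(res$effects$total, res$effects$life_years)
    comp <- unlist(res$costs[setdiff(names(res$costs), "total")])
    expect_true(all(comp >= 0))
    expect_equal(sum(comp), res$costs$total)
    expect_equal(res$effects$pfs + res$effects$pd + res$effects$end_stage -
                   res$effects$ae_disutility, res$effects$total)
  }
})

test_that("discounting strictly reduces totals and vanishes at rate zero", {
  res <- evaluate_strategy(short_cfg, "tislelizumab")
  cfg0 <- apply_override(short_cfg, "discount_rate", 0)
  res0 <- evaluate_strategy(cfg0, "tislelizumab")
  expect_lt(res$costs$total, res0$costs$total)
  expect_lt(res$effects$total, res0$effects$total)
  expect_equal(res0$effects$life_years, res$effects$life_years)  # undiscounted
})

test_that("each unit price moves only its own cost component", {
  base <- evaluate_strategy(short_cfg, "tislelizumab")$costs
  up <- evaluate_strategy(apply_override(short_cfg, "price_tislelizumab",
                                         1013.76), "tislelizumab")$costs
  expect_gt(up$drug, base$drug)
  for (comp in c("followup", "bsc", "palliative", "subsequent_therapy", "ae")) {
    expect_equal(up[[comp]], base[[comp]], info = comp)
  }
  up2 <- evaluate_strategy(apply_override(short_cfg, "cost_bsc", 506.25),
                           "tislelizumab")$costs
  expect_gt(up2$bsc, base$bsc)
  expect_equal(up2$drug, base$drug)
  expect_equal(up2$palliative, base$palliative)
})
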