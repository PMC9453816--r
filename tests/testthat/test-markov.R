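test_that("cohort trace conserves mass with monotone absorbing death", {
  for (nm in names(short_cfg$strategies)) {
    tr <- run_cohort(short_cfg, nm)
    expect_equal(nrow(tr), n_cycles(short_cfg) + 1L)
    expect_true(all(abs(rowSums(tr) - 1) < 1e-9), info = nm)
    expect_true(all(tr >= 0 & tr <= 1), info = nm)
    expect_true(all(diff(tr[, "DEATH"]) >= -1e-12), info = nm)
    expect_equal(tr[1, ], c(PFS_ON = 1, PFS_OFF = 0, PD = 0,
                            END_STAGE = 0, DEATH = 0))
  }
})

test_that("PFS exits split competing risks with death taken from OS", {
  p <- pfs_exit_probs(base_cfg, "tislelizumab", 1)
  expect_equal(p$p_death, 0.00927 / 1.00927)
  expect_equal(p$p_progress, 0.09158 / 1.09158 - 0.00927 / 1.00927)

  pd <- pd_exit_probs(base_cfg, 1)
  expect_equal(pd$p_death, 0.01184 / 1.01184)

  # PFS curve identical to OS: progression is clipped to zero everywhere
  cfg <- base_cfg
  cfg$strategies$tislelizumab$pfs <- cfg$strategies$tislelizumab$os
  expect_true(all(pfs_exit_probs(cfg, "tislelizumab", 1:500)$p_progress == 0))
})

test_that("cumulative death telescopes to 1 - S_OS where the oracle is exact", {
  # no progression (PFS == OS): every death follows the OS curve, so
  # cumulative death equals 1 - S_OS(t) at machine precision
  cfg <- short_cfg
  cfg$strategies$tislelizumab$pfs <- cfg$strategies$tislelizumab$os
  tr <- run_cohort(cfg, "tislelizumab")
  os <- loglogistic_params(0.00927, 1.46070)
  t_grid <- 0:n_cycles(cfg)
  expect_equal(tr[, "DEATH"], 1 - loglogistic_survival(os, t_grid),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(tr[, "PD"] == 0))

  # base case: the identity holds to 1e-3 over the first cycles, before
  # post-progression occupancy (on its own mortality clock) accumulates
  tr_base <- run_cohort(base_cfg, "tislelizumab")
  expect_lt(max(abs(tr_base[1:5, "DEATH"] -
                      (1 - loglogistic_survival(os, 0:4)))), 1e-3)
})

test_that("discontinuation feeds the off-therapy sub-state and nothing else", {
  tr <- run_cohort(short_cfg, "tislelizumab")
  expect_gt(max(tr[, "PFS_OFF"]), 0)

  cfg0 <- apply_override(short_cfg, "disc_prob_tislelizumab", 0)
  tr0 <- run_cohort(cfg0, "tislelizumab")
  expect_true(all(tr0[, "PFS_OFF"] == 0))
  # sub-state split leaves total PFS occupancy unchanged
  expect_equal(tr0[, "PFS_ON"] + tr0[, "PFS_OFF"],
               tr[, "PFS_ON"] + tr[, "PFS_OFF"], tolerance = 1e-12)
})

test_that("a higher all-cause hazard never gains life-years", {
  cfg1 <- apply_override(short_cfg, "hr_os_nivolumab", 1)
  cfg2 <- apply_override(short_cfg, "hr_os_nivolumab", 2)
  ly1 <- life_years(run_cohort(cfg1, "nivolumab"), cfg1)
  ly2 <- life_years(run_cohort(cfg2, "nivolumab"), cfg2)
  expect_lt(ly2, ly1)
})

test_that("degenerate transition regimes behave as limits demand", {
  # near-zero hazards: the cohort stays in PFS on therapy essentially forever
  cfg <- short_cfg
  cfg$strategies$tislelizumab$os <- loglogistic_params(1e-12, 1.2)
  cfg$strategies$tislelizumab$pfs <- loglogistic_params(1e-12, 1.2)
  cfg$strategies$tislelizumab$discontinuation_prob_per_cycle <- ranged_value(0)
  tr <- run_cohort(cfg, "tislelizumab")
  Tn <- n_cycles(cfg)
  expect_gt(min(tr[, "PFS_ON"]), 1 - 1e-8)
  expect_equal(life_years(tr, cfg), Tn * 21 / 365.25, tolerance = 1e-8)

  # fixed end-stage mortality of 1: end-stage lasts exactly one cycle, so
  # occupancy equals the previous cycle's entrants
  cfg1 <- short_cfg
  cfg1$settings$end_stage_mortality_mode <- "fixed"
  cfg1$settings$end_stage_fixed_prob <- 1
  tr1 <- run_cohort(cfg1, "docetaxel")
  entr <- attr(tr1, "end_entrants")
  expect_equal(tr1[-1, "END_STAGE"], entr, tolerance = 1e-12,
               ignore_attr = TRUE)

  # end-stage must be transient: a fixed probability of 0 is rejected
  expect_error({
    s <- short_cfg$settings
    model_settings(cycle_length_days = s$cycle_length_days,
                   horizon_years = s$horizon_years,
                   discount_rate_annual = s$discount_rate_annual,
                   wtp_per_qaly = s$wtp_per_qaly,
                   body_weight_kg = s$body_weight_kg,
                   body_surface_m2 = s$body_surface_m2,
                   utilities = s$utilities, care_costs = s$care_costs,
                   anlotinib = s$anlotinib,
                   end_stage_mortality_mode = "fixed",
                   end_stage_fixed_prob = 0)
  }, "transient")
})

test_that("the post-progression clock mode switches tunnel indexing", {
  cfg_mt <- short_cfg
  cfg_mt$settings$pd_clock_mode <- "model_time"
  tr_mt <- run_cohort(cfg_mt, "docetaxel")
  tr_se <- run_cohort(short_cfg, "docetaxel")
  expect_true(all(abs(rowSums(tr_mt) - 1) < 1e-9))
  # model-time clocking ages PD faster (entry happens at t > tau), so
  # post-progression survival is shorter overall
  expect_lt(life_years(tr_mt, cfg_mt), life_years(tr_se, short_cfg))
})

test_that("half-cycle correction shifts life-years by less than one cycle", {
  cfg_h <- short_cfg
  cfg_h$settings$half_cycle_correction <- TRUE
  tr <- run_cohort(short_cfg, "tislelizumab")
  ly_off <- life_years(tr, short_cfg)
  ly_on <- life_years(tr, cfg_h)
  expect_true(abs(ly_on - ly_off) <= 21 / 365.25)
  expect_false(ly_on == ly_off)
})
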