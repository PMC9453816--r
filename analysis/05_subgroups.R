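#!/usr/bin/env Rscript
# Sex-specific scenario machinery. The indirect comparison behind the
# nivolumab curves reports sex-specific OS hazard ratios vs tislelizumab
# (male 1.342, female 0.740); those are applied here as configuration
# overrides. Sex-specific tislelizumab-vs-docetaxel effects are NOT
# published, so the docetaxel comparison is deliberately left out: supply
# your own hazard ratios through the same override mechanism if you have
# them.
#
# Finding: tislelizumab dominates nivolumab in the male scenario; in the
# female scenario (HR < 1 favours nivolumab's survival) nivolumab gains
# QALYs but at a cost far beyond the threshold.

suppressMessages(library(nsclcCEA))
dir.create("results", showWarnings = FALSE)

cfg <- base_case_config()
wtp <- cfg$settings$wtp_per_qaly
scenarios <- list(male = 1.342, female = 0.740)

rows <- list()
for (sx in names(scenarios)) {
  cfg_s <- apply_override(cfg, "hr_os_nivolumab", scenarios[[sx]])
  bc <- run_base_case(cfg_s)
  cmp <- compare_strategies(bc$summary, "nivolumab", wtp)
  tis <- cmp[cmp$strategy == "tislelizumab", ]
  cat(sprintf("%s (HR_OS %-5.3f): tislelizumab vs nivolumab -> dC %9.0f, dQ %6.3f, %s\n",
              sx, scenarios[[sx]], tis$delta_cost, tis$delta_qaly,
              tis$decision))
  rows[[sx]] <- cbind(subgroup = sx, hr_os = scenarios[[sx]], tis)
}
out <- do.call(rbind, rows)
write.csv(out, "results/subgroup_tis_vs_niv.csv", row.names = FALSE)
write_manifest("results/manifest_05.json", base_case_path(), "05_subgroups",
               NA, "results/subgroup_tis_vs_niv.csv")
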