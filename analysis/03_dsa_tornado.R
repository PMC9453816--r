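#!/usr/bin/env Rscript
# One-way deterministic sensitivity analysis with tornado ranking.
#
# Every parameter with a printed range is swept to its bounds, all else at
# baseline; the fitted theta/kappa pairs stay fixed. Outcomes: the ICER of
# tislelizumab vs docetaxel, and (net monetary benefit) tislelizumab vs
# nivolumab, where dominance makes signed ICERs meaningless.
#
# Finding: the tislelizumab price is the only parameter whose range pushes
# the tislelizumab-vs-docetaxel ICER across the $35,663/QALY threshold; the
# tislelizumab-vs-nivolumab comparison is driven by the hazard ratios.

suppressMessages(library(nsclcCEA))
dir.create("results", showWarnings = FALSE)

cfg <- base_case_config()
wtp <- cfg$settings$wtp_per_qaly

dsa_doc <- run_dsa(cfg, outcome = outcome_icer("tislelizumab", "docetaxel"))
top_doc <- tornado_top(dsa_doc, k = 10)
cat("tornado (ICER, tislelizumab vs docetaxel), top 10:\n")
print(transform(top_doc, outcome_low = round(outcome_low),
                outcome_high = round(outcome_high), width = round(width)),
      row.names = FALSE)
flips <- dsa_doc[(dsa_doc$outcome_low > wtp) != (dsa_doc$outcome_high > wtp), ]
cat("\nparameters that flip the decision at WTP", wtp, ":",
    paste(flips$parameter, collapse = ", "), "\n")

dsa_niv <- run_dsa(cfg, outcome = outcome_nmb("tislelizumab", "nivolumab"))
top_niv <- tornado_top(dsa_niv, k = 10)
cat("\ntornado (NMB, tislelizumab vs nivolumab), top 10:\n")
print(transform(top_niv, outcome_low = round(outcome_low),
                outcome_high = round(outcome_high), width = round(width)),
      row.names = FALSE)

write.csv(dsa_doc, "results/dsa_tis_vs_doc.csv", row.names = FALSE)
write.csv(top_doc, "results/tornado_tis_vs_doc.csv", row.names = FALSE)
write.csv(dsa_niv, "results/dsa_tis_vs_niv.csv", row.names = FALSE)
write.csv(top_niv, "results/tornado_tis_vs_niv.csv", row.names = FALSE)
write_manifest("results/manifest_03.json", base_case_path(), "03_dsa_tornado",
               NA, c("results/dsa_tis_vs_doc.csv",
                     "results/tornado_tis_vs_doc.csv",
                     "results/dsa_tis_vs_niv.csv",
                     "results/tornado_tis_vs_niv.csv"))
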