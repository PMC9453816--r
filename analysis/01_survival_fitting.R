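#!/usr/bin/env Rscript
# Survival-fitting stage on the synthetic individual-patient-data pathway.
#
# The published transition probabilities rest on log-logistic curves fitted
# to pseudo-IPD reconstructed from digitized Kaplan-Meier figures. The
# figures themselves are not machine-readable, so this script demonstrates
# the same pipeline on synthetic data: draw right-censored pseudo-IPD from
# the known tislelizumab OS law, estimate the KM curve, invert its
# coordinates back into pseudo-IPD, and refit all five candidate families
# with AIC/BIC selection. Finding: at trial-like sample sizes the
# log-logistic family ranks first (at a few hundred subjects with heavy
# censoring the Weibull can tie it, which is exactly why the published
# selection relied on information criteria) and refitting recovers
# theta/kappa to within a few percent.

suppressMessages(library(nsclcCEA))
dir.create("results", showWarnings = FALSE)
seed <- 20260901

true_os <- loglogistic_params(0.00927, 1.46070)
ipd <- simulate_ipd(true_os, n = 2000, admin_censor_time = 60,
                    dropout_rate = 0.002, seed = seed)
write.csv(ipd, "results/synthetic_ipd.csv", row.names = FALSE)
cat(sprintf("simulated %d subjects: %d events, %d censored\n",
            nrow(ipd), sum(ipd$event), sum(1 - ipd$event)))

km <- km_estimate(ipd)
write.csv(km, "results/synthetic_km.csv", row.names = FALSE)

# digitized-style reconstruction: KM coordinates -> pseudo-IPD -> refit
rec <- invert_km_coordinates(km, n_start = nrow(ipd))
sel <- select_best_fit(rec)
write.csv(sel$table, "results/fit_selection.csv", row.names = FALSE)
cat("\nfamily ranking on reconstructed data (ascending AIC):\n")
print(sel$table, row.names = FALSE)

best <- sel$fits[[1]]
cat(sprintf("\nbest fit by AIC: %s (%s)\n", best$family,
            paste(names(best$params), signif(unlist(best$params), 5),
                  sep = " = ", collapse = ", ")))
ll <- sel$fits[["loglogistic"]]
cat(sprintf("log-logistic refit: theta-hat = %.5f (true %.5f), kappa-hat = %.4f (true %.4f)\n",
            ll$params$theta, true_os$theta, ll$params$kappa, true_os$kappa))
cat(sprintf("implied median: %.1f cycles (true %.1f)\n",
            median_time(loglogistic_params(ll$params$theta, ll$params$kappa)),
            median_time(true_os)))
write.csv(curve_table(best$curve, 100), "results/fitted_curve.csv",
          row.names = FALSE)
write_manifest("results/manifest_01.json", base_case_path(),
               "01_survival_fitting", seed,
               c("results/synthetic_ipd.csv", "results/synthetic_km.csv",
                 "results/fit_selection.csv", "results/fitted_curve.csv"))
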