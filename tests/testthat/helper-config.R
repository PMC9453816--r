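# Shared fixtures. The bundled base case is loaded once; tests that need a
# modified configuration copy it (configs are plain values, so copies are
# cheap and isolated).

base_cfg <- base_case_config()

# shorter horizon keeps property loops fast without changing the mechanics
short_cfg <- local({
  cfg <- base_cfg
  cfg$settings$horizon_years <- 5
  cfg
})

# a trace with known occupancy, for valuation unit tests:
# the whole cohort spends cycle 0 in PFS on therapy, then dies.
one_cycle_trace <- function() {
  tr <- matrix(c(1, 0, 0, 0, 0,
                 0, 0, 0, 0, 1), nrow = 2, byrow = TRUE,
               dimnames = list(NULL, c("PFS_ON", "PFS_OFF", "PD",
                                       "END_STAGE", "DEATH")))
  structure(tr, deaths = 1, pd_entrants = 0, end_entrants = 0,
            strategy = "tislelizumab",
            class = c("cohort_trace", "matrix", "array"))
}

# direct log-logistic log-likelihood with right censoring (independent of
# the fitting route): f(t) = theta*kappa*t^(kappa-1) / (1+theta*t^kappa)^2
ll_loglik <- function(theta, kappa, ipd) {
  s <- 1 / (1 + theta * ipd$time^kappa)
  f <- theta * kappa * ipd$time^(kappa - 1) * s^2
  sum(ifelse(ipd$event == 1, log(f), log(s)))
}
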