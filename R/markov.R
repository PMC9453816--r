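# Cohort state-transition engine. Health states: PFS on therapy, PFS off
# therapy (toxicity-related discontinuation), progressive disease (PD),
# end-stage disease, death. PD and end-stage are tunnel states keyed on time
# since progression so the further-line (anlotinib) transition probabilities
# can follow their own clock.

#' Resolve a strategy's OS/PFS curves
#'
#' Directly parameterized endpoints become log-logistic curves; endpoints
#' given as a hazard ratio against a reference arm are derived with
#' [apply_hazard_ratio()] using the configured application method
#' (proportional hazards by default).
#'
#' @param config A `cea_config`.
#' @param name Strategy name.
#' @return List with elements `os` and `pfs` (`survival_curve`s).
#' @export
strategy_curves <- function(config, name) {
  s <- get_strategy(config, name)
  resolve <- function(e) {
    if (inherits(e, "loglogistic_params")) return(as_survival_curve(e))
    ref <- get_strategy(config, e$reference)[[e$endpoint]]
    apply_hazard_ratio(ref, e$hr, method = config$settings$hr_application)
  }
  list(os = resolve(s$os), pfs = resolve(s$pfs))
}

#' Competing-risk exit probabilities from the PFS states
#'
#' Deaths are taken from the OS curve; progressions are the remainder of the
#' PFS-exit probability after deaths, clipped at zero (standard practice when
#' only the marginal OS and PFS curves are available).
#'
#' @param config A `cea_config`.
#' @param name Strategy name.
#' @param t Cycle index (>= 1, vectorized).
#' @return Data frame with columns `p_death`, `p_progress`.
#' @export
pfs_exit_probs <- function(config, name, t) {
  cur <- strategy_curves(config, name)
  p_death <- cycle_transition_prob(cur$os, t)
  p_leave <- cycle_transition_prob(cur$pfs, t)
  data.frame(p_death = p_death, p_progress = pmax(0, p_leave - p_death))
}

#' Per-cycle probability of toxicity-related treatment discontinuation
#'
#' Constant over time; applied to PFS-on-therapy survivors who neither died
#' nor progressed in the cycle.
#'
#' @param config A `cea_config`.
#' @param name Strategy name.
#' @param t Cycle index (accepted for interface symmetry; the probability
#'   does not depend on it).
#' @return Scalar probability.
#' @export
discontinuation_prob <- function(config, name, t = 1) {
  stopifnot(all(t >= 1))
  get_strategy(config, name)$discontinuation_prob_per_cycle$mean
}

#' Exit probabilities from the PD state
#'
#' On the further-line (anlotinib) clock: death follows the anlotinib OS
#' curve and transition to end-stage disease is the anlotinib-PFS-exit
#' remainder after death, clipped at zero. `tau` is time since progression
#' (tunnel clock) under the default `pd_clock_mode = "state_entry"`; under
#' `"model_time"` callers pass the model cycle instead.
#'
#' @param config A `cea_config`.
#' @param tau Tunnel index (>= 1, vectorized).
#' @return Data frame with columns `p_death`, `p_end_stage`.
#' @export
pd_exit_probs <- function(config, tau) {
  anl <- config$settings$anlotinib
  p_death <- cycle_transition_prob(anl$os, tau)
  p_leave <- cycle_transition_prob(anl$pfs, tau)
  data.frame(p_death = p_death, p_end_stage = pmax(0, p_leave - p_death))
}

#' Per-cycle death probability in end-stage disease
#'
#' Default mode continues the time-since-progression clock on the anlotinib
#' OS curve (no separate survival law exists for end-stage disease);
#' the `"fixed"` mode uses a constant per-cycle probability from the
#' configuration.
#'
#' @param config A `cea_config`.
#' @param tau Tunnel index (>= 1, vectorized).
#' @return Vector of probabilities.
#' @export
end_stage_death_prob <- function(config, tau) {
  st <- config$settings
  switch(st$end_stage_mortality_mode,
    anlotinib_os_clock = cycle_transition_prob(st$anlotinib$os, tau),
    fixed = rep(st$end_stage_fixed_prob, length(tau)),
    stop("unknown end_stage_mortality_mode '", st$end_stage_mortality_mode,
         "'", call. = FALSE))
}

check_probs <- function(p, what, t) {
  bad <- which(p < -1e-12 | p > 1 + 1e-12)
  if (length(bad)) {
    stop("internal consistency error: ", what, " outside [0, 1] at cycle ",
         t[bad[1]], " (value ", p[bad[1]], ")", call. = FALSE)
  }
  pmin(pmax(p, 0), 1)
}

#' Propagate the cohort over the model horizon
#'
#' The cohort starts 100\% in PFS on therapy. Within a cycle the event order
#' is death, then progression, then discontinuation among the remaining
#' on-therapy PFS patients. PD entrants carry tunnel index 1 in the next
#' cycle; the tunnel clock keeps running through end-stage disease. Mass is
#' conserved to 1e-9 at every cycle and death occupancy is non-decreasing.
#'
#' @param config A `cea_config`.
#' @param strategy Strategy name.
#' @return A `cohort_trace`: a `(n_cycles + 1) x 5` matrix of occupancy
#'   fractions (rows = cycles 0..T, columns `PFS_ON`, `PFS_OFF`, `PD`,
#'   `END_STAGE`, `DEATH`), with attributes `deaths`, `pd_entrants`,
#'   `end_entrants` (per-cycle flows, length T) and `strategy`.
#' @export
run_cohort <- function(config, strategy) {
  st <- config$settings
  s <- get_strategy(config, strategy)
  Tn <- n_cycles(st)
  tg <- seq_len(Tn)

  cur <- strategy_curves(config, strategy)
  p_death <- check_probs(cycle_transition_prob(cur$os, tg), "OS transition", tg)
  p_leave <- check_probs(cycle_transition_prob(cur$pfs, tg), "PFS transition", tg)
  p_prog <- pmax(0, p_leave - p_death)
  d <- s$discontinuation_prob_per_cycle$mean

  # post-progression probabilities, indexed by tunnel time (or model time)
  tau_grid <- seq_len(Tn + 1L)
  pd_p <- pd_exit_probs(config, tau_grid)
  p_pd_death <- check_probs(pd_p$p_death, "PD death", tau_grid)
  p_pd_end <- check_probs(pd_p$p_end_stage, "PD to end-stage", tau_grid)
  p_end_death <- check_probs(end_stage_death_prob(config, tau_grid),
                             "end-stage death", tau_grid)
  model_clock <- identical(st$pd_clock_mode, "model_time")

  pfs_on <- 1; pfs_off <- 0; dead <- 0
  pd <- numeric(Tn + 1L); en <- numeric(Tn + 1L)  # tunnel occupancy by tau
  trace <- matrix(0, nrow = Tn + 1L, ncol = 5L,
                  dimnames = list(NULL, c("PFS_ON", "PFS_OFF", "PD",
                                          "END_STAGE", "DEATH")))
  trace[1L, ] <- c(1, 0, 0, 0, 0)
  deaths <- pd_entrants <- end_entrants <- numeric(Tn)

  for (t in tg) {
    die_pfs <- (pfs_on + pfs_off) * p_death[t]
    prog <- (pfs_on + pfs_off) * p_prog[t]
    stay <- 1 - p_death[t] - p_prog[t]
    stay_on <- pfs_on * stay
    new_off <- pfs_off * stay + stay_on * d
    new_on <- stay_on * (1 - d)

    if (model_clock) {
      pdd <- pd * p_pd_death[t]; pde <- pd * p_pd_end[t]
      end_d <- en * p_end_death[t]
    } else {
      pdd <- pd * p_pd_death; pde <- pd * p_pd_end
      end_d <- en * p_end_death
    }
    pd_stay <- pd - pdd - pde
    en_stay <- en - end_d

    # advance tunnel clocks; the last index is sticky so no mass is dropped
    pd_new <- c(prog, pd_stay[seq_len(Tn)])
    pd_new[Tn + 1L] <- pd_new[Tn + 1L] + pd_stay[Tn + 1L]
    en_new <- c(0, en_stay[seq_len(Tn)] + pde[seq_len(Tn)])
    en_new[Tn + 1L] <- en_new[Tn + 1L] + en_stay[Tn + 1L] + pde[Tn + 1L]

    deaths[t] <- die_pfs + sum(pdd) + sum(end_d)
    pd_entrants[t] <- prog
    end_entrants[t] <- sum(pde)
    dead <- dead + deaths[t]
    pfs_on <- new_on; pfs_off <- new_off; pd <- pd_new; en <- en_new

    trace[t + 1L, ] <- c(pfs_on, pfs_off, sum(pd), sum(en), dead)
    if (abs(sum(trace[t + 1L, ]) - 1) > 1e-9) {
      stop("internal consistency error: cohort mass not conserved at cycle ",
           t, " (row sum ", sum(trace[t + 1L, ]), ")", call. = FALSE)
    }
  }

  structure(trace, deaths = deaths, pd_entrants = pd_entrants,
            end_entrants = end_entrants, strategy = strategy,
            class = c("cohort_trace", "matrix", "array"))
}

# Occupancy attributed to each lived cycle t = 0..T-1. With the half-cycle
# correction, transitions are treated as mid-cycle: occupancy is averaged
# over the cycle's start and end rows.
cycle_occupancy <- function(trace, settings) {
  Tn <- nrow(trace) - 1L
  occ <- trace[seq_len(Tn), , drop = FALSE]
  if (settings$half_cycle_correction) {
    occ <- (occ + trace[seq_len(Tn) + 1L, , drop = FALSE]) / 2
  }
  occ
}

#' Undiscounted life-years of a cohort trace
#'
#' Sum of the alive fraction over lived cycles times the cycle length in
#' years, with the half-cycle correction applied if enabled.
#'
#' @param trace A `cohort_trace`.
#' @param config A `cea_config`.
#' @return Life-years (scalar).
#' @export
life_years <- function(trace, config) {
  st <- config$settings
  occ <- cycle_occupancy(trace, st)
  alive <- rowSums(occ[, c("PFS_ON", "PFS_OFF", "PD", "END_STAGE"), drop = FALSE])
  sum(alive) * st$cycle_length_days / 365.25
}

#' Export a cohort trace as a data frame
#' @param trace A `cohort_trace`.
#' @return Data frame with a `cycle` column (0..T) and one column per state.
#' @export
trace_table <- function(trace) {
  data.frame(cycle = seq_len(nrow(trace)) - 1L, unclass(trace)[, , drop = FALSE])
}
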