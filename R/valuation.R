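# Valuation of a cohort trace: drug acquisition with vial-wastage rounding,
# background care costs, one-time adverse-event burdens, state utilities,
# discounting.

#' Per-cycle drug acquisition cost with vial-wastage rounding
#'
#' The administered dose is resolved from the dosing kind (flat mg, mg/kg,
#' mg/m2, or a per-cycle pack), rounded up to an integral number of pricing
#' units (wasted partial vials are paid for), and costed per administration.
#'
#' @param dosing A [dosing_rule()].
#' @param weight Body weight in kg.
#' @param bsa Body surface area in m2.
#' @return Cost per model cycle (currency).
#' @examples
#' # docetaxel 75 mg/m2 at 1.72 m2: 129 mg -> 2 x 75 mg vials
#' d <- dosing_rule(39.53, 75, "per_m2", 75)
#' cycle_drug_cost(d, weight = 65, bsa = 1.72)
#' @export
cycle_drug_cost <- function(dosing, weight, bsa) {
  stopifnot(inherits(dosing, "dosing_rule"))
  dose_mg <- switch(dosing$dose_kind,
    flat = dosing$dose_value,
    per_kg = dosing$dose_value * weight,
    per_m2 = dosing$dose_value * bsa,
    per_cycle_pack = dosing$dose_value)
  if (!is.finite(dose_mg) || dose_mg <= 0) {
    stop("resolved dose must be positive (got ", dose_mg, " mg)", call. = FALSE)
  }
  units <- ceiling(round(dose_mg / dosing$unit_size, 9))
  units * dosing$unit_price$mean * dosing$administrations_per_cycle
}

#' Discount factor at a given cycle
#'
#' `(1 + r)^(-t * cycle_length_days / 365.25)` with the annual rate `r` from
#' the settings; costs and effects share the same rate.
#'
#' @param config A `cea_config` or `model_settings`.
#' @param t Cycle index (>= 0, vectorized; fractional values allowed).
#' @return Discount factors in (0, 1\].
#' @export
discount_factor <- function(config, t) {
  st <- if (inherits(config, "cea_config")) config$settings else config
  stopifnot(all(t >= 0))
  r <- st$discount_rate_annual$mean
  (1 + r)^(-t * st$cycle_length_days / 365.25)
}

#' Discounted cost breakdown of a cohort trace
#'
#' Per lived cycle: PFS on therapy accrues drug + follow-up + best supportive
#' care (BSC); PFS off therapy accrues follow-up + BSC; PD accrues follow-up
#' + BSC + the subsequent-therapy proportion times the anlotinib cycle cost;
#' end-stage disease accrues follow-up, plus palliative care per cycle when
#' `palliative_cost_mode = "per_cycle"`. In the default `"one_time_death"`
#' mode the palliative/terminal-care sum is instead applied once per death,
#' discounted at the death cycle (`"one_time_entry"`: once per end-stage
#' entrant). The frequency-weighted adverse-event aggregate is added once at
#' model entry. All components are discounted.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param config A `cea_config`.
#' @param strategy Strategy name (defaults to the trace's strategy).
#' @return An object of class `cost_breakdown`: named list with `drug`,
#'   `followup`, `bsc`, `subsequent_therapy`, `palliative`, `ae` and `total`.
#' @export
accrue_costs <- function(trace, config, strategy = attr(trace, "strategy")) {
  st <- config$settings
  s <- get_strategy(config, strategy)
  Tn <- nrow(trace) - 1L
  occ <- cycle_occupancy(trace, st)
  df <- discount_factor(st, seq_len(Tn) - 1L)

  drug_cycle <- cycle_drug_cost(s$dosing, st$body_weight_kg$mean,
                                st$body_surface_m2$mean)
  anl_cycle <- cycle_drug_cost(st$anlotinib$dosing, st$body_weight_kg$mean,
                               st$body_surface_m2$mean)
  alive <- rowSums(occ[, c("PFS_ON", "PFS_OFF", "PD", "END_STAGE"), drop = FALSE])
  on_treatment <- rowSums(occ[, c("PFS_ON", "PFS_OFF", "PD"), drop = FALSE])

  drug <- sum(occ[, "PFS_ON"] * drug_cycle * df)
  followup <- sum(alive * st$care_costs$followup$mean * df)
  bsc <- sum(on_treatment * st$care_costs$bsc$mean * df)
  subsequent <- sum(occ[, "PD"] * s$subsequent_therapy_proportion$mean *
                      anl_cycle * df)

  pall_price <- st$care_costs$palliative$mean
  df_flow <- discount_factor(st, seq_len(Tn))  # flows materialize at cycle end
  palliative <- switch(st$palliative_cost_mode,
    per_cycle = sum(occ[, "END_STAGE"] * pall_price * df),
    one_time_entry = sum(attr(trace, "end_entrants") * pall_price * df_flow),
    one_time_death = sum(attr(trace, "deaths") * pall_price * df_flow))

  ae <- s$ae_cost$mean  # once at model entry, discount factor 1
  out <- list(drug = drug, followup = followup, bsc = bsc,
              subsequent_therapy = subsequent, palliative = palliative,
              ae = ae)
  out$total <- sum(unlist(out))
  class(out) <- "cost_breakdown"
  out
}

#' Discounted QALY breakdown of a cohort trace
#'
#' Sum over lived cycles and states of occupancy x state utility x cycle
#' length in years x discount factor, minus the one-time adverse-event
#' disutility applied at model entry. Both PFS sub-states use the PFS
#' utility.
#'
#' @inheritParams accrue_costs
#' @return An object of class `effect_breakdown`: named list with per-state
#'   QALY contributions (`pfs`, `pd`, `end_stage`), `ae_disutility`, `total`
#'   and undiscounted `life_years`.
#' @export
accrue_qalys <- function(trace, config, strategy = attr(trace, "strategy")) {
  st <- config$settings
  s <- get_strategy(config, strategy)
  Tn <- nrow(trace) - 1L
  occ <- cycle_occupancy(trace, st)
  df <- discount_factor(st, seq_len(Tn) - 1L)
  cyy <- st$cycle_length_days / 365.25

  pfs <- sum((occ[, "PFS_ON"] + occ[, "PFS_OFF"]) * st$utilities$pfs$mean *
               cyy * df)
  pd <- sum(occ[, "PD"] * st$utilities$pd$mean * cyy * df)
  end_stage <- sum(occ[, "END_STAGE"] * st$utilities$end_stage$mean * cyy * df)
  ae <- s$ae_disutility$mean
  total <- pfs + pd + end_stage - ae
  if (total < 0) {
    warning("negative QALY total (", total, ") for strategy '", strategy, "'")
  }
  structure(list(pfs = pfs, pd = pd, end_stage = end_stage,
                 ae_disutility = ae, total = total,
                 life_years = life_years(trace, config)),
            class = "effect_breakdown")
}

#' Run one strategy end-to-end
#'
#' Cohort propagation plus cost and QALY valuation.
#'
#' @param config A `cea_config`.
#' @param strategy Strategy name.
#' @return List with `strategy`, `trace`, `costs`, `effects`.
#' @export
evaluate_strategy <- function(config, strategy) {
  trace <- run_cohort(config, strategy)
  list(strategy = strategy, trace = trace,
       costs = accrue_costs(trace, config, strategy),
       effects = accrue_qalys(trace, config, strategy))
}

#' Run all strategies of a configuration
#'
#' @param config A `cea_config`.
#' @return List with `results` (per-strategy [evaluate_strategy()] output)
#'   and `summary` (data frame with `strategy`, `cost`, `qaly`,
#'   `life_years`).
#' @export
run_base_case <- function(config) {
  results <- lapply(names(config$strategies), function(nm)
    evaluate_strategy(config, nm))
  names(results) <- names(config$strategies)
  summary <- data.frame(
    strategy = names(results),
    cost = vapply(results, function(r) r$costs$total, numeric(1)),
    qaly = vapply(results, function(r) r$effects$total, numeric(1)),
    life_years = vapply(results, function(r) r$effects$life_years, numeric(1)),
    row.names = NULL)
  list(results = results, summary = summary)
}
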