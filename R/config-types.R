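#' Value with an uncertainty range and a sampling distribution
#'
#' The model's parameter table attaches to most inputs a baseline value, a
#' deterministic sensitivity range and a distribution tag used by the
#' probabilistic sensitivity analysis. `ranged_value()` bundles the four and
#' enforces the invariants `low <= mean <= high`, beta-tagged values in
#' \[0, 1\] and gamma-tagged values non-negative.
#'
#' @param mean Baseline (point-estimate) value.
#' @param low,high Bounds of the sensitivity range; default to `mean`.
#' @param distribution One of `"fixed"`, `"beta"`, `"gamma"`, `"normal"`.
#'   `"fixed"` values are held at baseline in the PSA (they may still carry a
#'   DSA range, e.g. the discount rate).
#' @return An object of class `ranged_value`.
#' @export
ranged_value <- function(mean, low = mean, high = mean,
                         distribution = c("fixed", "beta", "gamma", "normal")) {
  distribution <- match.arg(distribution)
  if (!is.numeric(mean) || !is.numeric(low) || !is.numeric(high) ||
      length(mean) != 1L || length(low) != 1L || length(high) != 1L) {
    stop("ranged_value fields must be numeric scalars", call. = FALSE)
  }
  if (!(low <= mean && mean <= high)) {
    stop(sprintf("ranged value violates low <= mean <= high (low=%g, mean=%g, high=%g)",
                 low, mean, high), call. = FALSE)
  }
  if (distribution == "beta" && (low < 0 || high > 1)) {
    stop(sprintf("beta-distributed value must lie in [0, 1] (low=%g, high=%g)",
                 low, high), call. = FALSE)
  }
  if (distribution == "gamma" && low < 0) {
    stop(sprintf("gamma-distributed value must be non-negative (low=%g)", low),
         call. = FALSE)
  }
  structure(list(mean = mean, low = low, high = high,
                 distribution = distribution),
            class = "ranged_value")
}

#' Hazard ratio with a 95\% interval
#'
#' Used to derive the nivolumab survival curves from the tislelizumab
#' reference curves (no head-to-head trial exists; the ratios come from an
#' indirect comparison).
#'
#' @param mean Point estimate (> 0).
#' @param ci_low,ci_high 95\% interval bounds, `ci_low <= mean <= ci_high`.
#' @return An object of class `hazard_ratio`.
#' @export
hazard_ratio <- function(mean, ci_low, ci_high) {
  if (any(c(mean, ci_low, ci_high) <= 0)) {
    stop("hazard ratio and its interval must be positive", call. = FALSE)
  }
  if (!(ci_low <= mean && mean <= ci_high)) {
    stop(sprintf("hazard ratio violates ci_low <= mean <= ci_high (%g, %g, %g)",
                 ci_low, mean, ci_high), call. = FALSE)
  }
  structure(list(mean = mean, ci_low = ci_low, ci_high = ci_high),
            class = "hazard_ratio")
}

#' Log-logistic survival parameters
#'
#' Parameterization used throughout the model: `S(t) = 1 / (1 + theta * t^kappa)`
#' with `t` measured in model cycles (3 weeks by default). Under this
#' convention the published theta/kappa pairs reproduce the source trials'
#' median survival times.
#'
#' @param theta Positive rate-like scale parameter (per cycle^kappa).
#' @param kappa Positive shape parameter (dimensionless).
#' @return An object of class `loglogistic_params`.
#' @export
loglogistic_params <- function(theta, kappa) {
  if (!is.numeric(theta) || !is.numeric(kappa) || theta <= 0 || kappa <= 0) {
    stop("log-logistic parameters theta and kappa must be positive", call. = FALSE)
  }
  structure(list(theta = theta, kappa = kappa), class = "loglogistic_params")
}

#' Reference to another strategy's curve, adjusted by a hazard ratio
#'
#' Survival endpoints that are not fitted directly but derived from a
#' reference arm (nivolumab's OS and PFS relative to tislelizumab).
#'
#' @param reference Name of the reference strategy.
#' @param endpoint `"os"` or `"pfs"`.
#' @param hr A [hazard_ratio()].
#' @return An object of class `hr_reference`.
#' @export
hr_reference <- function(reference, endpoint = c("os", "pfs"), hr) {
  endpoint <- match.arg(endpoint)
  stopifnot(is.character(reference), length(reference) == 1L,
            inherits(hr, "hazard_ratio"))
  structure(list(reference = reference, endpoint = endpoint, hr = hr),
            class = "hr_reference")
}

#' Drug dosing and pricing rule
#'
#' Encodes how a per-cycle acquisition cost is computed: the dose is resolved
#' from the dosing kind (flat mg, mg/kg, mg/m2, or a fixed per-cycle pack),
#' rounded up to an integral number of pricing units to account for vial
#' wastage, and multiplied by the unit price and the number of
#' administrations per model cycle.
#'
#' @param unit_price Price per pricing unit; a [ranged_value()] (a bare
#'   number is promoted to a fixed ranged value).
#' @param unit_size Drug mass per pricing unit (mg).
#' @param dose_kind One of `"flat"`, `"per_kg"`, `"per_m2"`, `"per_cycle_pack"`.
#' @param dose_value mg (flat / pack), mg/kg or mg/m2 according to `dose_kind`.
#' @param administrations_per_cycle Administrations per model cycle (may be
#'   fractional, e.g. 1.5 for a 2-weekly schedule in a 3-week cycle).
#' @return An object of class `dosing_rule`.
#' @export
dosing_rule <- function(unit_price, unit_size,
                        dose_kind = c("flat", "per_kg", "per_m2", "per_cycle_pack"),
                        dose_value, administrations_per_cycle = 1) {
  dose_kind <- match.arg(dose_kind)
  if (is.numeric(unit_price)) unit_price <- ranged_value(unit_price)
  stopifnot(inherits(unit_price, "ranged_value"))
  vals <- c(unit_price = unit_price$mean, unit_size = unit_size,
            dose_value = dose_value,
            administrations_per_cycle = administrations_per_cycle)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad)) {
    stop("dosing rule fields must be positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(unit_price = unit_price, unit_size = unit_size,
                 dose_kind = dose_kind, dose_value = dose_value,
                 administrations_per_cycle = administrations_per_cycle),
            class = "dosing_rule")
}

#' Specification of one comparator arm
#'
#' @param name Strategy name.
#' @param os,pfs Survival endpoints: [loglogistic_params()] or [hr_reference()].
#' @param discontinuation_prob_per_cycle Per-cycle probability of
#'   toxicity-related treatment discontinuation ([ranged_value()], mean in
#'   \[0, 1\]).
#' @param dosing A [dosing_rule()].
#' @param ae_cost One-time frequency-weighted adverse-event management cost
#'   ([ranged_value()], currency).
#' @param ae_disutility One-time adverse-event QALY decrement ([ranged_value()]).
#' @param subsequent_therapy_proportion Proportion of progressing patients who
#'   receive further-line anlotinib ([ranged_value()], mean in \[0, 1\]).
#' @return An object of class `strategy_spec`.
#' @export
strategy_spec <- function(name, os, pfs, discontinuation_prob_per_cycle,
                          dosing, ae_cost, ae_disutility,
                          subsequent_therapy_proportion) {
  stopifnot(is.character(name), length(name) == 1L)
  for (endp in list(os, pfs)) {
    if (!inherits(endp, "loglogistic_params") && !inherits(endp, "hr_reference")) {
      stop("strategy '", name,
           "': os/pfs must be loglogistic_params or hr_reference", call. = FALSE)
    }
  }
  for (fld in c("discontinuation_prob_per_cycle", "ae_cost", "ae_disutility",
                "subsequent_therapy_proportion")) {
    v <- get(fld)
    if (!inherits(v, "ranged_value")) {
      stop("strategy '", name, "': ", fld, " must be a ranged_value", call. = FALSE)
    }
  }
  for (fld in c("discontinuation_prob_per_cycle", "subsequent_therapy_proportion")) {
    m <- get(fld)$mean
    if (m < 0 || m > 1) {
      stop("strategy '", name, "': ", fld, " mean must lie in [0, 1] (got ",
           m, ")", call. = FALSE)
    }
  }
  stopifnot(inherits(dosing, "dosing_rule"))
  structure(list(name = name, os = os, pfs = pfs,
                 discontinuation_prob_per_cycle = discontinuation_prob_per_cycle,
                 dosing = dosing, ae_cost = ae_cost,
                 ae_disutility = ae_disutility,
                 subsequent_therapy_proportion = subsequent_therapy_proportion),
            class = "strategy_spec")
}

#' Global model settings
#'
#' Everything that is shared across comparator arms: the cycle/horizon grid,
#' discounting, willingness-to-pay, patient anthropometrics, state utilities,
#' background care costs, the further-line anlotinib parameters, and the
#' structural switches (half-cycle correction, end-stage mortality mechanics,
#' palliative-cost application, post-progression clock, hazard-ratio
#' application).
#'
#' @param cycle_length_days Model cycle length in days (default 21).
#' @param horizon_years Time horizon in years (> 0; default 30).
#' @param discount_rate_annual Annual discount rate for costs and effects
#'   ([ranged_value()], mean in \[0, 0.08\]).
#' @param wtp_per_qaly Willingness-to-pay threshold per QALY (currency).
#' @param body_weight_kg,body_surface_m2 Patient anthropometrics
#'   ([ranged_value()]) used by weight- and BSA-based dosing.
#' @param utilities Named list of [ranged_value()] utilities for `pfs`, `pd`,
#'   `end_stage` (each mean in \[0, 1\]).
#' @param care_costs Named list of per-cycle [ranged_value()] costs:
#'   `followup`, `bsc`, `palliative`.
#' @param anlotinib List with `os`, `pfs` ([loglogistic_params()]) and
#'   `dosing` ([dosing_rule()]) for the further-line therapy.
#' @param half_cycle_correction Apply a trapezoidal half-cycle correction to
#'   state occupancy when accruing costs and QALYs (default `FALSE`).
#' @param end_stage_mortality_mode `"anlotinib_os_clock"` (default; the
#'   time-since-progression clock keeps running on the anlotinib OS curve) or
#'   `"fixed"` (constant per-cycle probability `end_stage_fixed_prob`).
#' @param end_stage_fixed_prob Per-cycle end-stage death probability for the
#'   `"fixed"` mode; must lie in (0, 1] (end-stage must be transient).
#' @param palliative_cost_mode `"one_time_death"` (default: the palliative /
#'   terminal-care sum is applied once per death), `"one_time_entry"` (once
#'   per end-stage entrant) or `"per_cycle"` (accrued per cycle of end-stage
#'   occupancy).
#' @param pd_clock_mode `"state_entry"` (default: post-progression transition
#'   probabilities follow time since progression, tracked through tunnel
#'   states) or `"model_time"` (probabilities indexed by model cycle).
#' @param hr_application `"ph"` (default: proportional hazards,
#'   `S_new = S_ref^HR`) or `"aft"` (accelerated failure time,
#'   `S_new(t) = S_ref(HR * t)`).
#' @return An object of class `model_settings`.
#' @export
model_settings <- function(cycle_length_days = 21,
                           horizon_years = 30,
                           discount_rate_annual,
                           wtp_per_qaly,
                           body_weight_kg,
                           body_surface_m2,
                           utilities,
                           care_costs,
                           anlotinib,
                           half_cycle_correction = FALSE,
                           end_stage_mortality_mode = c("anlotinib_os_clock", "fixed"),
                           end_stage_fixed_prob = NULL,
                           palliative_cost_mode = c("one_time_death",
                                                    "one_time_entry", "per_cycle"),
                           pd_clock_mode = c("state_entry", "model_time"),
                           hr_application = c("ph", "aft")) {
  end_stage_mortality_mode <- match.arg(end_stage_mortality_mode)
  palliative_cost_mode <- match.arg(palliative_cost_mode)
  pd_clock_mode <- match.arg(pd_clock_mode)
  hr_application <- match.arg(hr_application)
  if (!is.numeric(horizon_years) || horizon_years <= 0) {
    stop("horizon_years must be positive (got ", horizon_years, ")", call. = FALSE)
  }
  if (!is.numeric(cycle_length_days) || cycle_length_days <= 0) {
    stop("cycle_length_days must be positive", call. = FALSE)
  }
  for (fld in c("discount_rate_annual", "body_weight_kg", "body_surface_m2")) {
    if (!inherits(get(fld), "ranged_value")) {
      stop(fld, " must be a ranged_value", call. = FALSE)
    }
  }
  if (discount_rate_annual$mean < 0 || discount_rate_annual$mean > 0.08) {
    stop("discount_rate_annual mean must lie in [0, 0.08] (got ",
         discount_rate_annual$mean, ")", call. = FALSE)
  }
  for (nm in c("pfs", "pd", "end_stage")) {
    u <- utilities[[nm]]
    if (is.null(u) || !inherits(u, "ranged_value")) {
      stop("utilities.", nm, " missing or not a ranged_value", call. = FALSE)
    }
    if (u$mean < 0 || u$mean > 1) {
      stop("utilities.", nm, " mean must lie in [0, 1] (got ", u$mean, ")",
           call. = FALSE)
    }
  }
  for (nm in c("followup", "bsc", "palliative")) {
    cc <- care_costs[[nm]]
    if (is.null(cc) || !inherits(cc, "ranged_value")) {
      stop("care_costs.", nm, " missing or not a ranged_value", call. = FALSE)
    }
  }
  if (!inherits(anlotinib$os, "loglogistic_params") ||
      !inherits(anlotinib$pfs, "loglogistic_params") ||
      !inherits(anlotinib$dosing, "dosing_rule")) {
    stop("anlotinib must provide os/pfs loglogistic_params and a dosing rule",
         call. = FALSE)
  }
  if (end_stage_mortality_mode == "fixed") {
    p <- end_stage_fixed_prob
    if (is.null(p) || !is.numeric(p) || p <= 0 || p > 1) {
      stop("end_stage_fixed_prob must lie in (0, 1] when ",
           "end_stage_mortality_mode = 'fixed' (end-stage must be transient)",
           call. = FALSE)
    }
  }
  structure(list(cycle_length_days = cycle_length_days,
                 horizon_years = horizon_years,
                 discount_rate_annual = discount_rate_annual,
                 wtp_per_qaly = wtp_per_qaly,
                 body_weight_kg = body_weight_kg,
                 body_surface_m2 = body_surface_m2,
                 utilities = utilities,
                 care_costs = care_costs,
                 anlotinib = anlotinib,
                 half_cycle_correction = isTRUE(half_cycle_correction),
                 end_stage_mortality_mode = end_stage_mortality_mode,
                 end_stage_fixed_prob = end_stage_fixed_prob,
                 palliative_cost_mode = palliative_cost_mode,
                 pd_clock_mode = pd_clock_mode,
                 hr_application = hr_application),
            class = "model_settings")
}

#' Full model configuration
#'
#' @param settings A [model_settings()].
#' @param strategies List of [strategy_spec()] objects; names are taken from
#'   the specs.
#' @return An object of class `cea_config`.
#' @export
model_config <- function(settings, strategies) {
  stopifnot(inherits(settings, "model_settings"))
  if (!length(strategies)) stop("at least one strategy is required", call. = FALSE)
  for (s in strategies) stopifnot(inherits(s, "strategy_spec"))
  names(strategies) <- vapply(strategies, `[[`, character(1), "name")
  # hr references must resolve to a concrete (fitted) curve
  for (s in strategies) {
    for (ep in c("os", "pfs")) {
      e <- s[[ep]]
      if (inherits(e, "hr_reference")) {
        ref <- strategies[[e$reference]]
        if (is.null(ref)) {
          stop("strategy '", s$name, "': hr reference '", e$reference,
               "' is not a known strategy", call. = FALSE)
        }
        if (!inherits(ref[[e$endpoint]], "loglogistic_params")) {
          stop("strategy '", s$name, "': hr reference must point to a ",
               "directly parameterized endpoint", call. = FALSE)
        }
      }
    }
  }
  structure(list(settings = settings, strategies = strategies),
            class = "cea_config")
}

#' Retrieve a strategy by name
#' @param config A `cea_config`.
#' @param name Strategy name.
#' @return The matching [strategy_spec()].
#' @export
get_strategy <- function(config, name) {
  s <- config$strategies[[name]]
  if (is.null(s)) {
    stop("unknown strategy '", name, "'; available: ",
         paste(names(config$strategies), collapse = ", "), call. = FALSE)
  }
  s
}

#' Number of model cycles in the horizon
#'
#' `floor(horizon_years * 365.25 / cycle_length_days)`: the horizon is cut at
#' the last complete cycle so no partial terminal cycle is simulated. The
#' default 30-year horizon with 3-week cycles gives 521 cycles.
#'
#' @param x A `cea_config` or `model_settings`.
#' @return Integer cycle count.
#' @export
n_cycles <- function(x) {
  st <- if (inherits(x, "cea_config")) x$settings else x
  stopifnot(inherits(st, "model_settings"))
  as.integer(floor(st$horizon_years * 365.25 / st$cycle_length_days))
}
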