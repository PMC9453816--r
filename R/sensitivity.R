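# Deterministic (one-way, tornado-ranked) and probabilistic (Monte Carlo,
# CEAC) sensitivity analysis.

#' Draw one value from a parameter's tagged distribution
#'
#' Standard errors are reconstructed from the printed ranges by treating the
#' range as a 95\% interval: `SE = (high - low) / 3.92`. Sampling rules:
#' beta by method of moments on \[0, 1\]; gamma with `shape = (mean/SE)^2`,
#' `scale = SE^2/mean`; normal-tagged [ranged_value()]s as a raw normal
#' truncated at zero; [hazard_ratio()]s on the log scale with
#' `sdlog = (log(high) - log(low)) / 3.92` by default (their printed
#' intervals are multiplicatively symmetric), or as a truncated raw normal
#' with `hr_scale = "normal"`; `"fixed"` always returns the baseline. A beta
#' whose moment solution is infeasible falls back to uniform(low, high) with
#' a warning.
#'
#' @param x A [ranged_value()] or [hazard_ratio()].
#' @param hr_scale `"log"` (default) or `"normal"`, for hazard ratios.
#' @return One drawn value (uses the current RNG stream).
#' @export
sample_distribution <- function(x, hr_scale = c("log", "normal")) {
  hr_scale <- match.arg(hr_scale)
  if (inherits(x, "hazard_ratio")) {
    if (x$ci_high == x$ci_low) return(x$mean)
    if (hr_scale == "log") {
      sdlog <- (log(x$ci_high) - log(x$ci_low)) / 3.92
      return(exp(stats::rnorm(1, log(x$mean), sdlog)))
    }
    se <- (x$ci_high - x$ci_low) / 3.92
    repeat {
      v <- stats::rnorm(1, x$mean, se)
      if (v > 0) return(v)
    }
  }
  stopifnot(inherits(x, "ranged_value"))
  m <- x$mean
  se <- (x$high - x$low) / 3.92
  if (x$distribution == "fixed" || se == 0) return(m)
  switch(x$distribution,
    beta = {
      if (m <= 0 || m >= 1 || m * (1 - m) <= se^2) {
        warning("beta moment solution infeasible (mean ", m, ", se ", se,
                "); falling back to uniform(low, high)")
        return(stats::runif(1, x$low, x$high))
      }
      nu <- m * (1 - m) / se^2 - 1
      stats::rbeta(1, m * nu, (1 - m) * nu)
    },
    gamma = {
      if (m <= 0) return(m)
      stats::rgamma(1, shape = (m / se)^2, scale = se^2 / m)
    },
    normal = {
      repeat {
        v <- stats::rnorm(1, m, se)
        if (v > 0) return(v)
      }
    },
    stop("unknown distribution tag '", x$distribution, "'", call. = FALSE))
}

#' Draw a full joint parameter set for one PSA iteration
#'
#' Every parameter in [param_table()] whose distribution tag is not
#' `"fixed"` is drawn independently from its tagged distribution; the fitted
#' survival theta/kappa pairs are never sampled.
#'
#' @param config A `cea_config`.
#' @param hr_scale Passed to [sample_distribution()].
#' @return List with `config` (the overridden configuration) and `draws`
#'   (named numeric vector of the sampled values).
#' @export
sample_params <- function(config, hr_scale = "log") {
  entries <- param_registry(config)
  draws <- numeric(0)
  for (e in entries) {
    v <- config_get(config, e$path)
    if (e$kind == "ranged" && v$distribution == "fixed") next
    drawn <- sample_distribution(v, hr_scale = hr_scale)
    draws[e$id] <- drawn
    v$mean <- drawn
    config <- config_set(config, e$path, v)
  }
  list(config = config, draws = draws)
}

psa_compare <- function(summ, intervention, comparator, wtp) {
  i <- summ[summ$strategy == intervention, ]
  r <- summ[summ$strategy == comparator, ]
  dc <- i$cost - r$cost
  dq <- i$qaly - r$qaly
  data.frame(comparator = comparator, delta_cost = dc, delta_qaly = dq,
             icer = ifelse(dq != 0, dc / dq, NA_real_),
             nmb = net_monetary_benefit(dc, dq, wtp),
             cost_effective = net_monetary_benefit(dc, dq, wtp) > 0,
             dominant = dc < 0 && dq > 0)
}

#' Probabilistic sensitivity analysis
#'
#' `n_iter` Monte Carlo iterations: per iteration one joint draw of all
#' non-fixed parameters (see [sample_params()]) and a full model run per
#' strategy; the intervention is then classified against every comparator at
#' the willingness-to-pay threshold (cost-effective iff NMB > 0, which
#' subsumes dominance; dominant iff it costs less and yields more QALYs).
#' Bit-reproducible under a fixed seed. Iterations whose model run fails are
#' skipped with a warning; more than 1\% skipped raises an error.
#'
#' @param config A `cea_config`.
#' @param n_iter Number of iterations (default 1000).
#' @param wtp Threshold; defaults to the configured one.
#' @param seed Optional integer seed.
#' @param intervention Strategy compared against all others (default
#'   `"tislelizumab"`).
#' @param hr_scale Passed to [sample_distribution()].
#' @return An object of class `psa_result`: `samples` (one row per iteration
#'   and comparator: draws' incremental cost/QALY, ICER, NMB, flags),
#'   `strategy_values` (per-iteration cost/QALY per strategy), `summary`
#'   (per comparator: `prop_cost_effective`, `prop_dominant`), plus `wtp`,
#'   `n_iter`, `seed`, `n_skipped`.
#' @export
run_psa <- function(config, n_iter = 1000, wtp = NULL, seed = NULL,
                    intervention = "tislelizumab", hr_scale = "log") {
  stopifnot(n_iter >= 1)
  if (is.null(wtp)) wtp <- config$settings$wtp_per_qaly
  if (!is.null(seed)) set.seed(seed)
  get_strategy(config, intervention)  # validate early
  comparators <- setdiff(names(config$strategies), intervention)

  samples <- vector("list", n_iter)
  values <- vector("list", n_iter)
  skipped <- 0L
  for (it in seq_len(n_iter)) {
    drawn <- sample_params(config, hr_scale = hr_scale)
    res <- tryCatch(run_base_case(drawn$config), error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- skipped + 1L
      warning("PSA iteration ", it, " skipped: ", conditionMessage(res))
      next
    }
    cmp <- do.call(rbind, lapply(comparators, function(cm)
      psa_compare(res$summary, intervention, cm, wtp)))
    cmp <- cbind(iteration = it, cmp)
    samples[[it]] <- cmp
    values[[it]] <- cbind(iteration = it, res$summary)
  }
  if (skipped > 0.01 * n_iter) {
    stop(skipped, " of ", n_iter, " PSA iterations failed", call. = FALSE)
  }
  samples <- do.call(rbind, samples)
  values <- do.call(rbind, values)
  summ <- do.call(rbind, lapply(comparators, function(cm) {
    sub <- samples[samples$comparator == cm, ]
    data.frame(comparator = cm,
               prop_cost_effective = mean(sub$cost_effective),
               prop_dominant = mean(sub$dominant))
  }))
  structure(list(samples = samples, strategy_values = values, summary = summ,
                 intervention = intervention, wtp = wtp, n_iter = n_iter,
                 seed = seed, n_skipped = skipped),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA iterations with positive net monetary benefit at each
#' willingness-to-pay value, computed pointwise per comparator from the
#' stored incremental costs and QALYs. At the PSA's own threshold the curve
#' equals the summary proportion.
#'
#' @param psa A `psa_result` from [run_psa()].
#' @param lambda Vector of willingness-to-pay values.
#' @return Data frame with `comparator`, `lambda`, `prop_cost_effective`.
#' @export
ceac <- function(psa, lambda) {
  stopifnot(inherits(psa, "psa_result"), length(lambda) >= 1)
  s <- psa$samples
  do.call(rbind, lapply(unique(s$comparator), function(cm) {
    sub <- s[s$comparator == cm, ]
    data.frame(comparator = cm, lambda = lambda,
               prop_cost_effective = vapply(lambda, function(l)
                 mean(net_monetary_benefit(sub$delta_cost, sub$delta_qaly, l) > 0),
                 numeric(1)))
  }))
}

#' Default DSA outcome: the ICER of one pairwise comparison
#'
#' Returns a function of a configuration that runs both arms and computes
#' the ICER; if the incremental QALYs are not positive the comparison is
#' flagged as a dominance case and the outcome is `NA` (a signed ICER would
#' be meaningless).
#'
#' @param intervention,comparator Strategy names.
#' @return Function `config -> list(value, dominance)`.
#' @export
outcome_icer <- function(intervention = "tislelizumab",
                         comparator = "docetaxel") {
  function(config) {
    a <- evaluate_strategy(config, intervention)
    b <- evaluate_strategy(config, comparator)
    dc <- a$costs$total - b$costs$total
    dq <- a$effects$total - b$effects$total
    if (dq <= 0) list(value = NA_real_, dominance = TRUE)
    else list(value = dc / dq, dominance = FALSE)
  }
}

#' DSA outcome: net monetary benefit of one pairwise comparison
#'
#' Well-defined in every quadrant, so preferred for tornado ranking of
#' comparisons that can flip into dominance.
#'
#' @inheritParams outcome_icer
#' @param wtp Threshold; `NULL` uses the configured one.
#' @return Function `config -> list(value, dominance)`.
#' @export
outcome_nmb <- function(intervention = "tislelizumab",
                        comparator = "docetaxel", wtp = NULL) {
  function(config) {
    l <- if (is.null(wtp)) config$settings$wtp_per_qaly else wtp
    a <- evaluate_strategy(config, intervention)
    b <- evaluate_strategy(config, comparator)
    dc <- a$costs$total - b$costs$total
    dq <- a$effects$total - b$effects$total
    list(value = net_monetary_benefit(dc, dq, l), dominance = dc < 0 && dq > 0)
  }
}

#' One-way deterministic sensitivity analysis of a single parameter
#'
#' Re-runs the outcome with the named parameter at its low and at its high
#' bound, all else at baseline. The fitted theta/kappa pairs are not
#' sweepable (they are absent from [param_table()]).
#'
#' @param config A `cea_config`.
#' @param id Parameter id as in [param_table()].
#' @param outcome Outcome closure, e.g. [outcome_icer()] or [outcome_nmb()].
#' @return One-row data frame: `parameter`, `low`, `high`, `outcome_low`,
#'   `outcome_high`, `width`, `dominance_low`, `dominance_high`.
#' @export
dsa_one_way <- function(config, id, outcome = outcome_icer()) {
  pt <- param_table(config)
  row <- pt[pt$id == id, ]
  if (!nrow(row)) {
    stop("unknown parameter '", id, "'; valid names: ",
         paste(pt$id, collapse = ", "), call. = FALSE)
  }
  lo <- outcome(apply_override(config, id, row$low))
  hi <- outcome(apply_override(config, id, row$high))
  data.frame(parameter = id, low = row$low, high = row$high,
             outcome_low = lo$value, outcome_high = hi$value,
             width = abs(hi$value - lo$value),
             dominance_low = lo$dominance, dominance_high = hi$dominance,
             row.names = NULL)
}

#' One-way DSA over all sweepable parameters
#'
#' @param config A `cea_config`.
#' @param ids Parameter ids (default: every [param_table()] row with a
#'   non-degenerate range).
#' @param outcome As in [dsa_one_way()].
#' @return Data frame of [dsa_one_way()] rows.
#' @export
run_dsa <- function(config, ids = NULL, outcome = outcome_icer()) {
  pt <- param_table(config)
  if (is.null(ids)) ids <- pt$id[pt$high > pt$low]
  do.call(rbind, lapply(ids, function(id) dsa_one_way(config, id, outcome)))
}

#' Tornado ranking
#'
#' Entries sorted by descending bar width (`|outcome_high - outcome_low|`),
#' ties broken by parameter name, truncated to the top `k`.
#'
#' @param entries Data frame from [run_dsa()].
#' @param k Number of entries to keep (default 10).
#' @return The top-`k` rows.
#' @export
tornado_top <- function(entries, k = 10) {
  stopifnot(nrow(entries) >= 1)
  ord <- order(-entries$width, entries$parameter)
  utils::head(entries[ord, , drop = FALSE], k)
}
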