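# Synthetic individual-patient-data pathway: stands in for the published
# digitize-then-reconstruct step. Right-censored pseudo-IPD are drawn from a
# specified survival law, Kaplan-Meier curves estimated from them, and
# digitized-style KM coordinates inverted back into event/censoring times so
# the parametric fitting stage is testable without trial data.

survival_quantile <- function(curve, u) {
  # time at which S(t) = u
  curve <- as_survival_curve(curve)
  p <- curve$params
  switch(curve$family,
    loglogistic = ((1 - u) / (p$theta * u))^(1 / p$kappa),
    exponential = -log(u) / p$rate,
    weibull = stats::qweibull(u, p$shape, p$scale, lower.tail = FALSE),
    lognormal = stats::qlnorm(u, p$meanlog, p$sdlog, lower.tail = FALSE),
    gompertz = flexsurv::qgompertz(u, p$shape, p$rate, lower.tail = FALSE),
    ph = survival_quantile(p$base, u^(1 / p$hr)),
    aft = survival_quantile(p$base, u) / p$hr,
    stop("unknown survival family '", curve$family, "'", call. = FALSE))
}

#' Simulate right-censored pseudo individual patient data
#'
#' Event times are drawn by inverse-CDF sampling from the given survival law
#' (for the log-logistic, `t = ((1 - u) / (theta * u))^(1 / kappa)` with
#' `u ~ U(0, 1)`); independent exponential dropout and administrative
#' censoring at trial follow-up are superimposed, and each record is censored
#' at the earlier of the two if that precedes the event.
#'
#' @param law A survival curve or [loglogistic_params()].
#' @param n Number of subjects (>= 1).
#' @param admin_censor_time Administrative censoring horizon in cycles
#'   (default 35, about 24 months of follow-up).
#' @param dropout_rate Per-cycle exponential dropout rate (default 0).
#' @param seed Optional integer seed for reproducibility.
#' @return Data frame with columns `time` (cycles) and `event` (1 = event,
#'   0 = censored).
#' @export
simulate_ipd <- function(law, n, admin_censor_time = 35, dropout_rate = 0,
                         seed = NULL) {
  stopifnot(n >= 1, admin_censor_time > 0, dropout_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  curve <- as_survival_curve(law)
  u <- stats::runif(n)
  t_event <- survival_quantile(curve, u)
  t_drop <- if (dropout_rate > 0) stats::rexp(n, dropout_rate) else rep(Inf, n)
  t_cens <- pmin(t_drop, admin_censor_time)
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator via [survival::survfit()].
#'
#' @param ipd Data frame with columns `time`, `event`.
#' @return An object of class `km_curve`: a data frame with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival` (step coordinates at the
#'   observed times).
#' @export
km_estimate <- function(ipd) {
  ipd <- validate_ipd(ipd)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Invert digitized-style Kaplan-Meier coordinates into pseudo-IPD
#'
#' The simplified no-interval-censoring reconstruction: the survival drop at
#' each step time is allocated as events (cumulative rounding keeps the total
#' consistent with `round(n_start * dS)` per step), and residual survivors
#' are treated as administratively censored at the last coordinate, so the
#' output always holds exactly `n_start` records. On a censoring-free KM
#' curve this inverts [km_estimate()] exactly.
#'
#' @param curve Data frame with columns `time` and `survival` (step
#'   coordinates; survival must start at or below 1, be non-increasing and
#'   lie in \[0, 1\]). A `km_curve` works directly.
#' @param n_start Number of subjects at risk at time zero (>= 1).
#' @return Data frame with columns `time`, `event`.
#' @export
invert_km_coordinates <- function(curve, n_start) {
  stopifnot(n_start >= 1)
  if (!all(c("time", "survival") %in% names(curve)) || !nrow(curve)) {
    stop("curve must be a non-empty data frame with columns time, survival",
         call. = FALSE)
  }
  s <- curve$survival
  if (any(s < 0) || any(s > 1)) {
    stop("survival coordinates must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(s) > 1e-12)) {
    stop("survival coordinates must be non-increasing", call. = FALSE)
  }
  if (is.unsorted(curve$time)) {
    stop("time coordinates must be non-decreasing", call. = FALSE)
  }
  cum_events <- round(n_start * (1 - s))
  events <- diff(c(0, cum_events))
  times <- rep(curve$time, events)
  n_cens <- n_start - sum(events)
  data.frame(time = c(times, rep(curve$time[length(s)], n_cens)),
             event = c(rep(1L, length(times)), rep(0L, n_cens)))
}
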