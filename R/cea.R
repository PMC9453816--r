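# Incremental cost-effectiveness comparison, dominance detection, net
# monetary benefit and the decision against the willingness-to-pay threshold.

#' Net monetary benefit
#'
#' `NMB = lambda * dQALY - dCost`; positive iff the comparison is
#' cost-effective at the threshold.
#'
#' @param delta_cost,delta_qaly Incremental cost and QALYs.
#' @param wtp Willingness-to-pay threshold per QALY.
#' @return NMB (currency).
#' @export
net_monetary_benefit <- function(delta_cost, delta_qaly, wtp) {
  wtp * delta_qaly - delta_cost
}

#' Decision label for one pairwise comparison
#'
#' `"dominant"` when the comparator costs less and yields more QALYs than the
#' reference, `"dominated"` for the reverse; otherwise `"cost-effective"` iff
#' the net monetary benefit at the threshold is positive (equivalently, for
#' `dQALY > 0`, ICER < threshold).
#'
#' @param delta_cost,delta_qaly Incrementals of the comparator vs the
#'   reference.
#' @param wtp Willingness-to-pay threshold.
#' @return One of `"dominant"`, `"dominated"`, `"cost-effective"`,
#'   `"not cost-effective"`.
#' @export
decision_label <- function(delta_cost, delta_qaly, wtp) {
  if (delta_cost < 0 && delta_qaly > 0) return("dominant")
  if (delta_cost > 0 && delta_qaly < 0) return("dominated")
  if (net_monetary_benefit(delta_cost, delta_qaly, wtp) > 0) {
    "cost-effective"
  } else {
    "not cost-effective"
  }
}

#' Pairwise incremental comparison against a reference strategy
#'
#' For each non-reference strategy: incremental cost, incremental QALYs, the
#' ICER (reported whenever `dQALY != 0`; `NA` otherwise), the net monetary
#' benefit at the threshold and the decision label. Swapping comparator and
#' reference negates `dCost`, `dQALY` and NMB.
#'
#' @param summary Data frame with columns `strategy`, `cost`, `qaly` (as
#'   produced by [run_base_case()]).
#' @param reference Reference strategy name (default `"docetaxel"`).
#' @param wtp Willingness-to-pay threshold per QALY.
#' @return Data frame with one row per comparison: `strategy`, `reference`,
#'   `cost`, `qaly`, `delta_cost`, `delta_qaly`, `icer`, `nmb`, `decision`.
#' @export
compare_strategies <- function(summary, reference = "docetaxel", wtp) {
  stopifnot(all(c("strategy", "cost", "qaly") %in% names(summary)),
            nrow(summary) >= 2)
  if (!reference %in% summary$strategy) {
    stop("reference strategy '", reference, "' not present", call. = FALSE)
  }
  ref <- summary[summary$strategy == reference, ]
  others <- summary[summary$strategy != reference, , drop = FALSE]
  dc <- others$cost - ref$cost
  dq <- others$qaly - ref$qaly
  icer <- ifelse(dq != 0, dc / dq, NA_real_)
  data.frame(strategy = others$strategy, reference = reference,
             cost = others$cost, qaly = others$qaly,
             delta_cost = dc, delta_qaly = dq, icer = icer,
             nmb = net_monetary_benefit(dc, dq, wtp),
             decision = mapply(decision_label, dc, dq, MoreArgs = list(wtp = wtp)),
             row.names = NULL)
}

#' Efficiency-frontier (sequential) ICER table
#'
#' Strategies are ordered by cost; each is compared with the previous
#' strategy on the frontier. Strongly dominated strategies (more costly, no
#' more effective) are flagged and skipped as comparators; extendedly
#' dominated strategies (sequential ICER above the next one's) are flagged
#' likewise.
#'
#' @inheritParams compare_strategies
#' @return Data frame with `strategy`, `cost`, `qaly`, `delta_cost`,
#'   `delta_qaly`, `icer`, `status` (`"reference"`, `"nondominated"`,
#'   `"dominated"`, `"extendedly dominated"`).
#' @export
icer_frontier <- function(summary, wtp) {
  s <- summary[order(summary$cost, summary$qaly), , drop = FALSE]
  n <- nrow(s)
  status <- rep("nondominated", n); status[1] <- "reference"
  # strong dominance
  for (i in 2:n) {
    for (j in seq_len(i - 1)) {
      if (status[j] %in% c("reference", "nondominated") &&
          s$qaly[i] <= s$qaly[j] && s$cost[i] >= s$cost[j]) {
        status[i] <- "dominated"
        break
      }
    }
  }
  # extended dominance: iterate until sequential ICERs increase along the frontier
  repeat {
    idx <- which(status != "dominated" & status != "extendedly dominated")
    if (length(idx) < 3) break
    icers <- diff(s$cost[idx]) / diff(s$qaly[idx])
    drop <- which(diff(icers) < 0)
    if (!length(drop)) break
    status[idx[drop[1] + 1]] <- "extendedly dominated"
  }
  idx <- which(status != "dominated" & status != "extendedly dominated")
  dc <- dq <- icer <- rep(NA_real_, n)
  if (length(idx) > 1) {
    dc[idx[-1]] <- diff(s$cost[idx])
    dq[idx[-1]] <- diff(s$qaly[idx])
    icer[idx[-1]] <- dc[idx[-1]] / dq[idx[-1]]
  }
  data.frame(strategy = s$strategy, cost = s$cost, qaly = s$qaly,
             delta_cost = dc, delta_qaly = dq, icer = icer, status = status,
             row.names = NULL)
}
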