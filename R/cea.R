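#' Incremental cost-effectiveness comparison of two strategies
#'
#' Computes the ICER from unrounded inputs, labels simple dominance
#' (one strategy cheaper and more effective), and reports net monetary
#' benefit and the cost-effective strategy at the willingness-to-pay
#' threshold. Effects are the discounted QALY totals.
#'
#' @param a,b either [run_cohort()] traces, or lists with elements `name`,
#'   `cost`, `effect` (and optionally `effect_undiscounted`).
#' @param wtp willingness to pay, $ per QALY.
#' @return An object of class `"cea_result"`: a list with `strategies`
#'   (data frame of per-strategy cost, effect, NMB), `incremental_cost`,
#'   `incremental_effect`, `icer` (numeric, or `NA` with a `dominance`
#'   label), `dominance`, `decision` (name of the NMB-maximising strategy).
#' @examples
#' r <- compute_icer(run_cohort("scrt"), run_cohort("lcrt"))
#' r$icer
#' @export
compute_icer <- function(a, b, wtp = 100000) {
  as_outcome <- function(x) {
    if (inherits(x, "cohort_trace"))
      list(name = x$strategy, cost = x$discounted_costs,
           effect = x$discounted_qalys,
           effect_undiscounted = x$undiscounted_qalys)
    else x
  }
  a <- as_outcome(a); b <- as_outcome(b)
  dc <- b$cost - a$cost
  de <- b$effect - a$effect
  dominance <- NA_character_
  icer <- NA_real_
  if (de == 0) {
    dominance <- if (dc == 0) "equivalent" else if (dc < 0)
      paste0(b$name, " dominates (equal effect, cheaper)") else
      paste0(a$name, " dominates (equal effect, cheaper)")
  } else if (dc <= 0 && de > 0) {
    dominance <- paste0(b$name, " dominates")
    icer <- dc / de
  } else if (dc >= 0 && de < 0) {
    dominance <- paste0(a$name, " dominates")
    icer <- dc / de
  } else {
    icer <- dc / de
  }
  nmb <- function(x) wtp * x$effect - x$cost
  strategies <- data.frame(
    strategy = c(a$name, b$name),
    cost = c(a$cost, b$cost),
    effect = c(a$effect, b$effect),
    effect_undiscounted = c(a$effect_undiscounted %||% NA_real_,
                            b$effect_undiscounted %||% NA_real_),
    nmb = c(nmb(a), nmb(b)),
    stringsAsFactors = FALSE
  )
  decision <- strategies$strategy[which.max(strategies$nmb)]
  structure(list(strategies = strategies, incremental_cost = dc,
                 incremental_effect = de, icer = icer,
                 dominance = dominance, wtp = wtp, decision = decision),
            class = "cea_result")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>\n")
  s <- x$strategies
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-5s cost $%s  effect %.4f QALY  NMB $%s\n",
                toupper(s$strategy[i]),
                format(round(s$cost[i]), big.mark = ","), s$effect[i],
                format(round(s$nmb[i]), big.mark = ",")))
  if (!is.na(x$dominance)) {
    cat("  ", x$dominance, "\n")
  } else {
    cat(sprintf("  ICER $%s/QALY (WTP $%s)\n",
                format(round(x$icer), big.mark = ","),
                format(x$wtp, big.mark = ",")))
  }
  cat("  cost-effective:", toupper(x$decision), "\n")
  invisible(x)
}

#' Net monetary benefit
#'
#' @param cost,effect per-strategy discounted cost ($) and effect (QALY).
#' @param wtp willingness to pay, $ per QALY.
#' @return `wtp * effect - cost`.
#' @export
net_monetary_benefit <- function(cost, effect, wtp = 100000) {
  wtp * effect - cost
}

#' Cost per event prevented
#'
#' `(cost_a - cost_b) / (events_a - events_b)` on a common per-patient
#' basis: the extra spending of the costlier strategy per event it
#' prevents. Returns `NA` (with a message attribute) when the event
#' counts are equal.
#'
#' @param cost_a,cost_b per-patient costs of strategies a and b.
#' @param events_a,events_b per-patient event proportions (or counts on a
#'   common denominator).
#' @return Dollars per event prevented (positive when a costs more and b
#'   has more events), or `NA` if undefined.
#' @examples
#' cost_per_event_prevented(58369, 48336, 0.17, 0.28)  # LCRT vs SCRT colostomies
#' @export
cost_per_event_prevented <- function(cost_a, cost_b, events_a, events_b) {
  if (events_a == events_b) {
    out <- NA_real_
    attr(out, "note") <- "equal event counts: cost per event prevented undefined"
    return(out)
  }
  (cost_a - cost_b) / (events_b - events_a)
}

#' Number needed to treat
#'
#' Reciprocal of the absolute risk difference: patients that must receive
#' the first strategy instead of the second to prevent one event. A
#' negative value (labelled `"harm"`) means the first strategy has *more*
#' events.
#'
#' @param prop_a,prop_b event proportions in `[0, 1]` under the comparator
#'   (a) and the intervention (b).
#' @return NNT (`1 / (prop_a - prop_b)`), `NA` if the proportions are
#'   equal; attribute `direction` is `"benefit"` or `"harm"`.
#' @examples
#' number_needed_to_treat(0.28, 0.17)  # 9.09
#' @export
number_needed_to_treat <- function(prop_a, prop_b) {
  stopifnot(prop_a >= 0, prop_a <= 1, prop_b >= 0, prop_b <= 1)
  if (prop_a == prop_b) {
    out <- NA_real_
    attr(out, "note") <- "equal proportions: NNT undefined"
    return(out)
  }
  out <- 1 / (prop_a - prop_b)
  attr(out, "direction") <- if (out > 0) "benefit" else "harm"
  out
}

#' Evaluate both strategies under a scenario
#'
#' Runs the cohort engine for SCRT and LCRT and assembles the incremental
#' comparison (SCRT is the reference, as the cheaper strategy).
#'
#' @param params an `rc_params` object (already scenario-resolved), or
#'   `scenario` may be given.
#' @param scenario optional [scenario_spec()] applied to `params` first.
#' @param life_table a [make_life_table()] object.
#' @param wtp willingness to pay, $ per QALY (defaults to `params$wtp`).
#' @param ... passed to [run_cohort()] (reward timing etc.).
#' @return A `"cea_result"` (see [compute_icer()]) with the two traces
#'   attached as `traces`.
#' @examples
#' evaluate_strategies(rc_parameters())
#' @export
evaluate_strategies <- function(params = rc_parameters(), scenario = NULL,
                                life_table = default_life_table(),
                                wtp = NULL, ...) {
  if (!is.null(scenario)) params <- apply_scenario(params, scenario)
  wtp <- wtp %||% params$wtp
  tr_s <- run_cohort("scrt", params, life_table, ...)
  tr_l <- run_cohort("lcrt", params, life_table, ...)
  out <- compute_icer(tr_s, tr_l, wtp = wtp)
  out$traces <- list(scrt = tr_s, lcrt = tr_l)
  out
}
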