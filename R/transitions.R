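#' Health states of the model
#'
#' `NED_LAR` / `NED_APR`: no evidence of disease after low anterior /
#' abdominoperineal resection; `LOCAL_RECURRENCE`: pelvic recurrence not
#' amenable to (or failing) salvage; `SALVAGED_LR`: disease-free after
#' salvage surgery for a first local recurrence; `DISTANT_RECURRENCE`:
#' metastatic disease; `DEAD` is absorbing.
#'
#' @return Character vector of the six state names, in matrix order.
#' @export
health_states <- function() {
  c("NED_LAR", "NED_APR", "LOCAL_RECURRENCE", "SALVAGED_LR",
    "DISTANT_RECURRENCE", "DEAD")
}

#' Convert a multi-year probability to a per-cycle probability
#'
#' Under a constant-hazard assumption, a cumulative probability `p` over
#' `horizon_years` corresponds to a per-cycle probability
#' `1 - (1 - p)^(cycle_length_years / horizon_years)`, so compounding the
#' per-cycle value over the horizon recovers `p` exactly.
#'
#' @param p cumulative probability in `[0, 1]` (a [probability()] object is
#'   also accepted, in which case its own horizon is used).
#' @param horizon_years horizon over which `p` is defined, in years.
#' @param cycle_length_years model cycle length, in years (default 1).
#' @return Per-cycle probability.
#' @examples
#' pc <- prob_to_cycle(0.071, 10)
#' 1 - (1 - pc)^10   # 0.071
#' @export
prob_to_cycle <- function(p, horizon_years = 1, cycle_length_years = 1) {
  if (inherits(p, "probability")) {
    horizon_years <- p$horizon_years
    p <- p$value
  }
  if (cycle_length_years <= 0) stop("cycle length must be positive")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (p == 1) return(1)  # absorbing special case
  1 - (1 - p)^(cycle_length_years / horizon_years)
}

## Compose competing per-cycle probabilities via independent hazards:
## convert each probability to a hazard, sum, convert back, and apportion
## cause-specific shares proportional to hazards. Guarantees the total
## never exceeds 1 for any inputs. Vectorised over samples.
## Returns a list of cause-specific per-cycle probabilities.
compose_competing <- function(probs) {
  h <- lapply(probs, function(p) -log(1 - pmin(p, 1 - 1e-15)))
  H <- Reduce(`+`, h)
  Ptot <- 1 - exp(-H)
  share <- ifelse(H > 0, Ptot / H, 0)
  lapply(h, function(hi) ifelse(H > 0, hi * share, 0))
}

## Per-cycle event probabilities for one cycle, given scalar-or-vector
## parameter components. Returns list of named vectors.
cycle_probs <- function(lr10, dr10, dmet5, q_bg, p_salv, cycle_len = 1) {
  p_lr <- 1 - (1 - lr10)^(cycle_len / 10)
  p_dr <- 1 - (1 - dr10)^(cycle_len / 10)
  p_dm <- 1 - (1 - dmet5)^(cycle_len / 5)
  ned <- compose_competing(list(lr = p_lr, dr = p_dr, bg = q_bg))
  rec <- compose_competing(list(dm = p_dm, bg = q_bg))
  list(
    ned_lr_salv = ned$lr * p_salv,      # NED -> salvaged (via first LR)
    ned_lr      = ned$lr * (1 - p_salv),# NED -> unsalvaged local recurrence
    ned_lr_tot  = ned$lr,
    ned_dr      = ned$dr,
    ned_bg      = ned$bg,
    rec_death   = rec$dm + rec$bg       # LR / DR -> dead (cancer + background)
  )
}

#' Per-cycle transition matrix for a strategy
#'
#' Builds the row-stochastic transition matrix applied between cycle
#' `cycle` and `cycle + 1`. NED states move to local recurrence (split at
#' first transition between salvage and unsalvaged recurrence), distant
#' recurrence, and background death; competing risks are composed on the
#' hazard scale so each row sums to one for any admissible inputs. The
#' salvaged state faces the same recurrence hazards as NED but with no
#' second salvage; local and distant recurrence face cancer death (the
#' metastatic rate) plus background death; `DEAD` is absorbing.
#'
#' @param params an `rc_params` object.
#' @param strategy `"scrt"` or `"lcrt"`.
#' @param cycle 0-based cycle index in `[0, horizon_cycles)`; age at cycle
#'   `k` is `start_age + k`.
#' @param life_table a [make_life_table()] object.
#' @return A 6x6 matrix with `dimnames` [health_states()].
#' @export
transition_matrix <- function(params, strategy = c("scrt", "lcrt"), cycle,
                              life_table = default_life_table()) {
  strategy <- match.arg(strategy)
  if (cycle < 0 || cycle >= params$horizon_cycles)
    stop("cycle must lie in [0, horizon_cycles)")
  lr10 <- strategy_lr10(params, strategy)
  q_bg <- background_mortality(life_table, params$start_age + cycle)
  pr <- cycle_probs(lr10, params$p_distant_recurrence_10y,
                    params$p_death_metastatic_5y, q_bg,
                    params$p_salvage_lr, params$cycle_length_years)
  s <- health_states()
  P <- matrix(0, 6, 6, dimnames = list(s, s))
  for (ned in c("NED_LAR", "NED_APR")) {
    P[ned, "LOCAL_RECURRENCE"]   <- pr$ned_lr
    P[ned, "SALVAGED_LR"]        <- pr$ned_lr_salv
    P[ned, "DISTANT_RECURRENCE"] <- pr$ned_dr
    P[ned, "DEAD"]               <- pr$ned_bg
    P[ned, ned] <- 1 - pr$ned_lr_tot - pr$ned_dr - pr$ned_bg
  }
  P["SALVAGED_LR", "LOCAL_RECURRENCE"]   <- pr$ned_lr_tot
  P["SALVAGED_LR", "DISTANT_RECURRENCE"] <- pr$ned_dr
  P["SALVAGED_LR", "DEAD"]               <- pr$ned_bg
  P["SALVAGED_LR", "SALVAGED_LR"] <- 1 - pr$ned_lr_tot - pr$ned_dr - pr$ned_bg
  for (rec in c("LOCAL_RECURRENCE", "DISTANT_RECURRENCE")) {
    P[rec, "DEAD"] <- pr$rec_death
    P[rec, rec] <- 1 - pr$rec_death
  }
  P["DEAD", "DEAD"] <- 1
  bad <- abs(rowSums(P) - 1) > 1e-12
  if (any(bad))
    stop("internal error: non-stochastic row(s): ",
         paste(s[bad], collapse = ", "))
  P
}

## strategy-resolved 10-y local recurrence probability
strategy_lr10 <- function(params, strategy) {
  if (strategy == "scrt" && !is.na(params$p_local_recurrence_10y_scrt))
    params$p_local_recurrence_10y_scrt
  else
    params$p_local_recurrence_10y
}

## strategy-resolved radiation cost and LAR share
strategy_radiation_cost <- function(params, strategy) {
  mod <- if (strategy == "scrt") params$radiation_scrt else params$radiation_lcrt
  params[[paste0("c_", strategy, "_", mod)]]
}

strategy_lar_share <- function(params, strategy) {
  if (strategy == "scrt") params$p_lar_scrt else params$p_lar_lcrt
}
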