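#' Individual-level Monte Carlo simulation
#'
#' Simulates `n_patients` independent trajectories through the same
#' transition process as the cohort engine, tracking each patient's event
#' history: surgery type at entry, salvage of a first local recurrence,
#' permanent colostomy (set by APR at entry or by APR-type salvage, never
#' unset), and cause of death (cancer vs background). Costs and QALYs
#' accrue per patient under the same conventions as [run_cohort()]
#' (boundary reward timing, annuity colostomy supplies), so microsim
#' means converge to the cohort values as `n_patients` grows.
#'
#' All randomness derives from `seed`; the same seed reproduces the
#' summary bit-for-bit (draws are made cohort-wide in a fixed order, so
#' results do not depend on any scheduling).
#'
#' @param model a [strategy_model()] or strategy name.
#' @param params an `rc_params` object (used when `model` is a name).
#' @param life_table a [make_life_table()] object.
#' @param n_patients number of simulated patients.
#' @param seed integer seed.
#' @param reward_timing reward accrual convention (see [run_cohort()]).
#' @return An object of class `"microsim_result"`: list with `n`, `seed`,
#'   `strategy`, `mean_cost`, `mean_qaly_disc`, `mean_qaly_undisc`,
#'   `se_cost`, `se_qaly_disc`, `colostomy_proportion`, `salvage_proportion`,
#'   `deaths` (named counts by cause), `occupancy` (state frequencies at
#'   each cycle boundary).
#' @examples
#' run_microsim("scrt", n_patients = 1000, seed = 1)
#' @export
run_microsim <- function(model, params = rc_parameters(),
                         life_table = default_life_table(),
                         n_patients = 10000L, seed = 1L,
                         reward_timing = c("boundary", "start", "end", "half")) {
  reward_timing <- match.arg(reward_timing)
  if (is.character(model)) model <- strategy_model(model, params)
  stopifnot(inherits(model, "strategy_model"), n_patients >= 1)
  p <- model$params
  T <- p$horizon_cycles
  n <- as.integer(n_patients)
  set.seed(seed)

  disc <- (1 + p$discount_rate)^-(0:T)
  wts <- reward_weights(T, p$discount_rate, reward_timing)
  wts0 <- reward_weights(T, 0, reward_timing)
  ann <- rev(cumsum(rev(disc)))      # remaining-horizon annuity at t = 0..T
  u <- model$utilities               # per-state utilities, engine order
  p_lar <- unname(model$initial["NED_LAR"])

  ## state codes: 1 NED_LAR, 2 NED_APR, 3 LR, 4 SALV, 5 DR, 6 DEAD
  state <- ifelse(stats::runif(n) < p_lar, 1L, 2L)
  lar_origin <- state == 1L
  colostomy <- !lar_origin
  salvaged <- logical(n)
  death_cause <- rep(NA_character_, n)
  cost <- ifelse(lar_origin, p$c_lar, p$c_apr) + model$radiation_cost +
    p$n_adjuvant_chemo_cycles * p$c_capecitabine_cycle
  cost <- cost + ifelse(colostomy, p$c_colostomy_supplies * ann[1], 0)
  qd <- u[state] * wts[1]
  qu <- u[state] * wts0[1]

  counts <- matrix(0L, T + 1, 6,
                   dimnames = list(cycle = 0:T, state = health_states()))
  counts[1, ] <- tabulate(state, 6L)

  for (t in 1:T) {
    q_bg <- background_mortality(life_table, p$start_age + t - 1)
    pr <- cycle_probs(model$lr10, p$p_distant_recurrence_10y,
                      p$p_death_metastatic_5y, q_bg, p$p_salvage_lr,
                      p$cycle_length_years)
    ## cause split within recurrence-state deaths, for cause-of-death tags
    rec <- compose_competing(list(dm = 1 - (1 - p$p_death_metastatic_5y)^
                                    (p$cycle_length_years / 5), bg = q_bg))
    uu <- stats::runif(n)
    new_state <- state
    ## NED and salvaged share hazards; salvaged has no second salvage
    ned <- state == 1L | state == 2L
    if (any(ned)) {
      cp <- cumsum(c(pr$ned_lr, pr$ned_lr_salv, pr$ned_dr, pr$ned_bg))
      k <- findInterval(uu[ned], cp) + 1L  # 1 LR, 2 SALV, 3 DR, 4 dead, 5 stay
      dest <- c(3L, 4L, 5L, 6L, 0L)[k]
      idx <- which(ned)
      moved <- dest != 0L
      new_state[idx[moved]] <- dest[moved]
      died <- idx[dest == 6L]
      death_cause[died] <- "background"
      sv <- idx[dest == 4L]
      if (length(sv)) {
        salvaged[sv] <- TRUE
        cost[sv] <- cost[sv] + p$c_salvage * disc[t + 1]
        newcol <- sv[!colostomy[sv]]
        if (length(newcol)) {
          colostomy[newcol] <- TRUE
          cost[newcol] <- cost[newcol] + p$c_colostomy_supplies * ann[t + 1]
        }
      }
    }
    svst <- state == 4L
    if (any(svst)) {
      cp <- cumsum(c(pr$ned_lr_tot, pr$ned_dr, pr$ned_bg))
      k <- findInterval(uu[svst], cp) + 1L  # 1 LR, 2 DR, 3 dead, 4 stay
      dest <- c(3L, 5L, 6L, 0L)[k]
      idx <- which(svst)
      moved <- dest != 0L
      new_state[idx[moved]] <- dest[moved]
      death_cause[idx[dest == 6L]] <- "background"
    }
    recst <- state == 3L | state == 5L
    if (any(recst)) {
      cp <- cumsum(c(rec$dm, rec$bg))
      k <- findInterval(uu[recst], cp) + 1L  # 1 cancer death, 2 bg death, 3 stay
      idx <- which(recst)
      new_state[idx[k <= 2L]] <- 6L
      death_cause[idx[k == 1L]] <- "cancer"
      death_cause[idx[k == 2L]] <- "background"
    }
    state <- new_state
    counts[t + 1, ] <- tabulate(state, 6L)
    qd <- qd + u[state] * wts[t + 1]
    qu <- qu + u[state] * wts0[t + 1]
  }

  structure(list(
    n = n, seed = seed, strategy = model$name,
    mean_cost = mean(cost),
    mean_qaly_disc = mean(qd),
    mean_qaly_undisc = mean(qu),
    se_cost = stats::sd(cost) / sqrt(n),
    se_qaly_disc = stats::sd(qd) / sqrt(n),
    colostomy_proportion = mean(colostomy),
    salvage_proportion = mean(salvaged),
    deaths = c(cancer = sum(death_cause == "cancer", na.rm = TRUE),
               background = sum(death_cause == "background", na.rm = TRUE)),
    occupancy = counts / n
  ), class = "microsim_result")
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("<microsim_result> %s, n = %s (seed %d)\n", toupper(x$strategy),
              format(x$n, big.mark = ","), x$seed))
  cat(sprintf("  mean cost $%s (se %.0f)\n",
              format(round(x$mean_cost), big.mark = ","), x$se_cost))
  cat(sprintf("  mean QALYs %.4f disc / %.4f undisc (se %.4f)\n",
              x$mean_qaly_disc, x$mean_qaly_undisc, x$se_qaly_disc))
  cat(sprintf("  ever-colostomy %.2f%%, salvaged %.2f%%\n",
              100 * x$colostomy_proportion, 100 * x$salvage_proportion))
  invisible(x)
}

#' Proportion of patients ever carrying a permanent colostomy
#'
#' The denominator includes decedents: the flag records whether a
#' colostomy was ever created (APR at entry or APR-type salvage).
#'
#' @param summary a [run_microsim()] result.
#' @return Proportion in `[0, 1]`.
#' @export
colostomy_proportion <- function(summary) {
  stopifnot(inherits(summary, "microsim_result"))
  summary$colostomy_proportion
}
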