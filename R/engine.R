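## Internal vectorised cohort engine.
##
## Evaluates the Markov cohort for n parameter draws simultaneously: every
## component of `theta` is a vector of length n (or 1, recycled). The
## probabilistic sensitivity analysis runs 1e5 draws through this core in a
## handful of vectorised cycle updates; run_cohort() wraps the n = 1 case
## and additionally returns the full state-occupancy trace.
##
## theta components:
##   p_lar, rad_cost, lr10, dr10, dmet5, p_salv,
##   u_lar, u_apr, u_lr, u_sv, u_dr,
##   c_lar, c_apr, c_sup, c_cape, c_salv, n_chemo, disc
## scalars: T (cycles), start_age, cycle_len, life_table, reward_timing,
##   colostomy_cost_mode

reward_weights <- function(T, disc, timing) {
  d <- (1 + disc)^-(0:T)
  w <- switch(timing,
    boundary = d,
    start = c(d[1:T], 0),
    end   = c(0, d[2:(T + 1)]),
    half  = c(0.5 * d[1], d[2:T], 0.5 * d[T + 1]),
    stop("unknown reward timing: ", timing))
  w
}

cohort_core <- function(theta, life_table, T = 10L, start_age = 65L,
                        cycle_len = 1, reward_timing = "boundary",
                        colostomy_cost_mode = "annuity",
                        keep_trace = FALSE) {
  n <- max(lengths(theta))
  if (keep_trace && n != 1L)
    stop("keep_trace is only supported for a single parameter draw")
  th <- lapply(theta, rep_len, n)
  ## state columns: 1 NED_LAR, 2 NED_APR, 3 LR, 4 SALV, 5 DR, 6 DEAD
  X <- matrix(0, n, 6)
  X[, 1] <- th$p_lar
  X[, 2] <- 1 - th$p_lar
  disc <- th$disc
  dfac <- outer(disc, 0:T, function(r, t) (1 + r)^-t)  # n x (T+1)

  uw <- matrix(0, n, T + 1)   # discounted utility of occupancy at t = 0..T
  uu <- numeric(n)            # undiscounted QALY accumulator
  ly <- numeric(n)            # undiscounted life-years (alive occupancy)
  sup_cost <- numeric(n); salv_cost <- numeric(n); evercol <- numeric(n)
  occ <- if (keep_trace) array(0, c(T + 1, 6)) else NULL
  inc_lr <- inc_dr <- ned_at_risk <- lrdr_at_risk <- numeric(T)
  sv_in <- numeric(T)

  util <- function(Xm) Xm[, 1] * th$u_lar + Xm[, 2] * th$u_apr +
    Xm[, 3] * th$u_lr + Xm[, 4] * th$u_sv + Xm[, 5] * th$u_dr

  ## remaining-horizon discounted annuity factor per acquisition time
  ann <- t(apply(dfac, 1, function(d) rev(cumsum(rev(d)))))  # n x (T+1)
  if (n == 1) ann <- matrix(rev(cumsum(rev(dfac[1, ]))), 1)

  ## entry (cycle 0): radiation + surgery mix + adjuvant chemotherapy
  cost <- th$rad_cost + th$p_lar * th$c_lar + (1 - th$p_lar) * th$c_apr +
    th$n_chemo * th$c_cape
  if (colostomy_cost_mode == "annuity")
    sup_cost <- (1 - th$p_lar) * th$c_sup * ann[, 1]
  evercol <- 1 - th$p_lar

  uw[, 1] <- util(X)
  uu <- uu + util(X)
  ly <- ly + rowSums(X[, 1:5, drop = FALSE])
  if (keep_trace) occ[1, ] <- X[1, ]

  for (t in 1:T) {
    q_bg <- background_mortality(life_table, start_age + t - 1)
    pr <- cycle_probs(th$lr10, th$dr10, th$dmet5, q_bg, th$p_salv, cycle_len)
    ned <- X[, 1] + X[, 2]
    sv  <- X[, 4]
    if (keep_trace) {
      ned_at_risk[t] <- ned
      lrdr_at_risk[t] <- ned + sv
      inc_lr[t] <- ned * pr$ned_lr_tot           # first local recurrences
      inc_dr[t] <- (ned + sv) * pr$ned_dr        # first distant recurrences
    }
    sv_new <- ned * pr$ned_lr_salv               # salvage events at time t
    sv_in[t] <- if (n == 1) sv_new else NA_real_
    stay_ned <- 1 - pr$ned_lr_tot - pr$ned_dr - pr$ned_bg
    newX <- matrix(0, n, 6)
    newX[, 1] <- X[, 1] * stay_ned
    newX[, 2] <- X[, 2] * stay_ned
    newX[, 3] <- X[, 3] * (1 - pr$rec_death) + ned * pr$ned_lr + sv * pr$ned_lr_tot
    newX[, 4] <- sv * stay_ned + sv_new
    newX[, 5] <- X[, 5] * (1 - pr$rec_death) + (ned + sv) * pr$ned_dr
    newX[, 6] <- X[, 6] + X[, 3] * pr$rec_death + X[, 5] * pr$rec_death +
      (ned + sv) * pr$ned_bg
    X <- newX

    ## salvage surgery at arrival time t; new colostomies among LAR-origin
    salv_cost <- salv_cost + sv_new * th$c_salv * dfac[, t + 1]
    if (colostomy_cost_mode == "annuity")
      sup_cost <- sup_cost + sv_new * th$p_lar * th$c_sup * ann[, t + 1]
    evercol <- evercol + sv_new * th$p_lar

    uw[, t + 1] <- util(X)
    uu <- uu + util(X)
    ly <- ly + rowSums(X[, 1:5, drop = FALSE])
    if (keep_trace) occ[t + 1, ] <- X[1, ]
  }

  ## uw holds raw (undiscounted) occupancy utilities at t = 0..T; apply the
  ## timing weights with and without discounting
  if (length(unique(disc)) == 1L) {
    qd <- as.vector(uw %*% reward_weights(T, disc[1], reward_timing))
  } else {
    qd <- vapply(seq_len(n), function(i)
      sum(uw[i, ] * reward_weights(T, disc[i], reward_timing)), numeric(1))
  }
  qu <- as.vector(uw %*% reward_weights(T, 0, reward_timing))

  if (colostomy_cost_mode == "occupancy") {
    ## per-cycle accrual in NED_APR + SALVAGED_LR under the reward weights
    ## (requires the per-cycle occupancy; only supported for n == 1)
    if (!keep_trace)
      stop("colostomy_cost_mode = 'occupancy' requires keep_trace = TRUE")
    sup_cost <- sum((occ[, 2] + occ[, 4]) * th$c_sup *
                      reward_weights(T, disc[1], reward_timing))
  }

  total_cost <- cost + salv_cost + sup_cost
  out <- list(cost = total_cost, qaly_disc = qd, qaly_undisc = qu,
              life_years = ly, evercol = evercol)
  if (keep_trace) {
    out$occupancy <- occ
    out$inc_lr <- inc_lr; out$inc_dr <- inc_dr
    out$ned_at_risk <- ned_at_risk; out$lrdr_at_risk <- lrdr_at_risk
    out$sv_in <- sv_in
    out$cost_components <- c(entry = unname(cost[1]),
                             salvage = unname(salv_cost[1]),
                             colostomy_supplies = unname(sup_cost[1]))
  }
  out
}

## Assemble the engine parameter vectors for a strategy from an rc_params
## object (optionally with vectorised overrides from a PSA sample matrix).
theta_for_strategy <- function(params, strategy, overrides = NULL) {
  g <- function(id) {
    if (!is.null(overrides) && id %in% colnames(overrides)) overrides[, id]
    else params[[id]]
  }
  p_apr <- g(if (strategy == "scrt") "p_apr_scrt" else "p_apr_lcrt")
  rad_id <- paste0("c_", strategy, "_",
                   if (strategy == "scrt") params$radiation_scrt
                   else params$radiation_lcrt)
  lr10 <- if (strategy == "scrt") {
    ov <- if (!is.null(overrides) &&
              "p_local_recurrence_10y_scrt" %in% colnames(overrides))
      overrides[, "p_local_recurrence_10y_scrt"]
    else params$p_local_recurrence_10y_scrt
    if (all(is.na(ov))) g("p_local_recurrence_10y") else ov
  } else g("p_local_recurrence_10y")
  list(
    p_lar = 1 - p_apr,
    rad_cost = g(rad_id),
    lr10 = lr10,
    dr10 = g("p_distant_recurrence_10y"),
    dmet5 = g("p_death_metastatic_5y"),
    p_salv = g("p_salvage_lr"),
    u_lar = g("u_ned_lar"), u_apr = g("u_ned_apr"),
    u_lr = g("u_local_recurrence"), u_sv = g("u_salvaged_lr"),
    u_dr = g("u_distant_recurrence"),
    c_lar = g("c_lar"), c_apr = g("c_apr"),
    c_sup = g("c_colostomy_supplies"), c_cape = g("c_capecitabine_cycle"),
    c_salv = g("c_salvage"), n_chemo = g("n_adjuvant_chemo_cycles"),
    disc = g("discount_rate")
  )
}
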