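test_that("occupancy is conserved and death is monotone (property sweep)", {
  lt <- base_lt
  for (seed in 1:25) {
    p <- random_parameter_set(seed)
    tr <- run_cohort("scrt", p, lt)
    expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-10)
    expect_true(all(diff(tr$occupancy[, "DEAD"]) >= -1e-14))
    expect_lte(tr$discounted_qalys, p$horizon_cycles + 1)  # boundary accrual
  }
})

test_that("event-free cohort reproduces horizon and annuity identities", {
  p <- params_no_events()
  lt0 <- zero_mortality()
  ## end-of-cycle accrual: 10 cycles of utility 1
  p0 <- set_parameter(p, "discount_rate", 0)
  tr <- run_cohort("scrt", p0, lt0, reward_timing = "end")
  expect_equal(tr$discounted_qalys, 10, tolerance = 1e-9)
  ## 3% discounting: the 10-term annuity
  tr3 <- run_cohort("scrt", p, lt0, reward_timing = "end")
  annuity <- sum(1.03^-(1:10))
  expect_equal(tr3$discounted_qalys, annuity, tolerance = 1e-9)
  ## boundary accrual adds the cycle-0 reward: 11 terms
  trb <- run_cohort("scrt", p0, lt0, reward_timing = "boundary")
  expect_equal(trb$discounted_qalys, 11, tolerance = 1e-9)
  trb3 <- run_cohort("scrt", p, lt0, reward_timing = "boundary")
  expect_equal(trb3$discounted_qalys, 1 + annuity, tolerance = 1e-9)
  ## half-cycle correction: half weight at each endpoint
  trh <- run_cohort("scrt", p0, lt0, reward_timing = "half")
  expect_equal(trh$discounted_qalys, 10, tolerance = 1e-9)
})

test_that("discounting is monotone and QALYs follow utilities", {
  lt <- base_lt
  p <- rc_parameters()
  q_by_disc <- sapply(c(0, 0.03, 0.06), function(r) {
    tr <- run_cohort("scrt", set_parameter(p, "discount_rate", r), lt)
    c(tr$discounted_qalys, tr$discounted_costs)
  })
  expect_true(all(diff(q_by_disc[1, ]) < 0))
  expect_true(all(diff(q_by_disc[2, ]) < 0))
  ## raising the NED-LAR utility never lowers a strategy's QALYs
  hi <- run_cohort("lcrt", set_parameter(p, "u_ned_lar", 0.64), lt)
  lo <- run_cohort("lcrt", set_parameter(p, "u_ned_lar", 0.54), lt)
  expect_gt(hi$discounted_qalys, lo$discounted_qalys)
})

test_that("QALY advantage has the sign of the utility-weighted surgery shift", {
  lt <- base_lt
  sign_pred <- function(p) {
    sign((p$u_ned_lar - p$u_ned_apr) * (p$p_lar_lcrt - p$p_lar_scrt))
  }
  dq <- function(p) {
    run_cohort("lcrt", p, lt)$discounted_qalys -
      run_cohort("scrt", p, lt)$discounted_qalys
  }
  p <- rc_parameters()
  expect_equal(sign(dq(p)), sign_pred(p))
  ## invert the utility ordering: the advantage flips
  q <- set_parameter(set_parameter(p, "u_ned_lar", 0.45), "u_ned_apr", 0.55)
  expect_equal(sign(dq(q)), sign_pred(q))
  expect_equal(sign(dq(q)), -sign(dq(p)))
})

test_that("strategy models carry the right entry mix and costs", {
  p <- rc_parameters()
  m <- strategy_model("scrt", p)
  expect_equal(sum(m$initial), 1)
  expect_equal(unname(m$initial["NED_LAR"]), 0.72)
  expect_equal(m$entry_cost,
               7223 + 0.72 * 35569 + 0.28 * 21569 +
                 p$n_adjuvant_chemo_cycles * 1890)
  ml <- strategy_model("lcrt", p)
  expect_equal(ml$radiation_cost, 19311)
  expect_equal(unname(ml$initial["NED_APR"]), 0.17)
})

test_that("trace validation recovers the input event probabilities", {
  p <- rc_parameters()
  ## with background mortality zeroed the marginal cumulative incidences
  ## equal the 10-y inputs to numerical precision
  tr0 <- run_cohort("scrt", p, zero_mortality())
  v0 <- validate_against_trial(tr0, tolerance = 1e-9)
  expect_true(all(v0$pass))
  expect_equal(v0$model, c(0.071, 0.30), tolerance = 1e-9)
  ## competing background mortality does not bias the marginal recovery
  tr <- run_cohort("scrt", p, base_lt)
  v <- validate_against_trial(tr, tolerance = 1e-6)
  expect_true(all(v$pass))
  ## crude (competing-risk) incidences are attenuated below the marginals
  expect_lt(attr(v, "crude_lr"), 0.071)
  expect_lt(attr(v, "crude_dr"), 0.30)
  expect_gt(attr(v, "overall_survival"), 0.4)
  ## zero-event cohort: zero incidences
  trz <- run_cohort("scrt", params_no_events(), zero_mortality())
  vz <- validate_against_trial(trz)
  expect_equal(vz$model, c(0, 0), tolerance = 1e-12)
})

test_that("trace exports a tidy per-cycle table", {
  d <- as.data.frame(run_cohort("scrt"))
  expect_equal(nrow(d), 11)
  expect_true(all(health_states() %in% names(d)))
  expect_equal(d$cycle, 0:10)
  expect_true(all(diff(d$cum_inc_lr) >= 0))
})
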