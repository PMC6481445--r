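test_that("per-cycle conversion compounds back to the multi-year probability", {
  for (p in c(0.071, 0.30, 0.5, 0.86, 0.99)) {
    for (hz in c(5, 10)) {
      pc <- prob_to_cycle(p, hz)
      expect_lt(abs((1 - (1 - pc)^hz) - p), 1e-12)
    }
  }
  expect_identical(prob_to_cycle(0, 10), 0)
  expect_identical(prob_to_cycle(1, 10), 1)
  ## closed forms
  expect_equal(prob_to_cycle(0.86, 5), 1 - 0.14^(1 / 5), tolerance = 1e-12)
  expect_equal(prob_to_cycle(0.071, 10), 1 - 0.929^(1 / 10), tolerance = 1e-12)
  ## probability objects carry their own horizon
  expect_equal(prob_to_cycle(probability(0.071, 10)),
               prob_to_cycle(0.071, 10))
  expect_error(prob_to_cycle(0.5, 10, cycle_length_years = -1), "positive")
})

test_that("matrices are row-stochastic across the sensitivity ranges", {
  lt <- base_lt
  for (seed in 1:25) {
    p <- random_parameter_set(seed)
    for (cyc in c(0L, 5L, 9L)) {
      for (strat in c("scrt", "lcrt")) {
        P <- transition_matrix(p, strat, cyc, lt)
        expect_true(all(P >= 0 & P <= 1))
        expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
      }
    }
  }
})

test_that("structure: absorbing death, salvage only via local recurrence", {
  P <- transition_matrix(rc_parameters(), "scrt", 0, base_lt)
  expect_equal(unname(P["DEAD", ]), c(0, 0, 0, 0, 0, 1))
  ## salvage occurs at the first transition to local recurrence only:
  ## no inflow from recurrence states or from the salvaged state itself
  expect_identical(P["LOCAL_RECURRENCE", "SALVAGED_LR"], 0)
  expect_identical(P["DISTANT_RECURRENCE", "SALVAGED_LR"], 0)
  expect_identical(P["SALVAGED_LR", "SALVAGED_LR"] > 0, TRUE)
  ## salvaged patients re-enter the recurrence pool without second salvage
  expect_gt(P["SALVAGED_LR", "LOCAL_RECURRENCE"],
            P["NED_LAR", "LOCAL_RECURRENCE"])
  ## no direct LR -> DR pathway
  expect_identical(P["LOCAL_RECURRENCE", "DISTANT_RECURRENCE"], 0)
})

test_that("zero hazards give the identity matrix", {
  p <- params_no_events()
  P <- transition_matrix(p, "scrt", 0, zero_mortality())
  expect_equal(unname(P), diag(6), tolerance = 1e-9)
})

test_that("hazard composition preserves cause-specific hazards exactly", {
  p <- rc_parameters()
  P <- transition_matrix(p, "scrt", 0, base_lt)
  exit <- 1 - P["NED_LAR", "NED_LAR"]
  H <- -log(1 - exit)
  p_lr_tot <- P["NED_LAR", "LOCAL_RECURRENCE"] + P["NED_LAR", "SALVAGED_LR"]
  h_lr <- p_lr_tot * H / exit
  expect_equal(h_lr, -log(1 - prob_to_cycle(0.071, 10)), tolerance = 1e-12)
  h_dr <- P["NED_LAR", "DISTANT_RECURRENCE"] * H / exit
  expect_equal(h_dr, -log(1 - prob_to_cycle(0.30, 10)), tolerance = 1e-12)
  ## without competing causes the NED exit equals the converted probability
  q <- set_parameter(p, "p_distant_recurrence_10y", 0)
  P0 <- transition_matrix(q, "scrt", 0, zero_mortality())
  expect_equal(P0["NED_LAR", "LOCAL_RECURRENCE"] +
                 P0["NED_LAR", "SALVAGED_LR"],
               prob_to_cycle(0.071, 10), tolerance = 1e-12)
})

test_that("the SCRT-specific recurrence override only affects SCRT", {
  p <- set_parameter(rc_parameters(), "p_local_recurrence_10y_scrt", 0.104)
  Ps <- transition_matrix(p, "scrt", 0, base_lt)
  Pl <- transition_matrix(p, "lcrt", 0, base_lt)
  expect_gt(Ps["NED_LAR", "LOCAL_RECURRENCE"],
            Pl["NED_LAR", "LOCAL_RECURRENCE"])
  base <- transition_matrix(rc_parameters(), "lcrt", 0, base_lt)
  expect_equal(Pl, base)
})
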