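test_that("bisection threshold matches the closed-form root for linear costs", {
  p <- rc_parameters()
  lt <- base_lt
  ## the LCRT radiation cost enters the incremental NMB linearly with
  ## slope -1, so the root is available in closed form from two evaluations
  f <- function(v) rectalcea:::incremental_nmb(
    set_parameter(p, "c_lcrt_3d", v), lt, 1e5)
  v1 <- 10000; v2 <- 25000
  y1 <- f(v1); y2 <- f(v2)
  root <- v1 - y1 * (v2 - v1) / (y2 - y1)
  tr <- one_way(p, "c_lcrt_3d", c(9655, 28997))
  expect_equal(tr$threshold, root, tolerance = 1e-3)
  ## invariant to the pre-scan granularity
  tr2 <- one_way(p, "c_lcrt_3d", c(9655, 28997), n_scan = 11)
  expect_equal(tr2$threshold, tr$threshold, tolerance = 1e-3)
})

test_that("one-way results flag flips and report 'none' when bounds agree", {
  p <- rc_parameters()
  flip <- one_way(p, "c_lcrt_3d", c(9655, 28997))
  expect_identical(flip$preferred_low, "lcrt")
  expect_identical(flip$preferred_high, "scrt")
  expect_false(is.na(flip$threshold))
  expect_gt(flip$threshold, 9655); expect_lt(flip$threshold, 28997)
  none <- one_way(p, "c_apr", c(10785, 32354))
  expect_identical(none$preferred_low, "scrt")
  expect_identical(none$preferred_high, "scrt")
  expect_true(is.na(none$threshold))
  expect_error(one_way(p, "c_apr", c(5, 1)), "low < high")
})

test_that("two-way utility grid reproduces the published example cells", {
  p <- rc_parameters()
  g <- two_way(p, "u_ned_apr", "u_ned_lar", c(0.45, 0.50), c(0.59, 0.60))
  ## a patient valuing the colostomy state at 0.45 and the LAR state at
  ## 0.60 is better served by LCRT; the base-case cell prefers SCRT
  expect_identical(g$decision["0.45", "0.6"], "lcrt")
  expect_identical(g$decision["0.5", "0.59"], "scrt")
  ## degenerate 1x1 grid at base values reproduces the base decision
  g1 <- two_way(p, "u_ned_apr", "u_ned_lar", 0.50, 0.59)
  base <- evaluate_strategies(p)$decision
  expect_identical(unname(g1$decision[1, 1]), base)
  ## every cell equals a fresh NMB evaluation
  p2 <- set_parameter(set_parameter(p, "u_ned_apr", 0.45), "u_ned_lar", 0.59)
  expect_identical(g$decision["0.45", "0.59"],
                   if (rectalcea:::incremental_nmb(p2, base_lt, 1e5) > 0)
                     "lcrt" else "scrt")
  expect_error(two_way(p, "u_ned_apr", "u_ned_lar", c(2, 1), c(1, 2)),
               "ascending")
})

test_that("degenerate PSA reproduces the deterministic decision", {
  p <- rc_parameters()
  spec0 <- psa_spec(p, spread_scale = 0)
  ps <- run_psa(p, n_samples = 500, seed = 1, spec = spec0)
  a <- ps$acceptability
  expect_equal(a$p_scrt[a$wtp == 1e5], 1)
  ## point-mass increments equal the deterministic increments
  r <- evaluate_strategies(p)
  expect_equal(ps$incremental$delta_cost[1], r$incremental_cost,
               tolerance = 1e-9)
  expect_equal(ps$incremental$delta_effect[1], r$incremental_effect,
               tolerance = 1e-9)
})

test_that("acceptability probabilities partition and PSA is seeded", {
  p <- rc_parameters()
  ps <- run_psa(p, n_samples = 2000, seed = 42)
  a <- ps$acceptability
  expect_equal(a$p_scrt + a$p_lcrt, rep(1, nrow(a)))
  expect_true(all(a$p_scrt >= 0 & a$p_scrt <= 1))
  ps2 <- run_psa(p, n_samples = 2000, seed = 42)
  expect_identical(ps$acceptability, ps2$acceptability)
  ## sampled probabilities/utilities stay in [0,1]; costs non-negative
  draws <- with(ps, incremental)
  expect_true(all(is.finite(draws$delta_cost)))
  set.seed(42)
  d <- rectalcea:::sample_psa(psa_spec(p), 1000)
  prob_cols <- grepl("^p_|^u_", colnames(d))
  expect_true(all(d[, prob_cols] >= 0 & d[, prob_cols] <= 1))
  expect_true(all(d[, !prob_cols] >= 0))
})

test_that("acceptability declines toward LCRT as WTP rises", {
  ps <- run_psa(rc_parameters(), n_samples = 5000, seed = 7,
                wtp_grid = c(0, 5e4, 1e5, 1.5e5, 2e5, 4e5))
  a <- ps$acceptability
  ## the cheaper strategy dominates at WTP 0 in nearly every sample, and
  ## the acceptability curve falls monotonically toward LCRT
  expect_gt(a$p_scrt[a$wtp == 0], 0.9)
  expect_true(all(diff(a$p_scrt) <= 0))
  expect_lt(a$p_scrt[a$wtp == 4e5], a$p_scrt[a$wtp == 0])
})
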