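test_that("base-case registry reproduces the published inputs", {
  p <- rc_parameters()
  expect_identical(p$p_apr_lcrt, 0.17)
  expect_identical(p$p_lar_lcrt, 0.83)
  expect_identical(p$p_apr_scrt, 0.28)
  expect_identical(p$p_lar_scrt, 0.72)
  expect_identical(p$p_local_recurrence_10y, 0.071)  # 10-y (text value, not the table typo)
  expect_identical(p$p_distant_recurrence_10y, 0.30)
  expect_identical(p$p_death_metastatic_5y, 0.86)
  expect_identical(p$u_ned_apr, 0.50)
  expect_identical(p$u_ned_lar, 0.59)
  expect_identical(p$u_local_recurrence, 0.40)
  expect_identical(p$u_distant_recurrence, 0.20)
  expect_identical(p$u_death, 0)
  expect_identical(p$c_apr, 21569)
  expect_identical(p$c_lar, 35569)
  expect_identical(p$c_capecitabine_cycle, 1890)
  expect_identical(p$c_colostomy_supplies, 3427)
  expect_identical(p$c_lcrt_3d, 19311)
  expect_identical(p$c_lcrt_imrt, 25502)
  expect_identical(p$c_scrt_3d, 7223)
  expect_identical(p$c_scrt_imrt, 7814)
  expect_identical(p$discount_rate, 0.03)
  expect_identical(p$wtp, 1e5)
  expect_identical(p$horizon_cycles, 10L)
  expect_identical(p$start_age, 65L)
  expect_identical(p$distal_lar_conversion_lcrt, 0.39)
  expect_identical(p$distal_lar_conversion_scrt, 0.19)
})

test_that("validation rejects out-of-range and inconsistent inputs", {
  p <- unclass(rc_parameters())
  bad <- p; bad$p_apr_lcrt <- 1.2
  expect_error(validate_parameters(bad), "\\[0, 1\\]")
  bad <- p; bad$p_apr_lcrt <- 0.2; bad$p_lar_lcrt <- 0.7
  expect_error(validate_parameters(bad), "sum to 1")
  bad <- p; bad$u_death <- 0.1
  expect_error(validate_parameters(bad), "death utility")
  bad <- p; bad$c_apr <- -1
  expect_error(validate_parameters(bad), "non-negative")
  bad <- p; bad$horizon_cycles <- 0L
  expect_error(validate_parameters(bad), "horizon")
  expect_error(probability(1.2), "\\[0, 1\\]")
})

test_that("YAML round trip is exact and the bundled file is the base case", {
  p <- rc_parameters()
  f <- tempfile(fileext = ".yaml")
  write_parameters(p, f)
  q <- load_parameters(f)
  expect_equal(unclass(q), unclass(p))
  bundled <- system.file("extdata", "params_table1.yaml",
                         package = "rectalcea")
  expect_equal(unclass(load_parameters(bundled)), unclass(p))
})

test_that("partial configs need use_defaults; unknown keys are rejected", {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(use_defaults = TRUE, c_scrt_3d = 8000), f)
  p <- load_parameters(f)
  expect_equal(p$c_scrt_3d, 8000)
  expect_equal(p$c_lcrt_3d, 19311)
  yaml::write_yaml(list(c_scrt_3d = 8000), f)
  expect_error(load_parameters(f), "missing key")
  yaml::write_yaml(list(use_defaults = TRUE, nonsense_key = 1), f)
  expect_error(load_parameters(f), "unknown parameter")
})

test_that("scenarios swap radiation pricing and distal surgery shares", {
  p <- rc_parameters()
  q <- apply_scenario(p, scenario_spec("imrt", radiation_scrt = "imrt"))
  expect_equal(strategy_model("scrt", q)$radiation_cost, 7814)
  expect_equal(strategy_model("lcrt", q)$radiation_cost, 19311)
  d <- apply_scenario(p, scenario_spec("distal", population = "distal"))
  expect_equal(d$p_lar_lcrt, 0.39)
  expect_equal(d$p_apr_lcrt, 0.61)
  expect_equal(d$p_lar_scrt, 0.19)
  expect_equal(d$p_apr_scrt, 0.81)
  ## identity scenario: no change, input untouched
  id <- apply_scenario(p, scenario_spec("base"))
  expect_equal(unclass(id), unclass(p))
  expect_equal(p$p_lar_lcrt, 0.83)  # apply_scenario never mutates its input
  expect_equal(unclass(apply_scenario(id, scenario_spec("base"))),
               unclass(id))  # idempotent
})

test_that("sensitivity ranges reproduce the published tested ranges", {
  r <- default_sensitivity_ranges(rc_parameters())
  g <- function(id) r[r$parameter_id == id, ]
  expect_equal(unlist(g("u_ned_lar")[c("low", "high")]),
               c(low = 0.54, high = 0.64))
  expect_equal(unlist(g("u_ned_apr")[c("low", "high")]),
               c(low = 0.44, high = 0.56))
  expect_equal(unlist(g("c_scrt_3d")[c("low", "high")]),
               c(low = 3611.5, high = 10834.5))
  expect_equal(unlist(g("c_apr")[c("low", "high")]),
               c(low = 10784.5, high = 32353.5))
  ## the half-to-1.5x rule, with probabilities capped at 1
  expect_equal(g("p_lar_lcrt")$low, 0.415)
  expect_equal(g("p_lar_lcrt")$high, 1)
  expect_equal(unlist(g("p_local_recurrence_10y_scrt")[c("low", "high")]),
               c(low = 0.0355, high = 0.1065))
  ## every base value lies inside its range
  expect_true(all(r$base >= r$low & r$base <= r$high))
})

test_that("set_parameter preserves complements and distal conversions", {
  p <- rc_parameters()
  q <- set_parameter(p, "p_apr_scrt", 0.42)
  expect_equal(q$p_lar_scrt, 0.58)
  d <- apply_scenario(p, scenario_spec("distal", population = "distal"))
  d2 <- set_parameter(d, "distal_lar_conversion_lcrt", 0.30)
  expect_equal(d2$p_lar_lcrt, 0.30)
  expect_equal(d2$p_apr_lcrt, 0.70)
  expect_error(set_parameter(p, "no_such_param", 1), "unknown parameter")
})

test_that("random parameter sets are valid, seeded, and in range", {
  a <- random_parameter_set(42)
  b <- random_parameter_set(42)
  expect_equal(unclass(a), unclass(b))
  c_ <- random_parameter_set(43)
  expect_false(identical(unclass(a), unclass(c_)))
  expect_s3_class(validate_parameters(a), "rc_params")
  expect_equal(a$p_apr_lcrt + a$p_lar_lcrt, 1)
})
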