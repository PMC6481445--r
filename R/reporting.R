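#' Published-style incremental cost-effectiveness table
#'
#' Evaluates one or more scenarios and assembles a summary mirroring the
#' published layout: per-strategy cost, incremental cost, effectiveness,
#' incremental effectiveness, ICER. Costs and the ICER are discounted;
#' the effectiveness column is the per-strategy undiscounted QALY tracker
#' while incremental effectiveness is discounted (the convention of the
#' replicated analysis — see the vignette); `effect_discounted` carries
#' the discounted per-strategy totals at full precision.
#'
#' @param params an `rc_params` object.
#' @param scenarios list of [scenario_spec()]s (default: the published
#'   scenario set).
#' @param life_table a [make_life_table()] object.
#' @param wtp willingness to pay.
#' @return Data frame, two rows (SCRT then LCRT) per scenario.
#' @examples
#' cea_table(rc_parameters(), published_scenarios()["base"])
#' @export
cea_table <- function(params = rc_parameters(),
                      scenarios = published_scenarios(),
                      life_table = default_life_table(), wtp = NULL) {
  rows <- lapply(names(scenarios), function(nm) {
    r <- evaluate_strategies(params, scenarios[[nm]], life_table, wtp)
    s <- r$strategies
    data.frame(
      scenario = nm,
      strategy = s$strategy,
      cost = s$cost,
      incremental_cost = c(0, r$incremental_cost),
      effect = s$effect_undiscounted,
      effect_discounted = s$effect,
      incremental_effect = c(0, r$incremental_effect),
      icer = c(NA_real_, r$icer),
      decision = r$decision,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Colostomy-prevention metrics
#'
#' Computes the cost per permanent colostomy prevented and the number
#' needed to treat with LCRT to prevent one permanent colostomy, on two
#' event bases reported side by side: the surgery-mix basis (colostomy
#' proportion = APR share at entry) and the microsimulation end-of-horizon
#' basis (ever-colostomy flag, which additionally counts colostomies
#' created by APR-type salvage among LAR patients).
#'
#' @param params an `rc_params` object.
#' @param life_table a [make_life_table()] object.
#' @param n_patients microsimulation size.
#' @param seed microsimulation seed.
#' @return A list with `surgery_mix` and `microsim` components, each a
#'   list with `prop_scrt`, `prop_lcrt`, `cost_per_colostomy_prevented`,
#'   `nnt`; plus `delta_cost` (discounted LCRT - SCRT cost).
#' @export
colostomy_metrics <- function(params = rc_parameters(),
                              life_table = default_life_table(),
                              n_patients = 100000L, seed = 1L) {
  r <- evaluate_strategies(params, life_table = life_table)
  dc <- r$incremental_cost
  ## surgery-mix basis: entry APR shares
  p_s <- 1 - strategy_lar_share(params, "scrt")
  p_l <- 1 - strategy_lar_share(params, "lcrt")
  mix <- list(prop_scrt = p_s, prop_lcrt = p_l,
              cost_per_colostomy_prevented =
                cost_per_event_prevented(r$strategies$cost[2],
                                         r$strategies$cost[1], p_l, p_s),
              nnt = number_needed_to_treat(p_s, p_l))
  ## microsimulation end-of-horizon basis: ever-colostomy flags
  ms_s <- run_microsim("scrt", params, life_table, n_patients, seed)
  ms_l <- run_microsim("lcrt", params, life_table, n_patients, seed + 1L)
  q_s <- colostomy_proportion(ms_s)
  q_l <- colostomy_proportion(ms_l)
  ms <- list(prop_scrt = q_s, prop_lcrt = q_l,
             cost_per_colostomy_prevented =
               cost_per_event_prevented(ms_l$mean_cost, ms_s$mean_cost,
                                        q_l, q_s),
             nnt = number_needed_to_treat(q_s, q_l))
  list(surgery_mix = mix, microsim = ms, delta_cost = dc,
       n_patients = n_patients, seed = seed)
}

#' Run a configured analysis
#'
#' Single entry point used by the bundled command-line script: executes
#' one of the package's analyses from a configuration list and returns
#' its results together with a manifest (resolved configuration, seed,
#' package version).
#'
#' @param analysis one of `"evaluate"`, `"one_way"`, `"two_way"`, `"psa"`,
#'   `"colostomy"`, `"validate"`, `"calibrate"`.
#' @param params_file optional YAML parameter file ([load_parameters()]).
#' @param scenario scenario name among [published_scenarios()].
#' @param wtp willingness to pay (default: parameter set's).
#' @param seed integer seed for stochastic analyses.
#' @param n number of samples/patients for PSA or microsimulation.
#' @param parameter_id,parameter_id_b parameters for one-/two-way analyses.
#' @param life_table_file optional life-table file ([read_life_table()]).
#' @return List with elements `manifest` and `result`.
#' @export
run_analysis <- function(analysis = c("evaluate", "one_way", "two_way",
                                      "psa", "colostomy", "validate",
                                      "calibrate"),
                         params_file = NULL, scenario = "base", wtp = NULL,
                         seed = 1L, n = 10000L,
                         parameter_id = "u_ned_apr",
                         parameter_id_b = "u_ned_lar",
                         life_table_file = NULL) {
  analysis <- match.arg(analysis)
  params <- load_parameters(params_file)
  scen <- published_scenarios()
  if (!scenario %in% names(scen))
    stop("unknown scenario '", scenario, "'; available: ",
         paste(names(scen), collapse = ", "))
  params <- apply_scenario(params, scen[[scenario]])
  lt <- if (is.null(life_table_file)) default_life_table()
        else read_life_table(life_table_file)
  result <- switch(analysis,
    evaluate = cea_table(params, scen[scenario], lt, wtp),
    one_way = tornado_table(params, wtp, lt),
    two_way = {
      rngs <- default_sensitivity_ranges(params)
      ga <- rngs[rngs$parameter_id == parameter_id, ]
      gb <- rngs[rngs$parameter_id == parameter_id_b, ]
      two_way(params, parameter_id, parameter_id_b,
              seq(ga$low, ga$high, length.out = 21),
              seq(gb$low, gb$high, length.out = 21), wtp, lt)
    },
    psa = run_psa(params, n_samples = n, seed = seed, life_table = lt),
    colostomy = colostomy_metrics(params, lt, n_patients = n, seed = seed),
    validate = validate_against_trial(run_cohort("scrt", params, lt)),
    calibrate = calibrate_free_parameters(params, life_table = lt)
  )
  manifest <- list(
    analysis = analysis, scenario = scenario, seed = seed, n = n,
    wtp = wtp %||% params$wtp,
    params_file = params_file %||% "(defaults)",
    package_version = as.character(utils::packageVersion("rectalcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  list(manifest = manifest, result = result)
}
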