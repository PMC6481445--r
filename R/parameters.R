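#' @title Model parameter registry
#' @description Constructors, validators and file I/O for the full set of
#'   probabilities, utilities, costs and analysis constants used by the
#'   SCRT-vs-LCRT decision model.
#' @name parameters
NULL

## horizons (years) over which the multi-year probabilities are defined
.prob_horizons <- c(
  p_local_recurrence_10y      = 10,
  p_local_recurrence_10y_scrt = 10,
  p_distant_recurrence_10y    = 10,
  p_death_metastatic_5y       = 5
)

.param_groups <- list(
  probability = c("p_local_recurrence_10y", "p_local_recurrence_10y_scrt",
                  "p_distant_recurrence_10y", "p_death_metastatic_5y",
                  "p_apr_lcrt", "p_lar_lcrt", "p_apr_scrt", "p_lar_scrt",
                  "p_salvage_lr",
                  "distal_lar_conversion_lcrt", "distal_lar_conversion_scrt"),
  utility     = c("u_ned_apr", "u_ned_lar", "u_local_recurrence",
                  "u_salvaged_lr", "u_distant_recurrence", "u_death"),
  cost        = c("c_apr", "c_lar", "c_capecitabine_cycle",
                  "c_colostomy_supplies", "c_lcrt_3d", "c_lcrt_imrt",
                  "c_scrt_3d", "c_scrt_imrt", "c_salvage"),
  analysis    = c("discount_rate", "wtp", "horizon_cycles",
                  "cycle_length_years", "start_age",
                  "n_adjuvant_chemo_cycles"),
  setting     = c("radiation_scrt", "radiation_lcrt", "population")
)

#' A probability defined over a multi-year horizon
#'
#' Light container pairing a cumulative probability with the number of years
#' over which it applies (e.g. a 10-year local recurrence risk).
#'
#' @param value probability in `[0, 1]`.
#' @param horizon_years positive integer horizon, in years.
#' @return An object of class `"probability"`.
#' @examples
#' probability(0.071, 10)
#' @export
probability <- function(value, horizon_years = 1L) {
  stopifnot(is.numeric(value), length(value) == 1L)
  if (is.na(value) || value < 0 || value > 1)
    stop("probability value must lie in [0, 1], got ", value)
  if (horizon_years < 1) stop("horizon_years must be >= 1")
  structure(list(value = value, horizon_years = as.integer(horizon_years)),
            class = "probability")
}

#' @export
print.probability <- function(x, ...) {
  cat(sprintf("%g (%d-y probability)\n", x$value, x$horizon_years))
  invisible(x)
}

#' Default model parameters
#'
#' Returns the complete parameter registry at its base-case values: the
#' published probabilities, utilities and costs of the SCRT-vs-LCRT model
#' (2018 US dollars), the analysis constants (3% annual discounting, $100,000
#' per QALY willingness to pay, 10 one-year cycles from age 65), and the four
#' free parameters of the salvage/adjuvant pathway at their calibrated
#' defaults (see the package vignette for the calibration).
#'
#' @return An object of class `"rc_params"`: a named list of scalar values.
#' @examples
#' p <- rc_parameters()
#' p$c_scrt_3d     # 7223
#' p$p_apr_lcrt    # 0.17
#' @seealso [load_parameters()], [apply_scenario()], [set_parameter()]
#' @export
rc_parameters <- function() {
  p <- list(
    ## probabilities
    p_local_recurrence_10y      = 0.071,  # 10-y, shared by both strategies
    p_local_recurrence_10y_scrt = NA_real_,  # optional SCRT-specific override
    p_distant_recurrence_10y    = 0.30,   # 10-y
    p_death_metastatic_5y       = 0.86,   # 5-y
    p_apr_lcrt = 0.17, p_lar_lcrt = 0.83,
    p_apr_scrt = 0.28, p_lar_scrt = 0.72,
    p_salvage_lr = 0.25,                  # free parameter (calibrated)
    ## utilities
    u_ned_apr = 0.50, u_ned_lar = 0.59,
    u_local_recurrence = 0.40,
    u_salvaged_lr = 0.40,                 # free parameter (calibrated)
    u_distant_recurrence = 0.20,
    u_death = 0,
    ## costs, 2018 USD
    c_apr = 21569, c_lar = 35569,         # LAR includes ileostomy reversal
    c_capecitabine_cycle = 1890,          # per 28-day supply
    c_colostomy_supplies = 3427,          # per year
    c_lcrt_3d = 19311, c_lcrt_imrt = 25502,  # include concurrent capecitabine
    c_scrt_3d = 7223,  c_scrt_imrt = 7814,
    c_salvage = 21569,                    # free parameter (calibrated)
    ## analysis constants
    discount_rate = 0.03,
    wtp = 100000,
    horizon_cycles = 10L,
    cycle_length_years = 1,
    start_age = 65L,
    n_adjuvant_chemo_cycles = 0,          # free parameter (calibrated)
    ## distal-tumor downstaging: fraction achieving LAR when APR was
    ## initially deemed necessary
    distal_lar_conversion_lcrt = 0.39,
    distal_lar_conversion_scrt = 0.19,
    ## scenario settings
    radiation_scrt = "3d",
    radiation_lcrt = "3d",
    population = "all"
  )
  class(p) <- "rc_params"
  validate_parameters(p)
}

#' Validate a parameter set
#'
#' Checks ranges (probabilities and utilities in `[0, 1]`, non-negative
#' costs and discount rate), structural constraints (APR + LAR shares sum
#' to one for each strategy, death utility exactly zero, horizon of at
#' least one cycle) and setting levels.
#'
#' @param p an `rc_params` object (or plain named list with the same fields).
#' @return `p`, invisibly classed `"rc_params"`, or an error.
#' @export
validate_parameters <- function(p) {
  required <- unlist(.param_groups, use.names = FALSE)
  missing <- setdiff(required, names(p))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  for (id in .param_groups$probability) {
    v <- p[[id]]
    if (id == "p_local_recurrence_10y_scrt" && is.na(v)) next
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1)
      stop("parameter '", id, "' must be a probability in [0, 1], got ", v)
  }
  for (id in .param_groups$utility) {
    v <- p[[id]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1)
      stop("utility '", id, "' must lie in [0, 1], got ", v)
  }
  if (p$u_death != 0) stop("death utility must be exactly 0")
  for (id in .param_groups$cost) {
    v <- p[[id]]
    if (!is.numeric(v) || is.na(v) || v < 0)
      stop("cost '", id, "' must be non-negative, got ", v)
  }
  if (abs(p$p_apr_lcrt + p$p_lar_lcrt - 1) > 1e-8)
    stop("p_apr_lcrt + p_lar_lcrt must sum to 1 (got ",
         p$p_apr_lcrt + p$p_lar_lcrt, ")")
  if (abs(p$p_apr_scrt + p$p_lar_scrt - 1) > 1e-8)
    stop("p_apr_scrt + p_lar_scrt must sum to 1 (got ",
         p$p_apr_scrt + p$p_lar_scrt, ")")
  if (p$discount_rate < 0) stop("discount_rate must be >= 0")
  if (p$horizon_cycles < 1) stop("horizon_cycles must be >= 1")
  if (p$cycle_length_years <= 0) stop("cycle_length_years must be positive")
  if (!p$radiation_scrt %in% c("3d", "imrt"))
    stop("radiation_scrt must be '3d' or 'imrt'")
  if (!p$radiation_lcrt %in% c("3d", "imrt"))
    stop("radiation_lcrt must be '3d' or 'imrt'")
  if (!p$population %in% c("all", "distal"))
    stop("population must be 'all' or 'distal'")
  class(p) <- "rc_params"
  invisible(p)
}

#' @export
print.rc_params <- function(x, ...) {
  cat("<rc_params> SCRT-vs-LCRT model parameters\n")
  cat(sprintf("  scenario: SCRT %s / LCRT %s, population = %s\n",
              toupper(x$radiation_scrt), toupper(x$radiation_lcrt),
              x$population))
  cat(sprintf("  surgery mix: LCRT %.0f%% LAR, SCRT %.0f%% LAR\n",
              100 * x$p_lar_lcrt, 100 * x$p_lar_scrt))
  cat(sprintf("  horizon %d x %g y from age %d, discount %.1f%%, WTP $%s/QALY\n",
              x$horizon_cycles, x$cycle_length_years, x$start_age,
              100 * x$discount_rate, format(x$wtp, big.mark = ",")))
  invisible(x)
}

#' Load model parameters from a YAML file
#'
#' The file's keys mirror the field names of [rc_parameters()]. If the file
#' sets `use_defaults: true`, any omitted key falls back to the base-case
#' value; otherwise every parameter must be present. The result is fully
#' validated.
#'
#' @param path path to a YAML parameter file, or `NULL` for the base case.
#' @return A validated `rc_params` object.
#' @examples
#' cfg <- system.file("extdata", "params_table1.yaml", package = "rectalcea")
#' p <- load_parameters(cfg)
#' @export
load_parameters <- function(path = NULL) {
  if (is.null(path)) return(rc_parameters())
  raw <- yaml::read_yaml(path)
  use_defaults <- isTRUE(raw$use_defaults)
  raw$use_defaults <- NULL
  known <- unlist(.param_groups, use.names = FALSE)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  if (!use_defaults) {
    missing <- setdiff(known, names(raw))
    if (length(missing))
      stop("missing key(s) without defaults requested: ",
           paste(missing, collapse = ", "))
  }
  p <- unclass(rc_parameters())   # canonical field order
  p[names(raw)] <- raw
  # YAML reads NA/na as logical or string; normalise the optional override
  if (is.null(p$p_local_recurrence_10y_scrt) ||
      !is.numeric(p$p_local_recurrence_10y_scrt) ||
      is.na(p$p_local_recurrence_10y_scrt))
    p$p_local_recurrence_10y_scrt <- NA_real_
  p$horizon_cycles <- as.integer(p$horizon_cycles)
  p$start_age <- as.integer(p$start_age)
  class(p) <- "rc_params"
  validate_parameters(p)
}

#' Write model parameters to a YAML file
#'
#' Inverse of [load_parameters()]: `load_parameters(write_parameters(p, f))`
#' reproduces `p` exactly.
#'
#' @param p an `rc_params` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  validate_parameters(p)
  yaml::write_yaml(unclass(p), path)
  invisible(path)
}

#' Scenario specification
#'
#' A scenario names the radiation delivery technique priced for each
#' strategy (3-D conformal or IMRT) and the modelled population. For the
#' distal-tumor population, every patient initially requires APR and the
#' LAR shares are replaced by the downstaging conversion fractions.
#'
#' @param name scenario identifier.
#' @param radiation_scrt,radiation_lcrt `"3d"` or `"imrt"`.
#' @param population `"all"` or `"distal"`.
#' @return An object of class `"scenario_spec"`.
#' @examples
#' scenario_spec("scrt_imrt", radiation_scrt = "imrt")
#' @export
scenario_spec <- function(name = "base", radiation_scrt = "3d",
                          radiation_lcrt = "3d", population = "all") {
  radiation_scrt <- match.arg(radiation_scrt, c("3d", "imrt"))
  radiation_lcrt <- match.arg(radiation_lcrt, c("3d", "imrt"))
  population <- match.arg(population, c("all", "distal"))
  structure(list(name = name, radiation_scrt = radiation_scrt,
                 radiation_lcrt = radiation_lcrt, population = population),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s: SCRT %s, LCRT %s, population %s\n",
              x$name, toupper(x$radiation_scrt), toupper(x$radiation_lcrt),
              x$population))
  invisible(x)
}

#' Apply a scenario to a parameter set
#'
#' Returns a new parameter set with the radiation modality settings of the
#' scenario and, for the distal-tumor population, the LAR share after each
#' strategy replaced by its downstaging conversion fraction (APR shares the
#' complements). The input is never modified; applying the base scenario is
#' the identity.
#'
#' @param params an `rc_params` object.
#' @param scenario a [scenario_spec()].
#' @return A new validated `rc_params` object.
#' @examples
#' p <- apply_scenario(rc_parameters(), scenario_spec("distal", population = "distal"))
#' p$p_lar_lcrt  # 0.39
#' p$p_apr_scrt  # 0.81
#' @export
apply_scenario <- function(params, scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  p <- unclass(params)
  p$radiation_scrt <- scenario$radiation_scrt
  p$radiation_lcrt <- scenario$radiation_lcrt
  p$population <- scenario$population
  if (scenario$population == "distal") {
    p$p_lar_lcrt <- p$distal_lar_conversion_lcrt
    p$p_apr_lcrt <- 1 - p$distal_lar_conversion_lcrt
    p$p_lar_scrt <- p$distal_lar_conversion_scrt
    p$p_apr_scrt <- 1 - p$distal_lar_conversion_scrt
  }
  class(p) <- "rc_params"
  validate_parameters(p)
  p
}

#' Named scenarios of the published analysis
#'
#' @return A named list of [scenario_spec()] objects: `base` (3-D conformal
#'   for both strategies, all patients), `scrt_imrt` (IMRT pricing for SCRT,
#'   3-D conformal for LCRT), `distal` and `distal_scrt_imrt`.
#' @export
published_scenarios <- function() {
  list(
    base       = scenario_spec("base"),
    scrt_imrt  = scenario_spec("scrt_imrt", radiation_scrt = "imrt"),
    distal     = scenario_spec("distal", population = "distal"),
    distal_scrt_imrt = scenario_spec("distal_scrt_imrt",
                                     radiation_scrt = "imrt",
                                     population = "distal")
  )
}

#' Set a single parameter, preserving structural constraints
#'
#' Setting a surgery-mix share adjusts its complement so the shares still
#' sum to one; `p_local_recurrence_10y_scrt` sets the SCRT-specific local
#' recurrence override. All other identifiers are set directly. The result
#' is re-validated.
#'
#' @param params an `rc_params` object.
#' @param id parameter identifier (a field name of [rc_parameters()]).
#' @param value new numeric value.
#' @return A new validated `rc_params` object.
#' @export
set_parameter <- function(params, id, value) {
  p <- unclass(params)
  if (!id %in% names(p)) stop("unknown parameter id: ", id)
  p[[id]] <- value
  complement <- c(p_apr_lcrt = "p_lar_lcrt", p_lar_lcrt = "p_apr_lcrt",
                  p_apr_scrt = "p_lar_scrt", p_lar_scrt = "p_apr_scrt")
  if (id %in% names(complement)) p[[complement[[id]]]] <- 1 - value
  ## in the distal population the LAR shares ARE the conversion fractions
  if (p$population == "distal" && startsWith(id, "distal_lar_conversion_")) {
    strat <- sub("distal_lar_conversion_", "", id)
    p[[paste0("p_lar_", strat)]] <- value
    p[[paste0("p_apr_", strat)]] <- 1 - value
  }
  class(p) <- "rc_params"
  validate_parameters(p)
  p
}

#' Tested ranges for sensitivity analysis
#'
#' Returns, for every parameter varied in sensitivity analysis, its base
#' value and tested range. The two NED utilities carry literature-derived
#' ranges (plus/minus 0.06 and 0.05); every other parameter is varied over
#' 0.5 to 1.5 times its base value, with probabilities capped at 1.
#'
#' @param params an `rc_params` object.
#' @return A data frame with columns `parameter_id`, `base`, `low`, `high`,
#'   `source` (`"literature"` or `"half_to_1.5x"`).
#' @examples
#' r <- default_sensitivity_ranges(rc_parameters())
#' subset(r, parameter_id == "u_ned_lar")  # 0.54 - 0.64
#' @export
default_sensitivity_ranges <- function(params = rc_parameters()) {
  p <- params
  lit <- data.frame(
    parameter_id = c("u_ned_apr", "u_ned_lar"),
    base = c(p$u_ned_apr, p$u_ned_lar),
    low  = c(p$u_ned_apr - 0.06, p$u_ned_lar - 0.05),
    high = c(p$u_ned_apr + 0.06, p$u_ned_lar + 0.05),
    source = "literature",
    stringsAsFactors = FALSE
  )
  half_ids <- c("p_apr_lcrt", "p_lar_lcrt", "p_apr_scrt", "p_lar_scrt",
                "p_local_recurrence_10y_scrt",
                "p_distant_recurrence_10y", "p_death_metastatic_5y",
                "c_apr", "c_colostomy_supplies", "c_lar",
                "c_lcrt_3d", "c_lcrt_imrt", "c_scrt_3d", "c_scrt_imrt")
  base <- vapply(half_ids, function(id) {
    if (id == "p_local_recurrence_10y_scrt" && is.na(p[[id]]))
      p$p_local_recurrence_10y else p[[id]]
  }, numeric(1))
  is_prob <- grepl("^p_", half_ids)
  rule <- data.frame(
    parameter_id = half_ids,
    base = base,
    low  = 0.5 * base,
    high = ifelse(is_prob, pmin(1, 1.5 * base), 1.5 * base),
    source = "half_to_1.5x",
    stringsAsFactors = FALSE
  )
  out <- rbind(lit, rule)
  rownames(out) <- NULL
  stopifnot(all(out$low < out$high),
            all(out$base >= out$low & out$base <= out$high))
  out
}
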