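---
title: "Model structure, conventions and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, conventions and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rectalcea)
```

## The clinical question

Locally advanced rectal cancer is treated with neoadjuvant radiation
followed by total mesorectal excision. Two regimens are in wide use:
**short-course radiotherapy** (SCRT, 25 Gy in 5 fractions with surgery
about a week later) and **long-course chemoradiotherapy** (LCRT, 50.4 Gy in
28 fractions with concurrent capecitabine and delayed surgery).
Randomized comparisons show equivalent recurrence and survival, but LCRT
downstages more tumors, so more patients receive a sphincter-preserving
**low anterior resection** (LAR) rather than an **abdominoperineal
resection** (APR) with its permanent colostomy. LCRT is also several times
more expensive to deliver. The package quantifies that trade-off: is the
extra cost of LCRT justified by the quality-of-life gain from avoiding
permanent colostomies?

## Model structure

`rectalcea` implements a discrete-time Markov model with six health
states — NED-LAR and NED-APR (no evidence of disease, distinguished by
surgery type because utilities and ongoing costs differ), local
recurrence, salvaged local recurrence, distant recurrence, and death —
over ten one-year cycles for a cohort entering at age 65. Per-cycle
transition probabilities come from multi-year probabilities converted
under a constant-hazard assumption (`prob_to_cycle()`): a 10-year local
recurrence probability of 0.071 and distant recurrence probability of
0.30 (identical for both strategies in the base case), a 5-year death
probability of 0.86 once metastatic, and age-specific background
mortality from a period life table. At the *first* transition to local
recurrence a fraction `p_salvage_lr` of patients is salvaged surgically
(resolved within the same cycle); salvaged patients re-enter the
recurrence risk pool but are not eligible for a second salvage.
Unsalvaged local recurrences face the same cancer mortality as distant
recurrences — the model provides no separate local-recurrence death rate,
and no direct local-to-distant transition, because neither quantity is
identifiable from the inputs.

Competing risks within a cycle are composed on the hazard scale: each
per-cycle probability is converted to a hazard, hazards are summed, and
cause-specific exit probabilities are apportioned proportionally to
hazards. This guarantees row-stochastic transition matrices for *every*
parameter combination inside the sensitivity ranges (naive addition of
probabilities can exceed one at range extremes), and it makes the
marginal event probabilities exactly recoverable from a trace —
`validate_against_trial()` inverts the apportionment and reproduces the
10-year inputs to numerical precision regardless of background mortality.

The two strategies differ only in (i) radiation cost (3-D conformal:
\$7,223 vs \$19,311 including concurrent capecitabine; IMRT variants
\$7,814 / \$25,502), and (ii) the LAR/APR mix: 72%/28% after SCRT vs
83%/17% after LCRT. In the distal-tumor scenario every patient initially
requires APR and the LAR shares become the downstaging conversion
fractions (19% after SCRT, 39% after LCRT). All event dynamics are
shared.

## Reward conventions

The published totals this package replicates were produced by a
commercial Markov-modelling tool, and several accrual conventions are
not stated in words. They are, however, strongly identified by the
internal structure of the published numbers, and the package's defaults
follow that identification; each is configurable.

**Reward timing.** QALYs and per-cycle costs accrue at *every cycle
boundary* (`reward_timing = "boundary"`): occupancy at times 0..10, each
weighted by $(1+r)^{-t}$. This is the initial-plus-incremental-plus-final
accrual of common Markov software. With an event-free cohort, utility 1
and no discounting this yields 11 QALYs; the conventional end-of-cycle
accrual (`"end"`, yielding exactly 10, or the 10-term annuity 8.5302 at
3%) and a half-cycle correction (`"half"`) are available behind the same
flag.

**Colostomy supplies.** Annual colostomy supply costs (\$3,427) are
charged as a *discounted remaining-horizon annuity per colostomy
creation* (APR at entry, or APR-type salvage), independent of
subsequent survival. This is the only convention consistent with all
four published scenario cost totals simultaneously (the implied
accumulation factor is $\sum_{t=0}^{10} 1.03^{-t} = 9.5302$ in both the
base and the distal scenario); per-cycle accrual in the colostomy-bearing
NED and salvaged states is available via
`colostomy_cost_mode = "occupancy"`. The annuity convention slightly
overstates supply costs for patients who die early — a documented
limitation inherited from the replicated analysis.

**Discounting and the two effectiveness totals.** Costs and all decision
metrics (ICER, net monetary benefit, thresholds, acceptability) use
QALYs discounted at 3% per year. The trace additionally carries an
*undiscounted* QALY total, and the published-style summary table
(`cea_table()`) prints it as the per-strategy effectiveness column. The
reason is an inconsistency in the totals being replicated: the published
incremental effectiveness and every ICER are exactly consistent with
discounted increments (e.g. \$10,033 / 0.0752 discounted QALYs =
\$133,495/QALY), while the published *per-strategy* QALY levels
(4.72/4.79 base, 4.36/4.49 distal) exceed what any 3%-discounted accrual
can produce — with 10-year overall survival matching the source trial
(about 57–60%), discounted quality-adjusted accrual is bounded near 4.5
even at the NED-LAR utility ceiling of 0.59. The levels are instead
consistent with undiscounted accrual, i.e. they behave like
individual-level tracker sums to which discounting was not applied. The
package therefore computes both and reports them side by side rather than
forcing one number to play both roles; incremental comparisons always use
the discounted totals, keeping the NMB-argmax decision rule internally
coherent.

**Entry costs.** Radiation, the expected surgery cost
(LAR \$35,569 including ileostomy reversal, charged once at entry; APR
\$21,569) and any separately-charged adjuvant capecitabine are incurred
undiscounted at cycle 0.

## Free parameters and calibration

Four quantities the model needs are not published: the salvage
probability at first local recurrence, the salvage surgery cost, the
utility of the salvaged state, and the number of separately-charged
adjuvant capecitabine cycles. `calibrate_free_parameters()` tunes any
subset of them (optionally together with the Gompertz life-table level
and slope) by minimising the squared relative error between the model's
(cost, QALY) pairs and the four published per-strategy totals, under
bounded L-BFGS-B. The package defaults are the frozen output of that
calibration under a-priori clinical bounds:

| parameter | default | bound rationale |
|---|---|---|
| `p_salvage_lr` | 0.25 | salvage attempted/successful in 25–75% of first local recurrences |
| `u_salvaged_lr` | 0.40 | between the local-recurrence utility (0.40) and the NED-APR utility (0.50); salvage is modelled as APR-type |
| `c_salvage` | \$21,569 | equal to the APR cost (the objective is nearly flat in this parameter) |
| `n_adjuvant_chemo_cycles` | 0 | the published totals are only consistent with capecitabine charged inside the LCRT radiation bundle; each additional 28-day cycle (\$1,890 per strategy) moves every scenario cost away from its published value |
| life table `q_ref`, `growth` | 0.016, 0.11 | annual death probability at 65 bounded a priori by the female-to-male period-table envelope (1.02%–1.60%); calibration selects the male end, consistent with a predominantly male rectal-cancer cohort |

With these values the four published cost totals are matched to within
0.02%, the effectiveness columns to within 0.4–1.2%, and the ICERs to
within about 6% — the residual ICER gap is the direct arithmetic
consequence of the discounting inconsistency described above and cannot
be removed without breaking the per-strategy totals (the two are coupled
through background mortality).

```{r calibration-fit}
evaluate_strategies(rc_parameters())
```

## Sensitivity analysis

**One-way.** `one_way()` varies a parameter across its tested range
(literature ranges for the two NED utilities; 0.5–1.5 times base
otherwise, probabilities capped at 1 — `default_sensitivity_ranges()`),
records the cost-effective strategy at each bound, and locates decision
thresholds as roots of the incremental net monetary benefit. A 32-point
pre-scan guards against multiple sign changes (all roots are reported);
roots are refined to a relative tolerance of 1e-4. Varying a surgery-mix
share moves its complement automatically, matching how the published
ranges were constructed.

**Two-way.** `two_way()` evaluates the full factorial grid of two
parameters and labels each cell with the NMB-argmax strategy — used for
the preference-sensitive utility analysis (NED-APR x NED-LAR) and for
the cost grids. The published two-way radiation-cost analysis is
reproduced by varying the strategy-level radiation costs (`c_scrt_3d`,
`c_lcrt_3d`); per-component variation is possible by editing the
parameter set directly.

**Probabilistic.** `run_psa()` samples the key parameters — the two
surgery-mix shares, the SCRT-specific local recurrence probability, the
two NED utilities, and the five cost inputs — from beta distributions
(probabilities/utilities) or zero-truncated normal distributions
(costs), each matching the base value as mean with SD equal to a quarter
of the tested range (range = mean ± 2 SD). The distribution *spreads*
are a package convention: the replicated analysis names the families but
not the spreads, which is why the published acceptability fraction
(63.5% at \$100,000/QALY) is treated as a soft target; under this
convention the model yields about 65%. Sampling and evaluation are fully
vectorised through the cohort engine, so 100,000 samples run in a few
seconds, and results are reproducible from the seed.

## Microsimulation

`run_microsim()` realises the same transition process patient by
patient, which is what makes event-history quantities well-defined: the
ever-colostomy flag (APR at entry or APR-type salvage, never unset),
salvage counts, and cause-of-death tags. Draws are made cohort-wide in a
fixed order from a single seed, so results are bit-reproducible and
independent of any scheduling. Means converge to the cohort engine (the
test suite asserts agreement within 3 Monte-Carlo standard errors at
n = 100,000, and state-frequency agreement within $4/\sqrt{n}$).

One replication caveat: with identical recurrence dynamics in both arms,
every colostomy-generating mechanism scales with the LAR/APR mix, so the
difference in ever-colostomy proportions is
$0.11 \times (1 - p_{salv}\cdot\mathrm{cumLR}) \le 0.11$ and the number
needed to treat is bounded below by $1/0.11 = 9.09$; the model reports
about 9.3 at the calibrated salvage rate. A published NNT of 8.23 would
require a colostomy-proportion difference of 0.122, which no mechanism
consistent with equal recurrence rates can produce; the companion
cost-per-colostomy-prevented figure *is* consistent with the surgery-mix
basis (difference 0.11), and both bases are therefore reported side by
side by `colostomy_metrics()`.

## Synthetic inputs

The only input not printed in the replicated analysis is background
mortality. `make_life_table()` generates a Gompertz period table
$q(a) = q_{ref}\,e^{growth\,(a-65)}$; the bundled, frozen copy
(`inst/extdata/life_table_synthetic_gompertz.tsv`) spans ages 60–90 with
$q(65) = 1.6\%$ doubling roughly every 6–7 years — the shape and level of
US period mortality for an older, predominantly male cohort. It is a
synthetic stand-in: swapping in an official actuarial table is a one-file
substitution, and `random_parameter_set()` plus the property tests do not
depend on its exact values. What the synthetic table cannot emulate is
cohort-specific mortality (comorbidity selection, secular improvement),
so passing tests demonstrate internal consistency of the engine, not
calibration of absolute survival to any external population.

## Numerical choices and limitations

* Transition-matrix rows are asserted row-stochastic to 1e-12 at build
  time; cohort occupancy is conserved to 1e-10 over the horizon.
* Threshold search assumes at most one sign change per scanned interval;
  the pre-scan reports multiple roots if they occur (none do within the
  published ranges).
* Beta moment-matching fails only if a requested SD exceeds the
  Bernoulli bound $\sqrt{m(1-m)}$; the sampler rejects such inputs
  explicitly rather than silently truncating.
* The horizon is fixed at ten years with no extrapolation; late
  radiation toxicity is excluded (assumed equal between arms and
  therefore irrelevant to the increment), as are acute-toxicity costs —
  exclusions that bias, if anything, against the cheaper strategy.
* Currency is 2018 US dollars throughout; no inflation adjustment.
* Problem sizes used by the bundled checks — 100,000 PSA samples,
  1,000,000 microsimulated patients for colostomy metrics — were chosen
  to make Monte-Carlo error negligible relative to the tolerances tested
  (the NNT standard error at n = 10^6 is about 0.05).
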