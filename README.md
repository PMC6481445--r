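# rectalcea

Decision-analytic cost-effectiveness model comparing the two standard
neoadjuvant radiation strategies for locally advanced rectal cancer:

* **SCRT** — short-course radiotherapy, 25 Gy in 5 fractions, surgery about
  one week later;
* **LCRT** — long-course chemoradiotherapy, 50.4 Gy in 28 fractions with
  concurrent capecitabine, delayed surgery.

Trial evidence shows equivalent recurrence and survival, but LCRT
downstages more tumors, so more patients keep their sphincter (low
anterior resection, LAR) instead of receiving an abdominoperineal
resection (APR) with a permanent colostomy — at several times the
radiation cost. The package is written for health-economics and
radiation-oncology researchers who want to reproduce, probe, or extend
that trade-off analysis.

## The model

A six-state discrete-time Markov model (cycle length 1 year, horizon 10
years, cohort age 65): NED-LAR, NED-APR, local recurrence, salvaged local
recurrence, distant recurrence, dead. Multi-year probabilities are
converted to per-cycle probabilities under constant hazards,
`p_cycle = 1 − (1 − p)^(1/horizon)`, and competing risks are composed on
the hazard scale so transition matrices are row-stochastic for every
tested parameter value. Costs (2018 US\$, payer perspective) and QALYs
are discounted at 3%/year; the decision rule is net monetary benefit
`NMB = WTP × E − C` at a willingness to pay of \$100,000/QALY, equivalent
to the ICER-vs-WTP rule absent dominance:

```
ICER = (C_LCRT − C_SCRT) / (E_LCRT − E_SCRT)   [$ per QALY]
```

Both a deterministic cohort engine (`run_cohort()`) and an
individual-level microsimulation (`run_microsim()`, for event-history
quantities such as ever-colostomy proportions) are provided, plus
one-way/two-way sensitivity analysis with threshold finding, a
probabilistic sensitivity analysis with acceptability curves, and a
calibration routine for the unpublished salvage-pathway parameters. See
`vignettes/model-and-methods.Rmd` for conventions and calibration.

## Worked example

```r
library(rectalcea)

tab <- cea_table(rc_parameters(), published_scenarios()[c("base", "distal")])
tab[, c("scenario","strategy","cost","incremental_cost","effect",
        "incremental_effect","icer","decision")]
#>   scenario strategy  cost incremental_cost effect incremental_effect   icer decision
#> 1     base     scrt 48436                0  4.764            0.00000     NA     scrt
#> 2     base     lcrt 58496            10061  4.844            0.07078 142137     scrt
#> 3   distal     scrt 58203                0  4.379            0.00000     NA     lcrt
#> 4   distal     lcrt 66605             8402  4.524            0.12870  65287     lcrt
```

Reading this: for the full population LCRT buys 0.071 discounted QALYs
for an extra \$10,061 — an ICER of \$142,137/QALY, above the \$100,000
threshold, so SCRT is cost-effective. For distal tumors (where LCRT's
downstaging advantage is largest) the ICER falls to \$65,287/QALY and
LCRT becomes the cost-effective choice. The `effect` column is the
per-strategy undiscounted QALY tracker and `incremental_effect` is
discounted — the two conventions of the analysis this package
replicates; `effect_discounted` in the same table carries the discounted
per-strategy totals.

Threshold analysis — how cheap would LCRT have to get?

```r
one_way(rc_parameters(), "c_lcrt_3d", c(9655, 28997))
#> <threshold_result> c_lcrt_3d over [9655, 28997]
#>   preferred at bounds: LCRT / SCRT
#>   threshold: 16328.5
```

LCRT becomes cost-effective if its delivery cost (including concurrent
capecitabine) falls below about \$16,300.

A command-line wrapper over the same functions is installed at
`inst/cli/rectalcea-cli.R`
(`Rscript rectalcea-cli.R evaluate|one-way|two-way|psa|colostomy|validate|calibrate …`).

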