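# cbecea

A Markov cohort cost-effectiveness model of clinical breast examination
(CBE) screening versus no screening for HER2-positive breast cancer
patients, written for health-economics analysts working on cancer screening
in settings where mammography is not feasible.

## The model

Six health states — disease-free survival (DFS) on-treatment, DFS
off-treatment, non-metastatic recurrence, remission, metastatic breast
cancer (mBC), death — on a monthly cycle with half-cycle correction,
expanded to 87 tunnel-indexed states so that transition probabilities can
depend on time in state (12-month treatment tunnels; a 60-month mBC tunnel
carrying a year-since-entry mortality schedule). The two scenarios differ
only in the starting distribution: screening downstages diagnosis, moving
9.1 percentage points of the cohort from mBC to DFS (0.924 vs 0.833
starting in DFS).

Exit from DFS is governed by a parametric survival curve S(t) converted to
monthly probabilities, 1 − S(t+1)/S(t), scaled by a cure adjustment (95% of
the cohort cured by month 120) and split 72/28 into metastatic and
non-metastatic recurrence; background mortality comes from a life table
(annual q converted by 1 − (1 − q)^(1/12)). Outcomes are discounted
(1.5%/yr) life-years, QALYs (utilities by state group and age band), and
costs in million VND from three perspectives — patient, public payer,
healthcare sector (their exact sum) — yielding incremental
cost-effectiveness ratios

ICER = ΔCost / ΔQALY,

classified against the WHO 1× / 3× GDP-per-capita thresholds for Vietnam
(63.2 / 189.6 million VND per QALY; $1 ≈ 22,759 VND). One-way deterministic
sensitivity analysis produces a tornado table; probabilistic sensitivity
analysis (beta / log-normal / multivariate-log-normal parameter
distributions, 2000 iterations) produces cost-effectiveness-plane and
acceptability-curve tables. A microsimulation oracle, synthetic life-table
and DFS-event generators, and a censored-data Weibull fitter
(`fit_dfs_curve`, via flexsurv) complete the pipeline. The trial DFS curve
and national life table behind the original analysis are not publicly
deposited, so the packaged defaults are clearly labelled synthetic
stand-ins with realistic magnitudes: structure, directions and identities
carry over to real inputs; absolute levels do not.

## Worked example

```r
library(cbecea)
params <- default_parameters()
cea <- run_cea(params)
print(cea)
```

```
Cost-effectiveness analysis: CBE screening vs no screening
Horizon 672 months, start age 44, discount 1.5%/yr

-- patient perspective --
  screening     LY  24.35  QALY  19.76  cost    729.9 mVND
  no_screening  LY  22.14  QALY  17.95  cost    651.2 mVND
  incremental   dLY  2.21  dQALY  1.81  dCost    78.7 mVND
  ICER 43.4 mVND/QALY (~$1908/QALY): highly_cost_effective

-- public payer perspective --
  screening     LY  24.35  QALY  19.76  cost    460.4 mVND
  no_screening  LY  22.14  QALY  17.95  cost    376.0 mVND
  incremental   dLY  2.21  dQALY  1.81  dCost    84.4 mVND
  ICER 46.5 mVND/QALY (~$2044/QALY): highly_cost_effective

-- healthcare sector perspective --
  screening     LY  24.35  QALY  19.76  cost   1190.3 mVND
  no_screening  LY  22.14  QALY  17.95  cost   1027.2 mVND
  incremental   dLY  2.21  dQALY  1.81  dCost   163.1 mVND
  ICER 89.9 mVND/QALY (~$3952/QALY): cost_effective
```

Screening adds 2.21 life-years and 1.81 QALYs per person under the
synthetic inputs, at an extra 84.4 million VND from the public payer —
46.5 million VND per QALY gained, under the 63.2 million VND
(1× GDP per capita) bar, so highly cost-effective; from the healthcare
sector perspective the ICER lands between the two bars (cost-effective).
The cost of screening itself enters as a one-off 55 million VND per
diagnosis (healthcare sector): 0.033 million VND per examination divided by
the 0.06% detection rate.

One-way sensitivity (public payer):

```r
tornado <- run_dsa(params, perspective = "public_payer")
head(tornado[, c("path", "icer_low", "icer_high", "width")], 4)
```

```
                      path icer_low icer_high width
1    start.dfs_noscreening    33.31     66.42 33.11
2 settings.discount_annual    34.88     64.65 29.77
3        dfs.max_cure_rate    64.39     45.55 18.84
4       settings.start_age    41.11     55.23 14.12
```

The widest bar is the downstaging effect: narrowing the starting-state gap
(no-screening DFS start at 0.874) pushes the ICER from 46.5 to 66.4 million
VND. Probabilistic analysis and exports:

```r
psa <- run_psa(params, "public_payer", n_iterations = 2000, seed = 1)
ceac_table <- ceac(psa)
write_outputs(cea, "results", dsa = tornado, psa = psa, seed = 1)
```

Every PSA iteration falls in the northeast quadrant of the
cost-effectiveness plane (more effective, more costly). Configuration files
(YAML, validated against the parameter schema) and delimited life-table /
event-table inputs are supported via `load_config()`, `read_life_table()`
and `read_dfs_events()`; see `inst/extdata/example_config.yaml` and the
vignette in `vignettes/cbe-screening-model.Rmd`.

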