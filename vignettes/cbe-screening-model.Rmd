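---
title: "A Markov cohort model of CBE screening for HER2-positive breast cancer"
author: "cbecea authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of CBE screening for HER2-positive breast cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbecea)
```

## The decision problem

Mammography-based breast cancer screening is not a realistic option for many
low- and middle-income settings. Clinical breast examination (CBE) is a
low-cost alternative whose main clinical effect is *downstaging*: a screened
population is diagnosed earlier, so a smaller share presents with metastatic
(stage IV) disease. For HER2-positive patients, earlier diagnosis also means
eligibility for costly targeted therapy, so screening raises treatment
spending at the same time as it raises survival — the subgroup where
cost-effectiveness is hardest to demonstrate, and therefore the most
informative one to model.

`cbecea` implements this comparison as a Markov cohort model of two
scenarios that differ only in the starting-state distribution: with
screening, 92.4% of diagnosed patients enter in disease-free survival (DFS)
and 7.6% with metastatic breast cancer (mBC); without screening, 83.3% and
16.7%. The 9.1-percentage-point difference is the downstaging effect.

## Model structure

Six base health states: DFS on-treatment, DFS off-treatment, non-metastatic
recurrence, remission, mBC, and death. The cycle length is one month, with
half-cycle correction (state membership for a cycle is the average of its
start and end occupancy). Time-in-state dependence is handled by tunnel
expansion:

* DFS on-treatment and non-metastatic recurrence last at most 12 months
  (the standard duration of adjuvant targeted therapy); survivors of the
  12th tunnel month move to DFS off-treatment and remission respectively.
* mBC is expanded into 60 monthly tunnels so that its mortality can follow
  a year-since-entry schedule (monthly probabilities 0.0324, 0.0446,
  0.0492, 0.0511, 0.0541 for years 1–5); the 60th tunnel month is absorbing
  in tunnel time, holding the year-5+ rate thereafter.

The expanded space has 87 states. `make_state_space()` enumerates it,
`build_transition_matrix()` produces the per-cycle row-stochastic matrix,
and `run_cohort()` propagates a cohort. Rows failing stochasticity by more
than 1e-9, or trace rows failing conservation by more than 1e-10, raise
errors; nothing is silently renormalised.

Exits from the disease-free states combine three ingredients:

1. a parametric DFS curve S(t) (Weibull by default), converted to the
   conditional monthly event probability `1 - S(t+1)/S(t)`;
2. a cure adjustment: the cured fraction ramps linearly from 0 at diagnosis
   to 95% at month 120 and the recurrence probability is multiplied by one
   minus the cured fraction (a step-at-threshold variant is available via
   `cure_ramp = "step"`; the linear ramp is the default because it avoids a
   discontinuous hazard while reaching the same cured fraction at the
   threshold);
3. background mortality from a life table, converted from annual to monthly
   by `1 - (1 - q)^(1/12)` and looked up at the cohort's floored current
   age.

Death and recurrence compete multiplicatively with death taking precedence
(stay-probability `(1 - p_death)(1 - p_rec)`), so outflow can never exceed
one. Recurrences split 72% metastatic / 28% non-metastatic. Patients in
non-metastatic recurrence face only background mortality and move to
remission automatically after 12 months if alive; remission progresses to
mBC at 0.0076 per month. mBC mortality uses its own schedule alone — it
already reflects all-cause mortality for that state and dominates
background risk by an order of magnitude.

Because no state re-enters DFS, months-since-diagnosis for the DFS curve
and the cure ramp equals the cycle index, which is why DFS off-treatment
needs no tunnel of its own.

## Outcomes and costs

Life-years and QALYs accrue 1/12 per effective (half-cycle-corrected)
person-month, discounted at `(1 + r)^(-t/12)` with r = 1.5% per year.
Utilities are age-band-specific by default (bands <40, 40–49, 50–59, 60+,
switching at the floored cohort age), with pooled means available by
setting `utilities.age_adjusted` to `FALSE` (that is also what the
published one-way analysis did). Non-metastatic recurrence shares the DFS
on-treatment utility; remission shares DFS off-treatment.

Costs, in million VND throughout (USD derived only at reporting time, at
22,759 VND/USD), are kept per perspective — patient out-of-pocket, public
payer, and their component-wise sum, the healthcare sector; validation
enforces the additivity identity exactly. One-off costs at cycle 0
(undiscounted, not half-cycle corrected): the diagnosis cost in both arms —
every modelled person is a diagnosed patient — and, in the screening arm
only, the CBE cost per diagnosis, i.e. the per-person examination cost
divided by the 0.06% detection rate (0.033/0.0006 = 55 million VND from the
healthcare-sector perspective). Monthly streams: treatment cost in the
on-treatment states (the treatment mix defaults to 100% targeted therapy
in early-stage states and 0% in mBC, reflecting the reported choice
pattern; both fractions are configurable because no source prints them),
follow-up care off treatment, and in mBC supportive care for everyone plus
the 40-month-amortised targeted course for the (by default empty) targeted
fraction.

## Synthetic inputs and what they do and do not show

Two inputs of the original analysis are not publicly deposited: the
trial-derived DFS curve and the national life table. The package ships
clearly labelled synthetic stand-ins:

* `make_life_table()` — a deterministic Gompertz–Makeham table
  (makeham 4e-4, baseline 1e-5, slope 0.1/year, ages 0–100), giving
  q(44) ≈ 0.0012 and q(80) ≈ 0.03, the right order of magnitude for adult
  female mortality in Vietnam.
* the default DFS curve — Weibull shape 0.9 (decreasing hazard), scale 380
  months, i.e. raw 10-year event-free survival ≈ 0.70, a plausible
  adjuvant-HER2 magnitude.
* `make_dfs_events()` — individual event data from a known Weibull with
  exponential censoring and a 72% metastatic share among events, so the
  whole fit–configure–run pipeline is testable; `fit_dfs_curve()` (maximum
  likelihood under right censoring via `flexsurv`) recovers the generating
  parameters and exposes the log-scale covariance the PSA needs.

Consequences: structural and arithmetic results (transition logic, accrual,
ICER arithmetic, screening-cost identities, sensitivity directions) carry
over to real inputs, but absolute magnitudes do not. With the synthetic
inputs the cohort's discounted life expectancy (~24 discounted life-years
in the screening arm) exceeds the published ~14.5, so absolute LY/QALY/cost
levels and hence ICER levels differ from the published table, and a 30-year
horizon — effectively lifetime for the published cohort — truncates benefit
accrual here (raising the ICER by roughly a quarter), while horizons that
cover the synthetic cohort's lifetime (about 55 years and up) leave the
ICER insensitive to the exact bound. Users with access to a real life
table and fitted curve can drop them in via `read_life_table()` /
`fit_dfs_curve()` and a config file.

## Sensitivity analysis

`run_dsa()` is strictly one-way: each parameter in turn at its low and high
value (95% CI where reported, otherwise ±20%), ICER recorded at both ends,
bars sorted by width with lexicographic tie-breaks. Pinning a parameter at
its base value reproduces the base-case ICER bit-for-bit.

`run_psa()` draws all parameters jointly and independently across blocks:
beta for probabilities and utilities, log-normal for costs, multivariate
normal on the log scale for the Weibull parameters (fitted covariance when
available, otherwise diagonal with 10% coefficients of variation).
Hyperparameters are calibrated by matching the mean exactly and minimising
squared 2.5%/97.5% quantile error against the range (`fit_beta()`,
`fit_lognormal()`); where only a ±20% range exists its endpoints are
treated as the 95% interval, and utility upper bounds are capped at 0.99 to
stay inside the beta support. One deliberate coupling: the PSA draws the
no-screening starting probability and moves the screening start with it,
preserving the base-case downstaging reduction. Drawing the baseline
independently of a fixed screening start would let roughly 1 in 200 draws
reverse the downstaging sign, which contradicts the premise that the same
population is modelled under both scenarios; with the coupling, every
iteration lands in the northeast quadrant of the cost-effectiveness plane,
as in the original analysis. An independent-draws setup remains available
by passing an explicit `distributions` list.

The acceptability curve (`ceac()`) uses strict net monetary benefit
(`wtp * dQALY - dCost > 0`; ties count as not cost-effective).

## Validation

Three independent routes check the engine:

* the default fast propagation against literal per-cycle matrix
  multiplication (agreement to 1e-13);
* closed forms: geometric decay under constant mortality (19.5 effective
  person-months for a 5%/month cohort), tunnel exhaustion, unit-utility
  QALY = LY identity, 12-month survival products reproducing annual
  probabilities to 1e-12;
* `microsim_oracle()`, an individual-level simulation of the identical
  discrete-time process (one RNG sub-stream per individual, so results do
  not depend on iteration order) with the same half-cycle and discounting
  conventions, whose means the cohort model must match within Monte-Carlo
  error.

## Numerical and design choices

* Discounting uses the cycle-start exponent t/12 applied to that cycle's
  half-cycle-corrected accrual, consistent with the endpoint-average
  correction.
* The default horizon is 672 cycles (cohort age 100 from start age 44);
  the life table's last row covers all older ages.
* Test and validation problem sizes (e.g. 2000 PSA iterations, 20,000
  microsimulated individuals, 5000-patient fit fixtures) are the analysis'
  own defaults and keep every stage to seconds or a few minutes on one
  core.
* USD amounts round half away from zero to whole dollars.
* DSA perturbations of one perspective's cost input intentionally break the
  perspective-additivity identity for the perspectives not under analysis;
  validation is therefore strict at construction and config load, relaxed
  inside sensitivity reruns.

## Known limitations

Stages I–III are pooled into one DFS state; societal-perspective (indirect)
costs are out of scope, as in the source analysis; correlations other than
the DFS-curve covariance are not modelled in the PSA; and the packaged
base-case magnitudes are synthetic-input magnitudes, not reproductions of
the published table.

## A worked run

```{r example, eval = FALSE}
params <- default_parameters()
cea <- run_cea(params)
print(cea)

tornado <- run_dsa(params, perspective = "public_payer")
head(tornado, 4)

psa <- run_psa(params, "public_payer", n_iterations = 2000, seed = 1)
print(psa)
head(ceac(psa))

write_outputs(cea, "results", dsa = tornado, psa = psa, seed = 1)
```
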