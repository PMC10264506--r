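---
title: "A Markov cost-utility model of supervised exercise after endometrial cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cost-utility model of supervised exercise after endometrial cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excea)
library(dplyr)
```

## The decision problem

Cardiovascular disease (CVD) is the leading cause of death among women who
survive early-stage endometrial cancer: survivors are frequently overweight
and carry obesity-driven comorbidity, and their CVD-specific mortality
substantially exceeds that of the general female population. Supervised
exercise after curative-intent treatment reduces both CVD risk and the risk
of cancer recurrence, but it is not routinely funded as part of recovery
care. `excea` implements a decision-analytic model asking whether a 12-week
programme of 18 individually supervised exercise sessions is good value for
money compared with standard care, from the Australian health-system
perspective.

## Model structure

The model is a discrete-time Markov cohort model with annual cycles and six
mutually exclusive health states:

1. **no CVD** — disease-free survivorship (the whole cohort starts here at
   a starting age of 64, the rounded cohort mean);
2. **post-stroke**, 3. **post-CHD**, 4. **post-heart failure** — permanent
   states entered by surviving a first cardiovascular event;
5. **post-cancer recurrence** — entered on locoregional recurrence;
6. **dead** — absorbing.

From *no CVD* three risks compete each cycle: a first CVD event, cancer
recurrence, and background (all-cause) mortality taken from an age-indexed
life table. Competing risks are resolved simultaneously on the rate scale:
each annual probability is converted to a constant hazard, the total exit
probability is `1 - exp(-sum of rates)`, and exits are allocated in
proportion to their rates. This allocation is order-independent, which is
why it was preferred over any sequential "first check recurrence, then CVD"
convention. A CVD event is split into stroke/CHD/heart failure by a
Dirichlet share vector (means 0.35/0.31/0.34) and each event type is fatal
with its case-fatality probability (0.478 stroke, 0.424 CHD and heart
failure). The post-event and post-recurrence states admit no further event
transitions (the states are mutually exclusive); their only exit is death,
combining the disease-specific annual death probability with background
mortality multiplicatively on the survival scale.

The exercise arm differs from standard care in exactly two mechanisms,
sustained over the whole horizon: a hazard ratio of 0.77 on CVD events and
0.33 on recurrence, both applied on the rate scale
(`1 - (1 - p)^hr`), plus a one-time programme fee of $1,381 in the first
cycle.

### Cycle-length conversions

All multi-year inputs are annualised under a constant-hazard (exponential)
assumption — the only assumption the published point estimates support:

* 14-year cumulative risks (CVD 0.158, recurrence 0.240) via
  `p -> rate -> annual p`, giving 0.0122 and 0.0194 per year;
* 5-year survival fractions after stroke/CHD/heart failure/recurrence
  (0.731/0.859/0.705/0.625) via `1 - S^(1/5)`.

The 14-year window for the recurrence risk follows the source cohort's
follow-up; the annual value is sensitive to this reading (see
*Limitations*).

### Rewards, discounting and half-cycle correction

Utilities: *no CVD* takes the age-specific baseline utility; the post-event
states take absolute tabulated utilities (0.651/0.720/0.789); recurrence
applies a 0.112 decrement to the age-specific baseline (floored at zero);
death is 0. One-time disutilities for a first-time event
(0.075/0.15/0.07) attach to the non-fatal entering flows, so they are
counted exactly once. Costs: all alive non-recurrence states carry annual
cancer surveillance ($1,601, the single tabulated annual mean — the
6-monthly-then-annual follow-up schedule is collapsed into it); post-event
states add their follow-up costs; recurrence carries follow-up cancer care
($4,880) instead of surveillance. Acute treatment costs attach to non-fatal
event entries, recurrence treatment ($13,126) to recurrence entry, and a
fatal event carries a configurable one-time cost, defaulting to the event
type's acute treatment cost (the source for this quantity is not printed;
the default is deliberate and overridable via `fatal_event_cost`).

Costs and QALYs are discounted at 5% per year with a cycle-end convention
(cycle *t* discounted by `1.05^-t`). Half-cycle correction is the classic
trapezoid: state-reward accruals at the first and final cycle points are
half-weighted, for both costs and QALYs. One-time transition rewards are
never half-weighted because they are instantaneous events. The programme
fee is charged once to the entire cohort at the cycle-1 discount factor
rather than occupancy-weighted: every participant incurs the fee during the
first year regardless of later transitions, and this makes cost-only
scenario increments exact.

## Parameters and calibration

`parse_parameter_table()` loads the 33-row registry (15 transition, 8
utility, 10 cost parameters) shipped at `excea_example("parameters.csv")`
and calibrates every row into a samplable distribution. The sources publish
only a mean and a 95% CI, so calibration is a declared convention, not a
recovered fact:

* **normal**: `sd = width / (2 * 1.96)`;
* **lognormal**: `sdlog = log-width / (2 * 1.96)` with
  `meanlog = log(mean) - sdlog^2/2`, so the analytic mean equals the stated
  mean exactly;
* **beta / gamma**: the mean is matched exactly and the one remaining free
  parameter (precision, shape) is found by least squares on the 2.5% and
  97.5% quantiles against the stated CI;
* **Dirichlet**: concentration `mean * n_eff` with `n_eff = 100` by
  default — moderate uncertainty consistent with a single cohort source,
  and configurable because no concentration is published.

Across the packaged table this reproduces every mean to machine precision
and every CI bound to within 10% of the interval width. Draws are clipped
post hoc (probabilities and utilities to [0, 1], costs and disutilities to
[0, Inf)) to guard against heavy gamma tails; the starting age is sampled
as a normal in the PSA but rounded to an integer for table lookups.

## Synthetic age-indexed inputs

Two inputs of the original analysis are age-indexed tables that are not
printed: the national female life table and the age-specific baseline
utility norms. The package ships generators for documented stand-ins:

* `generate_life_table()` — Gompertz–Makeham hazard
  `q_x = 1 - exp(-(a + b * c^x))` with defaults `a = 2e-4`, `b = 8e-6`,
  `c = 1.11`, chosen once so that period life expectancy at age 64 is
  about 23 years (typical for women in a high-income country), with
  closure `q = 1` at age 110;
* `generate_utility_table()` — linear decline
  `u(age) = 0.81 - 0.03 * (age - 60)/10`, anchoring utility 0.81 at age 60
  and losing 0.03 per decade, in the range of published female EQ-5D
  population norms.

Both accept a real table in the same `age,qx` / `age,utility` CSV schema
(`read_age_table()`), which is the intended route for exact-reproduction
work. What the stand-ins do **not** emulate: cohort-specific utility
levels of cancer survivors (published totals imply a baseline utility
near 0.87 at these ages, higher than general-population norms), old-age
mortality deceleration, and year-specific life-table detail. Passing tests
therefore demonstrate the correctness of the machinery and the relative
economics of the comparison, not agreement with any specific national
data year.

## Analyses

```{r basecase}
registry <- parse_parameter_table(excea_example("parameters.csv"))
bc <- base_case(registry)
glance(bc)
```

* `base_case()` — both arms at point estimates; reports incremental cost,
  incremental QALYs, the ICER with a dominance flag, and the incremental
  net monetary benefit `iNMB = wtp * dQALY - dCost` at the $50,000/QALY
  threshold.
* `run_psa()` — Monte Carlo propagation (default 10,000 iterations); one
  joint draw drives both arms so all parameter uncertainty is common
  across arms. The summary ICER is the **ratio of mean increments**, not
  the mean of per-iteration ratios, which is unstable when `dQALY_i` is
  near zero; the deterministic base-case ICER is reported alongside, and
  the pairwise-ratio percentiles are exposed for comparability with
  percentile presentations.
* `ceac()` — for each willingness-to-pay value, the fraction of iterations
  with positive iNMB.
* `tornado()` — one parameter at a time at its 95% CI bounds (the only
  published ranges), all others at their means, sorted by ICER bar width.
* `horizon_sweep()` — re-runs the base case over horizons 1–40 years and
  flags the first cost-effective (iNMB > 0) and first dominant year.
* `extended_supervision_scenario()` — a costing scenario adding 36 further
  supervised sessions at $75/hour ($2,700) to the first-cycle fee,
  effectiveness unchanged.

```{r psa, fig.width = 6, fig.height = 4}
psa <- run_psa(registry, n_iter = 500, seed = 1)
glance(psa)[, c("delta_cost", "delta_qaly", "icer", "inmb")]
autoplot(ceac(psa))
```

(This vignette uses 500 iterations to keep build time down; analyses in
the package's tests and acceptance script use the full 10,000.)

## Numerical conventions and degenerate inputs

* Transition-matrix rows are validated to sum to 1 within `1e-9`; any
  negative computed probability is an error naming the offending cell, not
  a silent clamp.
* `p = 1` is rejected by `prob_to_rate()` (infinite rate); a survival
  fraction of 0 annualises to certain death with a warning.
* With every risk zeroed the transition matrix is exactly the identity,
  and with background mortality alone the trace reproduces the life
  table's cumulative survival to `1e-10` — both are tested invariants.
* A PSA over a registry of point masses is bit-identical to the base case;
  equal hazard ratios and a zero fee make the two arms exactly equivalent.
* Seeds: every stochastic entry point takes one integer seed
  (`withr::with_seed`), so results are reproducible and the caller's RNG
  state is untouched.

## Design choices that were genuinely open

* **ICER under PSA**: ratio of means, with the base case alongside —
  published presentations differ and the two printed numbers this model
  relates to are themselves inconsistent (the printed increments imply
  ~$4,537/QALY while the headline ICER is $5,184/QALY); reporting both
  avoids guessing intent.
* **Fatal-event one-time cost**: no value is printed; the default equals
  the event's acute treatment cost and is exposed as an override.
* **Recurrence from post-CVD states**: disallowed — the state diagram
  shows no such arrows and the states are described as mutually exclusive.
* **Intervention fee timing**: whole-cohort charge at the cycle-1 discount
  factor (see above).
* **Half-cycle correction scope**: applied to both costs and QALYs; the
  original description does not restrict it to one of the two.

## Limitations

* The two unprinted age-indexed inputs are synthetic; with them the model
  reproduces the published *relative* economics closely (the ratio of mean
  increments agrees with the ratio implied by the published increments to
  about 0.1%) but both absolute increments come out at roughly 40% of the
  published values, so headline agreement requires substituting the real
  tables.
* The annualised recurrence risk assumes the 0.240 cumulative risk refers
  to the source cohort's full 14-year follow-up; a shorter window would
  raise it substantially.
* Constant hazards within and across cycles; no tunnel states beyond the
  one-time entry rewards; no CVD after recurrence; health-system
  perspective only, costs as published for 2021 Australian dollars with no
  further inflation adjustment.
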