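# excea

Cost-utility modelling of a supervised exercise programme for survivors of
early-stage endometrial cancer.

Cardiovascular disease (CVD) is the leading cause of death after treatment
for early-stage endometrial cancer, and exercise reduces both CVD risk and
cancer recurrence in this population. `excea` implements a six-state Markov
cohort model — *no CVD*, *post-stroke*, *post-CHD*, *post-heart failure*,
*post-cancer recurrence*, *dead* — that compares a 12-week programme of 18
supervised exercise sessions against standard care over a 5-year horizon
from the Australian health-system perspective, with annual cycles, 5%
discounting and half-cycle correction. It is written for health economists
and methodologists who want a tested, scriptable version of this class of
analysis: every published mean and 95% CI is loaded from a tabulated
registry, calibrated into a samplable distribution, and propagated through
deterministic and probabilistic analyses.

## The model in brief

* Competing risks out of *no CVD* (first CVD event, recurrence, background
  death) are resolved on the rate scale: annual probabilities become
  constant hazards (`r = -ln(1-p)/t`), total exit is `1 - e^{-Σr}`, and
  exits split in proportion to rates. CVD events divide into
  stroke/CHD/heart failure by a Dirichlet share vector and are fatal with
  their case-fatality probabilities.
* The exercise arm applies sustained hazard ratios (0.77 on CVD, 0.33 on
  recurrence; `p' = 1 - (1-p)^{HR}`) and a one-time programme fee of
  $1,381 in the first cycle.
* Outcomes: discounted costs (AUD) and QALYs per arm; incremental cost
  ΔC, incremental QALYs ΔQ, `ICER = ΔC/ΔQ`, and net monetary benefit
  `iNMB = λ·ΔQ − ΔC` at λ = $50,000/QALY.
* Uncertainty: 10,000-iteration Monte Carlo PSA with mean-exact,
  CI-least-squares calibrated beta/gamma/lognormal/normal/Dirichlet
  distributions; cost-effectiveness acceptability curves; one-way (tornado)
  sensitivity at the 95% CI bounds; time-horizon sweep; an
  extended-supervision costing scenario (+36 sessions × $75).

Two age-indexed inputs (female life table, baseline utility norms) are not
printed in the source material; the package generates documented synthetic
stand-ins (Gompertz–Makeham mortality; linear utility decline) and accepts
real tables in the same `age,qx` / `age,utility` CSV schema. See the
vignette `vignettes/cost-utility-model.Rmd` for the model's assumptions and
what the stand-ins do and do not emulate.

## Worked example

```r
library(excea)

registry <- parse_parameter_table(excea_example("parameters.csv"))
bc <- base_case(registry)
bc
#> <ec_ce_result: base_case>
#>   exercise      $    9396  3.3955 QALYs
#>   standard care $    9250  3.3621 QALYs
#>   dCost $146, dQALY 0.0334, status trade_off
#>   ICER $4354/QALY, iNMB $1526 at WTP $50,000
```

At point estimates with the synthetic tables, exercise costs $146 more per
woman over 5 years, gains 0.0334 QALYs, and buys a QALY at $4,354 — far
below the $50,000 threshold, for a positive net benefit of $1,526 per
woman.

```r
psa <- run_psa(registry, n_iter = 1000, seed = 42)
glance(psa)[, c("delta_cost", "delta_qaly", "icer", "inmb")]
#>   delta_cost delta_qaly     icer     inmb
#> 1   198.2829      0.033 6011.424 1450.935
ceac(psa, 50000)$p_cost_effective
#> [1] 0.929
```

Under joint parameter uncertainty the ratio-of-means ICER is ~$6,000/QALY
and exercise is cost-effective at the threshold in 93% of iterations
(≈94% at the full 10,000 iterations). `autoplot()` methods draw the
cost-effectiveness plane, the acceptability curve, the tornado diagram,
the horizon sweep and cohort traces; `tornado()`, `horizon_sweep()` and
`extended_supervision_scenario()` cover the remaining analyses, and the
`cmd_basecase()`/`cmd_psa()`/`cmd_sensitivity()`/`cmd_fixtures()` functions
(or the thin CLI at `inst/cli/excea.R`) write all outputs as stamped
CSV/JSON files.

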