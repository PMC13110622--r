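# fatiguecea

A decision-analytic **cost-utility model of non-pharmacological fatigue
interventions** (physical activity promotion, CBT-based fatigue management,
mindfulness; each delivered individually or in groups) versus usual care, for
people with persistent fatigue associated with long-term medical conditions,
from a UK NHS/PSS perspective.

It is written for health-economic modellers who have category-level fatigue
treatment effects on the standardised-mean-difference (SMD) scale — e.g.
posterior draws from a network meta-analysis — plus study-level delivery
descriptions, and who want expected costs, QALYs, net monetary benefit and
full probabilistic uncertainty analysis out of a single auditable model.

## The model

For each strategy the treatment effect at end of treatment (EOT), short-term
(ST, ≤3 months after EOT) and long-term (LT, >3 months after EOT) follow-up
is converted from the SMD scale to Fatigue Severity Scale (FSS, 9–63) points,

&nbsp;&nbsp;ΔFSS(t) = SMD(t) · σ_FSS,&nbsp;&nbsp;FSS(t) = FSS₀ + ΔFSS(t),

with σ_FSS = 15.1 and baseline FSS₀ = 43.73. Usual care stays at FSS₀.
Between follow-ups the FSS path is piecewise linear; a missing ST point is
linearly interpolated between EOT and LT; after the last follow-up the effect
wanes linearly to zero at the horizon (24 months in the base case), or
returns immediately to baseline under the pessimistic scenario. FSS is mapped
to SF-6D utility by a configurable linear algorithm u = β₀ + β₁·FSS (β₁ < 0),
and QALYs are the discounted area under the utility curve,

&nbsp;&nbsp;Q = ∫₀^T u(t) (1+r)^(−t/12) dt / 12,&nbsp;&nbsp;r = 3.5 % p.a.,

evaluated by dense trapezoidal quadrature (0.25-month step, knots included).
Intervention costs are staff time: sessions × hours × unit cost, divided by
group size for group delivery; the category cost is the median across
studies. Decision metrics are NMB = λ·Q − C at λ = £20 000/QALY, INMB and
ICER versus usual care, pairwise cost-effectiveness probabilities, and the
multiway cost-effectiveness acceptability curve. The probabilistic analysis
(5000 iterations) draws SMDs row-wise from posterior samples (preserving
cross-timepoint correlation), baseline FSS from a truncated normal, mapping
coefficients from normals and costs from method-of-moments gamma
distributions. Eleven scenario analyses (horizons 15/48 months, immediate
waning, alternative baseline, delivery-specific CBT effects, earliest-LT
evidence, zero ST effect, low/high costs, 1.5 %/6 % discounting) are
declarative overlays on one model definition.

The published FSS→SF-6D regression coefficients are not redistributed here;
the shipped defaults are clearly-labelled synthetic placeholders (see the
methods vignette), as is the entire `reference_fixture()` input bundle.

## Worked example

```r
library(fatiguecea)
fx  <- reference_fixture()                 # synthetic 7-strategy bundle
det <- run_deterministic(fx$config, fx)
det[, c("strategy", "cost", "qalys", "inc_qalys", "inmb")]
```

```
                      strategy   cost qalys inc_qalys   inmb
1                   usual_care   0.00 1.228   0.00000   0.00
2 physical_activity_individual 114.23 1.273   0.04546 794.92
3      physical_activity_group  38.95 1.273   0.04546 870.20
4       cbt_fatigue_individual 629.74 1.261   0.03304  31.14
5            cbt_fatigue_group  97.50 1.261   0.03304 563.38
6       mindfulness_individual 314.89 1.274   0.04651 615.34
7            mindfulness_group  58.19 1.274   0.04651 872.05
```

Every intervention has positive INMB at £20 000/QALY, but the expensive
individually-delivered CBT strategy is marginal (£31; its ICER of
£19 058/QALY sits just under the threshold) — cost, not effect, drives the
ranking, and group delivery wins within each category.

```r
psa  <- run_psa(fx$config, fx)             # 5000 iterations
ceac <- multiway_ceac(psa, fx$config$lambda_grid)
subset(ceac, lambda == 20000)
```

```
    lambda                     strategy probability
141  20000                   usual_care      0.0004
143  20000      physical_activity_group      0.4622
145  20000            cbt_fatigue_group      0.0672
147  20000            mindfulness_group      0.4702
```

(zero rows omitted). The two cheap group strategies split almost all of the
probability of being the most cost-effective option; the pairwise
probability of individual CBT beating usual care is 0.53 versus 0.999 for
group physical activity. Scenario analyses:

```r
res <- run_scenarios(fx$config, fx)        # base case + 11 overlays
subset(res, inmb_sign_flip)                # strategies whose verdict changes
```

Under the synthetic inputs only `cbt_fatigue_individual` flips to negative
INMB, and it does so under the 15-month horizon, immediate-waning,
alternative-baseline and high-cost overlays — the fragility pattern this
kind of model is designed to expose for a high-cost, modest-effect strategy.

A command-line wrapper covers the same pipeline
(`synth`, `run`, `psa`, `ceac`, `scenarios`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli/fatiguecea.R", package="fatiguecea"))') \
    run --out-dir out --seed 1
```

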