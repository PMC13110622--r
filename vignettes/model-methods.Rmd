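---
title: "Model methods: cost-utility analysis of non-pharmacological fatigue interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatiguecea)
```

# The decision problem

People with long-term medical conditions frequently experience persistent
fatigue, and several non-pharmacological interventions — physical activity
promotion, CBT-based fatigue management, mindfulness — reduce it. These
interventions differ greatly in delivery intensity (and therefore cost),
while their fatigue effects, pooled at the category level on the
standardised-mean-difference (SMD) scale, are broadly similar. The question
the model answers is which strategy offers the best value at a
willingness-to-pay threshold λ for a QALY, compared with usual care and with
each other, and how robust that verdict is to the assumptions that evidence
gaps force on the analyst.

# Model structure

## From SMD to utility

Fatigue effects arrive as SMDs versus usual care at up to three follow-ups:
end of treatment (EOT), short-term (ST, defined as up to 3 months after EOT)
and long-term (LT, more than 3 months after EOT). Each is converted to
Fatigue Severity Scale (FSS) points by multiplying by the population SD of
the baseline FSS (σ = 15.1 by default), added to the common baseline FSS
(43.73), and clamped to the instrument range [9, 63]. Usual care keeps its
baseline FSS throughout. Utility is a linear map u = β₀ + β₁·FSS with
β₁ < 0, clamped to a configurable range ([0, 1] by default; SF-6D tariffs
have a floor near 0.29, so a tighter floor can be configured). The shipped
β₀ = 0.832, β₁ = −0.0045 are **synthetic placeholders**: the published
FSS→SF-6D regression that motivated this structure is not redistributed
here. They were chosen once so that utility at the baseline FSS is ≈ 0.635,
a plausible SF-6D value for moderate-to-severe fatigue, and are replaced via
the `mapping:` section of a config file when real coefficients are
available.

## Trajectories and waning

The absolute FSS path is piecewise linear through the knots at t = 0 and the
observed follow-ups. Evidence gaps are handled explicitly:

* **Missing ST**: the path runs straight from EOT to LT (linear change); a
  scenario flag instead forces a zero-effect ST knot. When the category has
  no ST *time* either, that forced knot is placed at EOT + 3 months, the
  boundary of the ST window — a choice the data cannot inform, made once.
* **Waning**: after the last observed follow-up the effect declines linearly
  to zero at the horizon (24 months base case; the horizon is also the
  waning endpoint under 15- and 48-month scenarios), or, pessimistically,
  the FSS returns to baseline immediately after the last follow-up
  (represented by a knot 10⁻⁶ months later, so knot times stay strictly
  increasing).
* **`none_beyond_followup`** treats the effect as zero wherever data are
  unavailable: zero-effect knots at missing interior points and an immediate
  return after the last observed follow-up.

## QALYs

QALYs are the discounted area under the utility curve,
Q = (1/12)·∫₀^T u(t)·(1+r)^(−t/12) dt with t in months, r = 3.5% per annum.
The integral uses trapezoidal quadrature on a 0.25-month grid with all knot
times inserted as nodes, so kinks never straddle a panel; for a constant
utility over 24 months this is within 10⁻⁷ QALYs of the closed-form annuity
(1−(1+r)^(−2))/ln(1+r), and the suite verifies general piecewise-linear
paths against an exact per-segment integral ∫(a+bt)e^(−ct)dt. Discounting is
continuous in time by default; this convention is genuinely open (the AUC
formulation suggests it, but annual-step weights are common in cohort
models), so an `"annual"` method — rectangle weights (1+r)^(−⌊t/12⌋), with
panels split at year boundaries — is available behind the
`discount_method` switch. FSS clamping and utility clamping are applied
pointwise at the quadrature nodes, after interpolation on the FSS scale;
with a linear mapping the order is immaterial away from clamp boundaries,
and doing arithmetic on the FSS scale first matches the model's
FSS-centred formulation.

## Costs

Intervention costs are staff time only: sessions × (minutes/60) × hourly
unit cost × staff per group, multiplied by the number of groups and divided
by participants for group delivery; a group size not reported is assumed to
be one group. Several staff-role rows per study arm are summed before the
per-patient division. Costs from older unit-cost compendia are uplifted by a
pay-and-prices index ratio (the shipped index values are synthetic
stand-ins). The category's deterministic cost is the **median** across study
arms; its SE, needed for the gamma PSA distribution, is not reported
anywhere, so the low–high range across studies is treated as a pseudo-95%
interval, SE = (high − low)/3.92, with SE = 25% of the expected cost as the
single-study and degenerate-range fallback. Intervention delivery is shorter
than a year, so costs are not discounted. Downstream resource-use offsets
and non-staff costs (web/app tools) are out of scope by construction.

## Probabilistic analysis

Each of the 5000 iterations draws one joint parameter set:

* **SMDs**: one row of the posterior draws per strategy, preserving the
  cross-timepoint correlation within a draw. Draws are consumed without
  replacement — more iterations than draws is an error unless a bootstrap
  flag is set — because cycling would silently break the correlation
  structure.
* **Baseline FSS**: Normal(43.73, 15.10) — the sampling SD is the one
  implied by the reported 95% CI, (73.33−14.13)/(2·1.96) — truncated to
  [9, 63] by resampling. Truncation is not innocuous: it moves the mean of
  the sampled baseline to 41.21, which the test suite checks against the
  closed-form truncated-normal mean rather than pretending the mean is
  unchanged.
* **Mapping coefficients**: independent normals by default (variance-
  covariance matrices are typically unreported; independence is the stated
  fallback), jointly normal when a covariance is configured.
* **Costs**: gamma with method-of-moments shape = m²/se², rate = m/se².

All strategies share the baseline and coefficient draw within an iteration
(common random numbers): the comparison lives inside one model realisation,
which reduces comparison variance. Whether the original analysis did this is
unknowable from the outside, so it is a config switch
(`psa$common_random_numbers`). Internally the PSA exploits the fact that,
clamps aside, the node-level FSS path is affine in the SMD vector, so each
strategy is a single matrix product per run; the test suite pins this fast
path to the explicit per-trajectory computation at machine precision.

## Decision outputs

NMB = λ·Q − C at λ = £20 000/QALY; INMB versus usual care (per-iteration,
then averaged — identical to the INMB of the means by linearity); ICER with
dominance classification and a |ΔQ| < 10⁻⁹ division guard; pairwise
probability of cost-effectiveness (ties count *against* the intervention —
conservative); and the multiway CEAC on a λ grid (0–50 000 by 1000, always
including 20 000), where iterations tying for the maximum NMB contribute
equal shares so probabilities sum to exactly 1. Tie handling is not
externally specified; equal splitting is the unbiased choice for the
multiway curve, while the conservative pairwise rule avoids flattering an
intervention.

## Scenarios

Eleven declarative overlays on the base configuration (never code
branches): 15- and 48-month horizons, immediate waning, alternative baseline
FSS mean/SD, delivery-specific CBT effects, the earliest-LT evidence set
with its adjusted LT timing, forced-zero ST for the no-ST-evidence
strategies, low and high cost bounds, and 1.5%/6% discount rates. An
override path that does not exist in the base config is an error naming the
path, so a typo cannot silently run the base case. The runner flags any
strategy whose INMB sign differs from base case.

# The synthetic data world

Nothing proprietary ships with the package, so `reference_fixture()`
generates every input with known ground truth: seven strategies (three
categories × two delivery modes + usual care), multivariate-normal
"posterior" draws with cross-timepoint correlation ρ = 0.7 (real
NMA posteriors are approximately normal on the SMD scale and strongly
correlated across follow-ups; the true ρ is unreported, so it is a knob),
follow-up schedules, and uniform-range study cost records. Its stated
conditions mirror the structure of the real evidence base: mindfulness has
no ST evidence and a wide LT SD (single-study), group mindfulness costs come
from one study (exercising the 25% SE rule), CBT is the most
delivery-intensive and its 2017-priced records exercise the uplift path, and
SMD magnitudes (≈ −0.3 to −0.65) are typical of these interventions.
Expected QALYs at the generating parameters are stored from the closed-form
integrator, so the trapezoid engine is always checked against an
independent oracle.

What a green test therefore establishes: the *machinery* — conversion,
trajectories, integration, costing, sampling, decision metrics — is correct
on inputs with this structure. What it does not establish: any empirical
claim about the real interventions; the fixture's INMBs, CEAC shares and
scenario flips are properties of the synthetic world (its base-case INMBs
are positive at λ = £20 000 by design of the stated magnitudes, and its
high-cost individual CBT strategy happens to flip sign under the adverse
overlays, which usefully exercises the flag).

# Numerical choices and limitations

Quadrature step 0.25 month (halving it moves results by < 10⁻⁵ QALYs);
truncation by resampling with a 1000-round cap; degenerate SEs (zero)
short-circuit to constants rather than sampling; the immediate-return knot
offset is 10⁻⁶ months; ICERs in the cheaper-and-worse quadrant are labelled
`"southwest"` rather than reported as ratios. The model deliberately omits
mortality, adverse events, condition-specific progression, half-cycle
corrections (it is not a Markov cohort model), downstream resource use, and
any re-estimation of the mapping regression; the fully incremental frontier
across all seven options is not computed (versus-usual-care comparisons plus
the multiway CEAC are). QALY results are only as good as the placeholder
mapping until real coefficients are configured.
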