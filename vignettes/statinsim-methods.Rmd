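---
title: "Methods: microsimulation of statin initiation thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsimulation of statin initiation thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statinsim)
```

## The decision problem

Chinese dyslipidemia guidelines start moderate-intensity statins for primary
prevention when an adult's 10-year atherosclerotic cardiovascular disease
(ASCVD) risk reaches 10%. Statins prevent coronary heart disease (CHD) and
stroke but modestly raise the risk of incident type 2 diabetes, and treating
at lower risk thresholds treats many more people. `statinsim` simulates
individual life courses under four initiation rules — no treatment, and
10-year-risk thresholds of 15%, 10% and 7.5% — and compares them by
discounted lifetime cost per quality-adjusted life year (QALY) on the
cost-effectiveness frontier, from the healthcare-system perspective in
2022 CN¥.

## Model structure

The engine is an individual-level state-transition model in annual cycles.
Each simulated adult starts ASCVD-free between ages 45 and 89 and is
followed until death or the end of the cycle in which they are 89 (the age
cap reflects the sparsity of the 90+ population). Health states are
event-free, post-CHD, post-stroke and dead (absorbing); treatment states
are never-treated, on-statin and discontinued (absorbing).

Within every cycle the engine executes a fixed, documented order:

1. **Screening and initiation.** Untreated, event-free individuals whose
   current 10-year risk is at or above the strategy threshold (inclusive
   `>=`; an epsilon of 1e-9 keeps exact ties eligible despite floating
   point) start statins. Screening repeats every cycle because risk factors
   drift with age.
2. **Annual ASCVD probability.** The Cox-form risk equation gives a 10-year
   composite risk, converted to a one-year probability by the
   constant-hazard DEALE transform `p1 = 1 - (1 - p10)^(1/10)`. The
   composite splits into CHD (29.46%) and stroke (70.54%) shares; for
   on-statin individuals each share is adjusted on the odds scale
   (odds ratios 0.70 for CHD, 0.81 for stroke — odds, not risk, because
   that is how the effects are tabulated).
3. **Event draw.** One composite event at most per cycle; its type follows
   the (treatment-conditional) CHD share; fatality is a table lookup by
   event type, sex and 10-year age band (85–89 reuses the 75–84 band, a
   conservative extension).
4. **Diabetes onset.** Non-diabetic survivors face an age-banded annual
   incidence, inflated on the odds scale by 1.21 while on statins. An onset
   counts as *statin-induced* only when its uniform draw falls in the
   excess band `[p_base, p_adjusted)` — onsets that would also have
   occurred untreated are natural, and a statin-induced diabetic keeps
   facing natural onsets at the base rate (a later natural onset
   supersedes the attribution, ending the excess person-years).
   Statin-induced diabetes carries the (configurable, default 0) diabetes
   cost and utility decrement but never feeds back into ASCVD risk: the
   risk equation's diabetes covariate reads the natural flag only, which
   makes the diabetes odds ratio provably inert for ASCVD outcomes — the
   contract that its harms act through quality of life and cost alone.
5. **Background mortality.** An all-cause annual probability by age and
   sex, doubled (configurable multiplier, default exactly 2.0) for
   individuals who entered the cycle in a post-event state. Survivors of an
   event *this* cycle face the base rate; the doubling starts the following
   cycle.
6. **Accrual.** Costs: annual statin cost (1,149.75) while on statins;
   hospitalization in the event cycle (AMI 22,611, stroke 13,983);
   first-year post-event care (5,255.85 / 2,652) in the first post-event
   year; one office visit per year thereafter (585.87 / 565). A cycle
   ending in death accrues only the event hospitalization. Utilities: the
   age-specific weight minus additive decrements floored at zero — acute
   (CHD 0.439, stroke 0.92) in the event cycle only, long-term (AMI 0.107,
   stroke 0.266) in every later post-event cycle. Decrements are additive
   rather than multiplicative because they are tabulated as negative
   utility weights; the near-total acute stroke decrement then sensibly
   wipes out the event-year utility. A death cycle contributes no utility.
7. **Progression.** Risk factors drift linearly, age increments, and
   initiators finishing their first treated year face a one-off 40%
   discontinuation draw.

Costs and QALYs are discounted at a single annual rate (default 3%),
`value / 1.03^t` with cycle 0 undiscounted. Recurrent ASCVD events are not
modelled by default: the risk equation is a primary-prevention equation, so
after a first non-fatal event an individual faces doubled background
mortality, post-event costs and disutility, and no further equation-driven
events. A `allow_recurrence` switch re-exposes post-event survivors to the
same annual hazard (decrements never stack beyond the larger one); it
defaults off. There is no half-cycle correction.

## Treatment model

Eligibility ties are inclusive, screening is annual, and the guideline
strategy defaults to a pure 10% threshold; direct-initiation predicates
(e.g. very high LDL-C) can be attached to any strategy but default off.
Discontinuation is evaluated once, at the end of the first treated cycle,
so every initiator pays and benefits for one full year; survivors of the
draw adhere for life. Discontinuation is absorbing — no re-initiation at a
later age, no residual ("legacy") treatment effect, no further statin cost.
Individuals with a prior event are outside the primary-prevention strategy
altogether.

## The risk equation and its coefficients

Ten-year risk is `1 - S0^exp(LP - mean_lp)` with a per-sex linear predictor
over named covariates (age, treated/untreated SBP, TC, HDL-C, LDL-C, waist
circumference, smoking, diabetes — the engine computes any covariate a
coefficient file declares). The packaged coefficient file
(`risk_coefficients_synthetic.json`) is *synthetic*: it has the equation's
form and plausible effect sizes for a Chinese population, because the
published equation's coefficients are not redistributed with this package.
Every analysis function accepts a replacement file via
`load_risk_coefficients()`, and all unit tests use small toy coefficient
sets so correctness never depends on any particular transcription.

## Synthetic data: what it emulates and what it does not

The cohort generator stands in for restricted national-survey microdata.
It reproduces per-sex marginal means and spreads of the five continuous
risk factors, binary prevalences (smoking, diabetes, antihypertensive
treatment), a configurable correlation structure (default: independence,
since no joint structure is published), and linear age trends fitted
cross-sectionally (deterministic drift, residual SD 0 by default).
Defaults were chosen once as literature-plausible values for Chinese adults
aged 45+ — e.g. SBP 135/132 mmHg (men/women), TC 4.7/4.9 mmol/L, smoking
52%/5%, diabetes 12%/13% — and the baseline age range starts at 45 because
the source survey excluded younger respondents, while the engine itself
accepts ages 40–89. The generator does **not** emulate survey weights,
item nonresponse, cluster structure, or longitudinal dynamics beyond the
linear trends, and the background mortality table, diabetes incidence and
age-specific utility weights are synthetic stand-ins built in code
(Gompertz-form mortality shaped to a contemporary Chinese period life
table; a declining EQ-5D-style weight table). Passing tests therefore
demonstrate that the *mechanism* is correct under known conditions — they
do not validate the synthetic inputs against any real population, and
absolute outputs (life expectancy, eligible fractions, ICER levels) shift
with every one of these replaceable inputs.

## Numerical choices

- Continuous risk factors are floored (HDL-C at 0.3 mmol/L, SBP at 80,
  etc.) so 40+ cycles of linear drift cannot drive the risk equation to
  impossible values.
- Rate tables are looked up by band; queries outside the covered range
  reuse the nearest band.
- All randomness is consumed as fixed-length uniform vectors indexed by
  (individual, cycle, purpose) from one seeded stream, so identical seeds
  give common random numbers (CRN) across strategies — incremental
  comparisons are variance-reduced by construction, and two strategies with
  identical rules produce bit-identical results.
- The cost-effectiveness ladder removes dominated strategies (no cheaper,
  no less effective competitor), then iteratively removes
  extended-dominated ones until step ICERs are nondecreasing. On *rounded*
  published aggregates two arms can tie on QALYs, in which case the
  cheaper arm survives; exact published ICERs are not reproducible from
  rounded tables and are never asserted.
- Probability sampling for PSA: beta and gamma by method of moments from
  (mean, SE); odds ratios lognormal with `sigma = SE/mean` (delta method)
  and the log-mean set so the distribution's mean equals the point value.
  The diabetes odds ratio is tabulated with a "Beta" family and no SE,
  which is not implementable as printed; it is held fixed in PSA by
  default, with a lognormal override available. Families that need an SE
  but lack one fall back to fixed with a warning.
- PSA holds the simulation seed fixed across draws and strategies: curves
  reflect parameter uncertainty only, and all-fixed specifications
  reproduce the deterministic base case exactly.
- One-way ranges default to value ± 1.96·SE clipped to the family support,
  or ±20% where no SE is tabulated.

## Problem sizes in the shipped workflow

The analysis drivers use 10,000 individuals for the base case (the study's
cohort size), a 1,000-person subcohort with 200 draws for PSA and the
tornado (frontier orderings and acceptability curves stabilise well below
the base-case size under CRN), 10,000 individuals for validation, and
100,000 identical individuals where the engine is checked against a
deterministic cohort-Markov recursion. The internal-validity statistic is
the least-squares R² of simulated first-cycle event frequencies on
analytic one-year probabilities across sex × 10-year-age groups in the
untreated arm.

## Known limitations

Beyond the synthetic stand-ins above: no secondary-prevention treatment,
no high-intensity statins, no diabetes complications (statin-induced
diabetes is assumed well controlled), no societal costs or equity
weighting, no recurrence by default, and cause-of-death attribution no
finer than ASCVD vs background. The printed currency labels in the source
material mix years and symbols; all computations here are in CN¥ with the
2022 GDP-per-capita thresholds (85,700 and 257,100 CN¥/QALY).
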