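---
title: "A dynamic energy-balance model of weight loss on very low-energy diets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamic energy-balance model of weight loss on very low-energy diets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebloss)
```

## The model

The clinical "3500-kcal rule" — a 500 kcal/d deficit loses about 1 lb
(0.45 kg) per week — treats energy expenditure as fixed. In reality
expenditure falls as weight is lost, in two ways: *obligatory* reductions
from the loss of metabolically active fat-free mass (FFM), and *adaptive
thermogenesis* (AT), the underfeeding-associated fall in resting energy
expenditure (REE) beyond what tissue loss explains. Ignoring both
overestimates weight loss substantially on very low-energy diets.

`ebloss` implements a single-state ordinary differential equation in body
weight $w(t)$ (kg):

$$\frac{dw}{dt} \;=\; \frac{EI(t) - TEE(w)}{\rho},
  \qquad \rho = 7700\ \text{kcal/kg},$$

with total energy expenditure split into AT-adjusted resting expenditure,
physical activity and diet-induced thermogenesis (DIT):

$$TEE(w) = PAL \times \big(REE(FFM(w)) - AT(w)\big) + \beta\, EI(t).$$

AT adjusts REE *before* the physical-activity-level (PAL) product is
taken, so activity expenditure scales with the adapted resting rate. PAL
defaults to 1.6 (moderately active); $\beta$, the DIT coefficient,
defaults to 0.05 (overweight/obese populations; 0.10 is typical for lean
subjects).

### Body composition

Baseline FFM is predicted from a linear construction anchored at a lean
reference subject: a lean female of 60 kg with 72% FFM (85% at 70 kg for
males), with every kg of excess weight carrying 25% FFM and 75% fat mass.
These lean-reference anchors are configuration fields
(`lean_ref_weight_*`, `lean_ref_ffm_frac_*`) rather than constants, since
they are literature-derived calibration points a user may wish to replace;
the linear construction itself is the contract.

During restriction the FFM *fraction* of remaining weight rises from its
baseline value $c$ and stabilises 10 percentage points higher. Two forms
are provided, keyed by the relative weight loss $x = (w_0 - w)/w_0$
(always measured against the pre-intervention weight, never re-based):

* **original** — an exponential rise saturating at $x = 0.10$, paired with
  the Cunningham equation $REE = 500 + 22\,FFM$;
* **refined** — a linear rise $c + 0.10\,(x/0.20)$ saturating at
  $x = 0.20$, paired with the FFM-based Mifflin form
  $REE = 413 + 19.7\,FFM$.

AT rises exponentially from zero and saturates at 15% of REE at
$x = 0.10$ in both variants.

### The exponential rise

The saturating-exponential pieces are implemented as

$$f(x) \;=\; f_{sat}\,
  \frac{1 - e^{-kx}}{1 - e^{-k\,x_{sat}}},\qquad
  k = \frac{-\log(1 - 0.99)}{x_{sat}},$$

i.e. the unnormalised curve reaches 99% of saturation at the threshold and
the normalisation pins both anchors exactly: $f(0) = 0$,
$f(x_{sat}) = f_{sat}$, constant beyond. This keeps the trajectories
continuous and monotone regardless of shape, and the anchors — which carry
all the quantitative content (baseline value, saturated value, threshold)
— exact. The 0.99 approach fraction is exposed as
`exp_saturation_frac` for sensitivity analysis.

## Integration and numerical choices

`simulate_weight()` integrates with `deSolve::ode` (lsoda, default
tolerances `1e-8`), restarting the integration at every intake-schedule
discontinuity so the step in prescribed intake never sits inside an
adaptive step. Output is a daily grid; weekly weigh-ins are read at days
7, 14, ... (end-of-week convention). End-weights are stable to well under
1 g across solver tolerances spanning two orders of magnitude, and agree
with an independent fixed-step Euler integration (dt = 0.01 d) to a
fraction of a gram over 12 weeks.

Intake steps use the half-open convention: a schedule switching in week
10 prescribes the old level on days [0, 70) and the new level from day 70.
The stated prescription ("<10 weeks: 800 kcal/d; >10 weeks: 1200 kcal/d")
leaves exactly 10 weeks undefined; the half-open choice matches the
motivation that food reintroduction begins *from* week 10.

Energy bookkeeping closes: the integral of the daily deficit equals
7700 kcal per kg lost to about $10^{-5}$ relative (`energy_closure()`;
the continuous expenditure part is integrated by trapezoid, the piecewise
constant intake/DIT parts exactly).

Degenerate inputs: weight gain ($x < 0$) is outside model scope and
rejected by the pure functions (the solver clamps sub-nanogram overshoot
at baseline); a weight reaching zero raises a simulation-diverged error
naming the day. No lower weight floor is imposed, but a trajectory whose
FFM falls below the lean-reference FFM emits a warning, since predictions
there extrapolate the composition model.

## The static comparator

`static_prediction(deficit, weeks)` implements the pound-based rule
exactly: $deficit \times 7 \times weeks / 3500 \times 0.45359237$ kg.
Because the dynamic model's deficit shrinks as expenditure adapts, the
dynamic prediction is below the static one for every subject on a grid of
starting weights 70–130 kg, deficits 300–1500 kcal/d and durations 6–12
weeks (verified exhaustively in the test suite).

## Evaluation statistics

`mean_error_delta()` is the primary accuracy metric,
$\delta = (actual - predicted)/actual \times 100$, positive when the
model under-predicts end-weight (over-predicts loss).
`cohort_error_summary()` and `weekly_error_profile()` aggregate per
subject-week with sample SD (n − 1): the convention for cohort
"mean (SD)" reporting. Subjects lacking a requested week are excluded
listwise — weekly n declines with attrition, never imputed.
`bland_altman()` returns bias = mean(actual − predicted loss) and limits
of agreement at bias ± 2 SD (the field's plotting convention here;
± 1.96 SD is available via `loa_mult`).

## The synthetic cohort

No public dataset of this kind exists (commercial weight-loss records are
proprietary), so `generate_cohort()` produces cohorts with the same
statistical structure for pipeline testing: female subjects, baseline
weight truncated-Normal(93.31, 19.18) kg, 6–12-week enrolments, weekly
weigh-ins at a stepped 800/1200 kcal/d prescription. Two systematic
phenomena the energy model deliberately does not capture are overlaid on
the latent model trajectory:

* **Glycogen-water loss** — early depletion of glycogen and its bound
  water (stored ~1:3 g) produces 1.5–2.0 kg of extra observed loss within
  the first 7–10 days. It is water, not an energy store, so it is modelled
  as an observed-weight offset $-b\,(1 - 2^{-t/h})$ (bolus $b$ uniform in
  1.5–2.0 kg, half-life $h$ = 5 d), zero at baseline and essentially spent
  by day 10 — not as a change to the energy model.
* **Compliance drift** — longer enrolments relax adherence; from week 8
  subjects consume +200 kcal/d above prescription. The magnitude is a
  fixture parameter, not an estimate: its role is to produce the
  qualitative late-intervention sign change in the weekly error profile.

Remaining defaults chosen once as field-realistic: weigh-in noise SD
0.3 kg (weekly scale repeatability in street clothes); truncation floor
45 kg (a plausibility guard cutting < 0.6% of the weight distribution, so
the realised cohort mean stays within ~0.3 kg of the target); enrolment
lengths over 6–12 weeks with mode at 8 weeks and smallest mass at 12
(mean 8.8 weeks), matching the reported enrolment pattern. Everything is
reproducible from `seed`.

With all perturbations at zero the generator and predictor traverse the
same code path on the same schedule object, so the simulate → evaluate
round trip returns $\delta \equiv 0$ identically — a strong pipeline
identity. With defaults, the weekly $\delta$ is negative in weeks 1–3
(the water bolus makes observed loss outrun the model) and rises by week
12 (compliance drift pulls it back) — the qualitative shape seen in real
programme data, in sign and ordering only.

What passing these tests does **not** show: that the model is accurate on
real clients. The synthetic truth *is* the model plus hand-chosen
perturbations; real cohorts add reporting error in intake, between-subject
variation in adaptive thermogenesis ("thrifty" vs "spendthrift"
phenotypes), delayed AT onset, and non-linear REE–FFM relationships in
severe obesity, none of which are emulated.

## Problem sizes

The shipped test-suite and acceptance-script runs use a 12-week reference
simulation (daily grid, Euler oracle at dt = 0.01 d), a 245-cell
dynamic-vs-static grid, a noise-free cohort of n = 100 and a default
cohort of n = 500 — sizes at which every statistic above is stable to the
tolerances tested while the whole suite runs in well under a minute.

## Known limitations

* Single-compartment state: FFM is an algebraic function of weight, not a
  separately integrated store; no weight regain or maintenance phase.
* The female lean-reference anchor is exercised against synthetic data
  shaped like the validation cohort; the male anchors are provided but
  untested against any data.
* AT is assumed to respond immediately to the deficit; evidence suggests
  onset over weeks in some subjects.
* PAL is a self-reported constant; activity changes during the diet are
  not modelled.
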