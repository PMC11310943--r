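---
title: "Methods: a decision tree + Markov cohort model for LDCT lung cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a decision tree + Markov cohort model for LDCT lung cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcsmodel)
```

## The question and the model class

Low-dose CT screening shifts lung cancer detection toward stage I, where
treatment is curative and cheap relative to metastatic disease. Whether a
national programme is worth its scanning bill is a classic
cost-effectiveness question, and the standard machinery is the one this
package implements: a decision tree that sorts incident cancers into
detection pathways, feeding a stage-stratified state-transition (Markov)
cohort model that accumulates discounted life years, QALYs and costs per
arm. Everything is deterministic person-mass propagation; a
microsimulation oracle exists only to validate the cohort engine.

## Decision tree

* **Eligibility.** `round(total_population × frac_aged_50_74) × smoking_rate`,
  rounded at each reported step. With the shipped base case this gives
  2,893,011 people aged 50–74 and 600,589 eligible (the published audit
  value, 600,555, comes from unrounded inputs; the two agree to 6e-5).
* **Participation.** `floor(eligible × uptake)`; base-case uptake 50%,
  adherence 100% per attended round (adherence applies independently each
  round).
* **Incidence.** Cancers arise in the participant cohort at an annual rate
  `annual_incidence_eligible × risk_concentration` (0.45%/yr × 2.0 =
  0.9%/yr), with the at-risk mass depleted by prior diagnosis and
  background mortality over the whole 42-year horizon. The concentration
  factor encodes that the screened group is the high-risk slice of the
  eligible population; 0.9%/yr matches detection rates observed in the
  large LDCT trials and reproduces the scale of published programme-level
  diagnosis totals. This is a stated-world choice made once; the share and
  ratio calibration targets are insensitive to it, the absolute ICER is
  not.
* **Detection.** A cancer arising in year *y* is screen-detectable at each
  attended round during its pre-clinical sojourn (`clinical_delay_years`,
  default 2) with `detection_prob_per_round` (default 0.9). Undetected
  cancers present clinically after the sojourn. Screening participants
  remain inside the surveillance system, so every screening-arm cancer is
  eventually diagnosed; "missed individuals" — cancers never diagnosed —
  exist only in the no-screening arm, where `clinical_detection_fraction`
  (0.666) of cancers present clinically and the rest stay pre-clinical.
  That definition fixes the screening/no-screening diagnosis ratio at
  1/0.666 ≈ 1.50, matching the published arm totals.
* **Stage.** Screen-detected cancers take the calibrated screen-detected
  stage distribution; clinical presenters take the registry distribution
  (16.3/7.8/27.7/48.2%).

## Synthetic screening outcomes and calibration

The trial-level screening performance inputs are not public, so
`make_screening_outcomes()` ships a synthetic, clearly labelled stand-in.
Calibration (`calibrate_screening_outcomes()`) solves the linear mixing
identity

\[ \text{target share} = f_{screen}\,s + (1 - f_{screen})\,\text{clinical} \]

for the screen-detected distribution \(s\), where \(f_{screen}\) (the
screen-detected fraction of screening-arm diagnoses) does not depend on
\(s\) — one pass is exact. Against targets of 51/7/20/22% this yields the
frozen default \(s \approx (0.630, 0.067, 0.173, 0.130)\). False-positive
(1.3%/screen, billed a full diagnostic work-up) and indeterminate rates
(2.0%/screen, billed a repeat LDCT) are NELSON-order magnitudes, not trial
values. A green calibration test therefore establishes that the pipeline
reproduces the published stage shift and diagnosis ratio — not that the
synthetic screen model equals the trial's.

## Survival

Each stage's OS is an exponential through its published 5-year anchor and
each stage's D/PFS an exponential through its 1-year anchor — with one
anchor per endpoint the exponential is the only identifiable family.
`fit_curve()` also supports Weibull, log-normal, log-logistic and Gompertz
fits (least squares on the log-cumulative-hazard scale, AIC selection under
an anchors−1 parameter cap) for richer inputs.

Transitions over a cycle \([t, t+\Delta]\):

* death from either living state: interval OS hazard plus the
  `bg_mult`-scaled Gompertz–Makeham background hazard, additively; the
  cause-of-death split is proportional to the hazard components, and only
  lung cancer deaths trigger end-of-life costs;
* pre → post: the excess hazard \(\max(h_{DPFS} - h_{OS}, 0)\) applied to
  cycle survivors (the literal "D/PFS minus OS" subtraction is negative;
  the alive-with-progression mass \(S_{OS} - S_{DPFS}\) is the
  sign-consistent reading);
* both living states die at the **stratum's own** OS hazard, so total
  survival reproduces the fitted OS curve exactly (progression switches
  utility and triggers second-line cost, not the death rate). Setting
  `settings$post_progression_mortality = "stage_iv"` switches to stage-IV
  post-progression mortality instead.

Missed individuals follow the stage-II OS curve (never treated, no
progression state) and carry age-specific population utilities.

## Economics

Discounting is `1/(1+r)^t` (5%/yr for costs and health), anchored at
programme start for programme costs (CT scans at their round year,
diagnostic work-up at the event year) and at each stratum's diagnosis year
for patient streams. Patients are booked **from diagnosis** (missed
individuals from presumed presentation); pre-diagnosis person-time is booked
in neither arm, mirroring the published accounting in which per-person
stage outcomes are arm-invariant. The residual lead-time asymmetry — a
screen-detected patient's stream starts earlier on the same from-diagnosis
survival curve — is inherent to anchor-based stage-shift models and is the
main structural caveat for interpreting the QALY gain.

Treatment billing per stage: the first-3-months block per person entering;
the rest of year 1 (split over cycles 1–3) and year 2 (cycles 4–7) per
alive pre-progression person-cycle; aftercare (CT + specialist consult)
every 6 months through year 2, annually thereafter; second-line treatment
once per progression event; end-of-life care once per lung cancer death.
People who never develop cancer accrue population-utility QALYs under
background mortality, identically in both arms.

## Sensitivity machinery

* **Tornado (`one_way`).** Full reruns at ±20%. The default lever set is
  the cost and utility parameters: demographic/epidemiological inputs
  rescale the modelled population in both arms (the incidence span would
  otherwise mechanically top the chart — true of the published incremental
  arithmetic as well) and are instead explored as scenarios. Dirichlet
  members are perturbed with proportional renormalisation of the siblings.
* **PSA (`sample_psa`).** Beta/gamma moment-matched to `(mean, se)` with
  the default `se = 0.2 × mean` (chosen once to match the ±20% one-way
  span; the published spreads are not public), Dirichlet concentrations
  `100 × share`. Probabilistic ICER is the ratio of means.
* **Scenarios.** `table3_scenarios()` covers horizons (accumulation
  truncated, transitions unchanged), discount rates, round counts, uptake,
  adherence, smoking rates, CT prices, a per-participant smoking-cessation
  cost, false-positive/indeterminate disutilities (one-time, one-year
  decrement per affected screen), an immunotherapy utilisation uplift
  (cost share 0.3 on late-stage first-line costs in both arms, survival
  gain 0.1 per unit uplift), and doubled background mortality.

## Numerical choices

3-month cycles, start-of-cycle occupancy accumulation without half-cycle
correction (flag available; the rectangle rule's O(Δ) offset is ~3% for the
stage-IV hazard and <1% elsewhere), extinction cutoff 1e-9, background
hazard capped at 50/yr where q = 1, horizon 42 years (entry age 58 to the
life-table tail). Person mass is continuous everywhere; rounding happens
only in reports (persons and EUR to integers, ratios to 2 decimals).

## What green tests do and do not establish

The test suite verifies closed-form identities on the published tables,
engine-vs-oracle agreement, conservation/monotonicity invariants, exact
null-intervention and degenerate-PSA identities, and the calibration bands
(stage-I share 0.49–0.53, diagnosis ratio 1.45–1.55, ICER within a
15,000–35,000 EUR/QALY sanity band). They do not establish reproduction of
the published headline ICER (24,627), which depends on non-public screening
and survival-fit inputs, nor external validity of the synthetic screening
model, the exponential extrapolation, or the lead-time handling.
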