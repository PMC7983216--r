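---
title: "Knowledge-based plan scoring, DVH prediction and model evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-based plan scoring, DVH prediction and model evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbplanr)
```

## Scope and model of the problem

`kbplanr` implements the analysis pipeline of knowledge-based VMAT planning
(KBP) research for pelvic (cervical cancer) radiotherapy: dose-volume
histogram (DVH) metrics and conformity/homogeneity indices, a 100-point plan
quality metric (PQM), a trainable geometry-to-DVH prediction model with
estimate bands, a closed-loop model-evolution procedure, a rank-based
model-comparison score, and a synthetic cohort generator that stands in for
clinical data. It does not perform fluence or arc optimization, parse
DICOM-RT, or make any clinical claim: plans enter as cumulative DVH curves
through a JSON/CSV interchange format.

## DVH representation and metrics

The canonical representation is the cumulative DVH: for structure volume
$V$ (cc), $v(D)$ is the fraction of the structure receiving at least dose
$D$ (Gy). Curves are stored on a strictly increasing grid starting at 0 Gy
with $v(0) = 1$, $v$ non-increasing in $[0,1]$; interpolation is linear in
both axes everywhere, and differential quantities (the mean dose) are
obtained from the cumulative curve by the trapezoid rule. The scalar
endpoints are the clinical family $D_{x\%}$, $V_{x\,\mathrm{Gy}}$
(reported in percent), $D_{x\,\mathrm{cc}}$, $D_\mathrm{mean}$ and
$D_\mathrm{min}$. Two conventions deserve note:

* $D_\mathrm{min}$ is the exact end of the full-coverage plateau (largest
  dose with $v \ge 1 - 10^{-6}$), not a near-minimum percentile.
* $D_{x\%}$ at $x = 100$ returns the largest dose with
  $v \ge 1 - 10^{-9}$, so rectangular curves behave continuously.

The conformity index is
$\mathrm{CI} = (V_\mathrm{Tref}/V_\mathrm{T})\,(V_\mathrm{Tref}/V_\mathrm{ref})$,
the product of target coverage and selectivity, and the homogeneity index is
$\mathrm{HI} = (D_{2\%} - D_{98\%})/D_{50\%}$. The reference isodose for CI
is a single configurable fraction of the prescription applied to both
$V_\mathrm{Tref}$ and $V_\mathrm{ref}$, default 0.95 (the conventional
choice when a protocol quotes "the 95% isodose" as its reference; sources
that mix 95% and 98% exist, so the fraction is an explicit parameter, not a
constant).

## The 100-point plan quality metric

`default_criteria()` encodes 19 criteria over the two targets (PGTVnd,
60 Gy in 25 fractions; PCTV, 45 Gy) and seven organs at risk, with maxima
summing to exactly 100. Threshold criteria follow a two-level scheme with
linear interpolation: values on the worse side of the *acceptable* level
score 0 (hard step), the acceptable level is worth exactly 60% of the
criterion's points, and the score rises linearly to full points at the
*excellent* level. This 60% anchor is visible in every printed
"acceptable/maximum" pair of the criteria table (4.8/8, 6/10, 3/5, 1.8/3,
1.2/2), and the linear segment is pinned by published value-score pairs
(e.g. a target $V_{60\,\mathrm{Gy}}$ of 99.40% scoring
$4.8 + 3.2\,(99.40-97)/3 = 7.36$ of 8). Conformity and homogeneity are
scored linearly as $p \cdot \mathrm{CI}$ and $p \cdot (1-\mathrm{HI})$,
clipped to $[0, p]$ — again matching all published pairs
(CI 0.84 → 1.68, HI 0.05 → 1.90, and so on). The hard step below the
acceptable level (rather than linear extrapolation) is the reading most
consistent with published mean scores of endpoint distributions that
straddle the acceptable level; it is configurable by editing the criteria
set.

## The DVH prediction model

The commercial estimation engine the methodology was developed around is
proprietary; `kbplanr` implements a transparent principal-component
regression in the same spirit. Per organ at risk (OAR):

1. all training DVHs are resampled onto a common grid (default 0–75 Gy in
   0.05 Gy steps — fine enough that grid error is far below every tolerance
   used here);
2. the mean-centered curves are decomposed by PCA, keeping $k$ modes
   (default 4);
3. a ridge regression (penalty $10^{-3}$ on standardized features) maps
   geometry features to mode scores. The feature basis is $f$ (overlap
   fraction of the OAR with the high-dose envelope), $\log\tau$ (dose
   fall-off scale, Gy), $(\log\tau)^2$, $f\log\tau$, $\log V_\mathrm{organ}$
   and $\log V_\mathrm{target}$.

The quadratic and interaction terms, and $k = 4$, are deliberate: the
synthetic DVH family is nonlinear in $\log\tau$, and with a purely linear
basis at $k = 3$ the held-out reconstruction error plateaus around
0.01–0.013 (max pointwise volume-fraction error), right at the package's own
recovery requirement; the enriched basis brings it to ~0.003 with no
stability cost at $n \ge 25$. Features with zero variance in a training set
(e.g. the overlap fraction of a never-overlapping organ) are dropped with a
warning.

Prediction reverses the chain: mean curve plus regressed modes, clipped to
$[0,1]$ and re-monotonized by a running minimum from dose 0 (the
minimal-distortion projection onto valid DVHs). The estimate band is the
prediction $\pm z$ times the residual projection
$\sqrt{\sum_m s_m^2 P_m(D)^2}$, where $s_m$ is the per-mode RMS training
residual (a Gaussian-style band, stable at small $n$; empirical quantiles
would need more data). The *lower* band is the optimistic edge and supplies
the organ-sparing optimization objectives
(`objectives_from_estimate()`), mirroring how KBP systems set objectives
from the lower bound of the estimate range.

## Synthetic cohort: what it emulates, and what it does not

Clinical DVH databases of this kind are not publicly deposited, so the
package generates its own study world. Per patient:

* anatomy per OAR is summarized by $(f, \tau, V)$: overlap fraction, dose
  fall-off scale and volume, drawn from priors chosen to caricature pelvic
  anatomy (bladder/rectum $f \sim 0.6\,\mathrm{Beta}(4,4)$, femoral heads
  $f \sim 0.2\,\mathrm{Beta}(2,8)$, kidneys essentially no overlap, spinal
  cord none; $\tau$ log-normal per organ, e.g. small for cord and kidneys);
* the *achievable* (best-effort) OAR DVH is
  $v(D) = f\,T(D) + (1-f)\,e^{-D/\tau}$, with $T$ the near-rectangular
  target-region curve (half-width $h = 3\%$ of prescription, which puts
  synthetic target HI at ≈ 0.05, the clinically printed magnitude);
* target structure curves are near-rectangular with the plateau centered
  slightly above prescription, giving realistic ~98–99% coverage at the
  prescription dose; the body curve is the volume-weighted mix of the target
  curves plus an exponential background chosen so conformity indices land in
  the clinically printed 0.5–0.85 range;
* planner skill is one excess-dose parameter $\varepsilon \ge 0$
  (half-normal, scale 0.08): the planned OAR curve is the achievable curve
  dilated along the dose axis by $1+\varepsilon$, targets untouched. This
  single knob strictly orders plan quality, which makes the
  flag/re-optimize/gate semantics exact and testable.

What the world does *not* have: voxel anatomy, target-coverage trade-offs,
correlated multi-organ difficulty, beam or machine effects, or the heavy
tail structure of real near-maximum doses (the exponential tail makes
femoral-head $D_{0.03\,\mathrm{cc}}$ pessimistic, so that criterion scores
low in synthetic cohorts). Passing tests therefore demonstrate the
*mechanics* of the pipeline — scoring arithmetic, estimator consistency,
closed-loop behavior — not clinical performance.

## Closed-loop model evolution

`run_evolution()` reproduces the refinement trajectory: model C0 is trained
on 25 plans; round 1 is pure closed-loop repair (plans whose endpoint
exceeds their prediction by more than a margin are re-optimized under the
model's guidance, then the model is retrained as C1); rounds 2–6 each admit
15 new plans through a self-checking gate before retraining, producing
database sizes 25, 25, 40, 55, 70, 85, 100 for C0–C6. Design choices made
where the procedure's description leaves room:

* **Suboptimality margin.** No numeric criterion for "relatively
  suboptimal" is published. Default: 0.9 Gy for dose endpoints (2% of the
  45 Gy prescription) and 2 percentage points for volume endpoints — small
  but noise-tolerant, and configurable.
* **Additions per round.** 15 per round is the unique uniform schedule
  reaching 25 → 100 in five adding rounds.
* **Re-optimization surrogate.** Synthetic plans shrink
  $\varepsilon \leftarrow \rho\,\varepsilon$ (default $\rho = 0.5$, at most
  8 iterations) until every OAR endpoint is at or below its predicted
  value; the result is never worse than the input on any endpoint. Real
  plans would need a treatment planning system; the operation refuses them.
* **Gate bar.** The gate accepts a candidate when every OAR endpoint is at
  or below the estimate's *upper band* (`gate_z = 1`), ties accepted.
  Gating strictly at the predicted curve (`gate_z = 0`) is available but
  makes the loop self-extinguishing: once the model tracks the achievable
  frontier, a candidate would have to beat an approximately unbiased
  prediction on all seven endpoints simultaneously (probability near
  $0.5^7$), and the candidate stream dries up. Because the estimate is a
  range — its lower edge is already the optimization objective — "superior
  to the prediction" is read against the range's upper edge. With zero
  residuals the two rules coincide.
* **Candidate supply.** Rejection is expected, so adding rounds consume the
  candidate stream until the quota is accepted (with a cap, after which a
  configuration error names the round).
* **Database quality.** Re-optimization can only improve a retained plan,
  so each plan's PQM is non-decreasing across rounds; the database *mean*
  PQM can still dip slightly when newly admitted patients have intrinsically
  harder anatomy, which is why the monotonicity test is per-plan.

The evolution trace records, per model, the database size, the mean database
PQM, and the mean absolute endpoint prediction error on a fixed evaluation
cohort whose reference plans are best-effort ($\varepsilon = 0$), playing
the role of the clinically approved reference plans.

## Rank-based model comparison

For each evaluation patient and OAR, the absolute error between each
model's predicted endpoint and the reference value is ranked from smallest
to largest; with $M$ models the best receives $M$ points down to 1 for the
worst, and tied errors share the average of the points they span (the
standard convention, which preserves the per-patient total
$M(M+1)/2$). Points are then averaged over patients per model and OAR. The
endpoint per OAR defaults to the criteria-table endpoint (cord
$D_{0.03\,\mathrm{cc}}$, bladder $D_{35\%}$, rectum $D_{60\%}$, kidneys
$V_{18\,\mathrm{Gy}}$, femoral heads $V_{35\,\mathrm{Gy}}$) and is
configurable, since published comparisons only name "key dosimetric
values".

## Numerical choices and problem sizes

* Dose grid 0–75 Gy in 0.05 Gy steps for synthetic curves and model
  training (sub-0.1% metric error); unit and property tests that do not
  probe grid resolution use a 0.25 Gy grid.
* Monotonicity repair on input accepts single increasing glitches up to
  $10^{-9}$ (floating-point noise in interchange files) and rejects
  anything larger, naming the structure.
* Ties at scoring thresholds take the better bracket, as printed
  ($\ge$/$\le$); an "excellent = 100%" coverage level is an ordinary linear
  endpoint whose full score is reached exactly at 100%.
* The stochastic refinement property (C6 beating C1 on median per-OAR
  evaluation error) is established over 20 seeds of the full default
  experiment (25 → 100 plans, 35-patient evaluation cohort,
  $\sigma_\varepsilon = 0.08$); parameter recovery uses 100 training and
  25 held-out noise-free patients, requiring mean held-out max-pointwise
  curve error below 0.01 per OAR.

## Known limitations

The prediction model is a deliberately transparent stand-in, not a
reimplementation of any commercial estimator; its accuracy statements are
about the synthetic world. The planner surrogate is one-dimensional, so
re-optimization cannot trade one organ against another. The gate, margin
and band defaults are package choices where the published procedure is
qualitative; all are exposed in configuration objects, and analyses that
depend on them should state the values used.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
db <- generate_cohort(cohort_config(n_patients = 25, seed = 1))
model <- fit_kbp_model(db, kbp_config(), version_label = "C0")
est <- predict_dvh(model, db[[1]]$features, "Bladder", z = 1)
objectives_from_estimate(est, list(dose_metric("dose_at_relative_volume", 35)))
score_plan(db[[1]]$plan)$total
res <- default_evolution_experiment(seed = 1)
res$trace
```
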