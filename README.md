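# kbplanr

Tools for knowledge-based VMAT planning (KBP) research on pelvic
radiotherapy plans. Inverse VMAT planning is trial-and-error and
operator-dependent; KBP counters this by training a model on prior plans to
predict the achievable dose-volume histogram (DVH) of each organ at risk
(OAR), and using the estimate to set optimization objectives and to judge
plan quality. `kbplanr` implements that research pipeline end to end on a
synthetic pelvic cohort, so the methodology is fully exercisable without
clinical data:

* **DVH core** — cumulative DVH curves with the clinical endpoint family
  (D_x%, V_xGy, D_xcc, D_mean, D_min), the conformity index
  CI = (V_Tref/V_T)·(V_Tref/V_ref) and the homogeneity index
  HI = (D_2% − D_98%)/D_50%.
* **Plan quality metric (PQM)** — a 19-criterion, 100-point score over two
  targets (PGTVnd 60 Gy / PCTV 45 Gy in 25 fractions) and seven pelvic
  OARs. Threshold criteria award 60% of their points at the *acceptable*
  level and interpolate linearly to full points at the *excellent* level;
  CI and HI are scored as `points·CI` and `points·(1 − HI)`.
* **DVH prediction model** — per-OAR principal-component regression from
  geometry features (overlap fraction, dose fall-off scale, volumes) to DVH
  mode scores, with a ±z residual band; the band's lower edge supplies the
  organ-sparing optimization objectives.
* **Closed-loop model evolution** — C0 is trained on 25 plans; suboptimal
  database plans are flagged against their predictions and re-optimized;
  new plans enter only through a self-checking admission gate; retraining
  through C6 grows the database 25 → 40 → 55 → 70 → 85 → 100.
* **Rank-based model comparison** — per patient and OAR, models are ranked
  by absolute endpoint prediction error (best of M earns M points, ties
  averaged) and points are averaged over the cohort.
* **Synthetic cohort generator** — pelvic anatomy priors, best-effort
  (achievable) DVHs, and a single planner-skill parameter that dilates OAR
  doses, strictly ordering plan quality.

See `vignettes/kbplanr-methods.Rmd` for the model, assumptions and design
choices.

## Worked example

```r
library(kbplanr)

db <- generate_cohort(cohort_config(n_patients = 25, seed = 1))
model <- fit_kbp_model(db, kbp_config(), version_label = "C0")
#> <kbp_model> C0: trained on 25 plans, 7 OARs, 4 modes

est <- predict_dvh(model, db[[1]]$features, "Bladder", z = 1)
est
#> <dvh_estimate> Bladder (z = 1): predicted D_mean 31.09 Gy, band [30.21, 32.52] Gy

objectives_from_estimate(est, list(dose_metric("dose_at_relative_volume", 35),
                                   dose_metric("mean_dose")))
#>      endpoint objective
#> 1  D_35% (Gy)  46.36013
#> 2 D_mean (Gy)  30.21317

score_plan(db[[1]]$plan)$total
#> [1] 89.77993
```

The estimate's lower band (here bladder D_35% = 46.4 Gy, D_mean =
30.2 Gy) is what a planner would hand the optimizer as starting OAR
objectives; the PQM total (89.8 of 100) summarizes how close the plan sits
to the criteria table's excellent levels. The full evolution experiment —
`default_evolution_experiment(seed = 1)` — returns the seven models C0–C6
plus a trace of database size, database quality and per-OAR prediction
error on a fixed 35-patient evaluation cohort; the per-OAR error shrinks as
the database grows and cleans itself (e.g. bladder D_35% median error
0.74 Gy at C1 vs 0.11 Gy at C6 over 20 seeds).

A thin command-line launcher (`inst/scripts/kbplanr`) exposes the same
pipeline as subcommands `simulate`, `score`, `train`, `predict`, `evolve`
and `rank`; see `?kbp_cli`.

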