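# Small, coarse-grid closed-loop fixtures; the full-scale default experiment
# is exercised in the acceptance suite.

small_world <- function(seed, n = 10, sigma = 0.08) {
  generate_cohort(coarse_cfg(n, seed, sigma_eps = sigma))
}

test_that("suboptimality flagging honors the margin", {
  db <- small_world(501, n = 10, sigma = 0.1)
  m <- suppressWarnings(fit_kbp_model(db, coarse_kbp_cfg()))
  # infinite margin: nothing can exceed prediction + margin
  cfg_inf <- refinement_config(margin_gy = Inf, margin_pct = Inf)
  expect_length(flag_suboptimal(db, m, cfg_inf), 0)
  # zero-variance world at margin 0: plans equal predictions exactly -> not flagged
  twins <- identical_entries(6)
  mt <- suppressWarnings(fit_kbp_model(twins, coarse_kbp_cfg()))
  cfg0 <- refinement_config(margin_gy = 0, margin_pct = 0)
  expect_length(flag_suboptimal(twins, mt, cfg0), 0)
})

test_that("a single low-skill outlier is the plan flagged at the default margin", {
  entries <- small_world(502, n = 15, sigma = 0)
  bad <- plan_with_skill(entries[[4]]$patient, 0.25)
  entries[[4]]$plan <- bad
  m <- suppressWarnings(fit_kbp_model(entries, coarse_kbp_cfg()))
  cfg <- refinement_config()
  flagged <- flag_suboptimal(entries, m, cfg)
  expect_identical(flagged, bad$patient_id)
  # brute-force cross-check of the flag rule for the outlier
  predicted <- predict_endpoints(m, entries[[4]]$features)
  planned <- vapply(names(m$endpoints), function(oar)
    evaluate_metric(bad, oar, m$endpoints[[oar]]), numeric(1))
  margins <- vapply(m$endpoints, function(ep)
    if (ep$kind == "volume_at_dose") cfg$margin_pct else cfg$margin_gy,
    numeric(1))
  expect_true(any(planned > predicted + margins))
})

test_that("re-optimization shrinks the excess-dose parameter geometrically and never hurts", {
  entries <- small_world(503, n = 6, sigma = 0)
  patient <- entries[[1]]$patient
  cfg <- refinement_config(reopt_factor = 0.5)
  # already optimal: returned unchanged
  p0 <- plan_with_skill(patient, 0)
  targets <- kbplanr:::planned_endpoint_values(p0, default_oar_endpoints())
  expect_equal(reoptimize_plan(p0, targets, cfg)$epsilon, 0)
  # one halving is enough when the target sits at the epsilon = 0.05 level
  p1 <- plan_with_skill(patient, 0.1)
  mid <- kbplanr:::planned_endpoint_values(plan_with_skill(patient, 0.05),
                                           default_oar_endpoints())
  expect_equal(reoptimize_plan(p1, mid + 1e-9, cfg)$epsilon, 0.05)
  # improvement property across seeded fixtures: all endpoints lower-better
  for (seed in 504:506) {
    w <- small_world(seed, n = 4, sigma = 0.15)
    for (entry in w) {
      hard <- kbplanr:::planned_endpoint_values(
        plan_with_skill(entry$patient, 0), default_oar_endpoints())
      out <- reoptimize_plan(entry$plan, hard, cfg)
      before <- kbplanr:::planned_endpoint_values(entry$plan, default_oar_endpoints())
      after <- kbplanr:::planned_endpoint_values(out, default_oar_endpoints())
      expect_true(all(after <= before + 1e-9))
    }
  }
  # plans without a planner surrogate cannot be re-optimized
  alien <- plan_record("X", entries[[1]]$plan$curves, c(PCTV = 45), "CP")
  expect_error(reoptimize_plan(alien, targets, cfg), "surrogate")
})

test_that("the self-check gate accepts ties, rejects worse plans, and composes with re-optimization", {
  twins <- identical_entries(6)
  mt <- suppressWarnings(fit_kbp_model(twins, coarse_kbp_cfg()))
  cfg <- refinement_config()  # zero residuals: band bar equals the prediction
  expect_true(self_check_gate(twins[[1]]$plan, mt, twins[[1]]$features, cfg))
  worse <- plan_with_skill(twins[[1]]$patient, 0.05)
  worse$patient_id <- "TWIN-worse"
  expect_false(self_check_gate(worse, mt, twins[[1]]$features, cfg))
  # strict point-prediction gate (gate_z = 0) behaves identically here
  cfg0 <- refinement_config(gate_z = 0)
  expect_true(self_check_gate(twins[[1]]$plan, mt, twins[[1]]$features, cfg0))
  expect_false(self_check_gate(worse, mt, twins[[1]]$features, cfg0))
  # composition: whenever re-optimization reaches the predicted values, the
  # gate must accept (the band bar is never below the prediction)
  db <- small_world(507, n = 12, sigma = 0.12)
  m <- suppressWarnings(fit_kbp_model(db, coarse_kbp_cfg()))
  cand <- generate_cohort(coarse_cfg(6, 508, sigma_eps = 0.12))
  reached <- 0L
  for (entry in cand) {
    predicted <- predict_endpoints(m, entry$features)
    reopt <- reoptimize_plan(entry$plan, predicted, cfg)
    planned <- kbplanr:::planned_endpoint_values(reopt, m$endpoints)
    if (all(planned <= predicted + 1e-9)) {
      reached <- reached + 1L
      expect_true(self_check_gate(reopt, m, entry$features, cfg))
    }
  }
  expect_gt(reached, 0)  # the fixture exercises the successful branch
})

test_that("an empty refinement round leaves the database intact and the refit unchanged", {
  twins <- identical_entries(6)
  m <- suppressWarnings(fit_kbp_model(twins, coarse_kbp_cfg(), "C0"))
  db <- plan_database(twins, 0L)
  res <- suppressWarnings(
    run_refinement_round(db, m, list(), refinement_config(margin_gy = 0, margin_pct = 0),
                         coarse_kbp_cfg()))
  expect_length(res$flagged, 0)
  expect_length(res$accepted, 0)
  expect_equal(length(res$db$entries), 6)
  expect_equal(res$db$version, 1)
  expect_equal(res$model$version_label, "C1")
  expect_identical(res$model$oars$Bladder$mean_curve, m$oars$Bladder$mean_curve)
})

test_that("the evolution run follows the configured database trajectory", {
  cfg <- refinement_config(initial_size = 8, additions_per_round = 3,
                           n_rounds = 3, seed = 509)
  initial <- generate_cohort(coarse_cfg(8, 509))
  eval_cohort <- generate_cohort(coarse_cfg(5, 510, sigma_eps = 0))
  stream <- make_candidate_stream(511, template = coarse_cfg(1, 1))
  res <- suppressWarnings(
    run_evolution(plan_database(initial), stream, eval_cohort, cfg,
                  coarse_kbp_cfg()))
  expect_named(res$models, c("C0", "C1", "C2", "C3"))
  expect_equal(res$trace$size, c(8, 8, 11, 14))
  expect_true(all(diff(res$trace$size) >= 0))
  # closed loop only: candidate stream never consulted when n_rounds = 1
  res1 <- suppressWarnings(
    run_evolution(plan_database(initial), NULL, eval_cohort,
                  refinement_config(initial_size = 8, n_rounds = 1, seed = 512),
                  coarse_kbp_cfg()))
  expect_named(res1$models, c("C0", "C1"))
  expect_equal(res1$trace$size, c(8, 8))
})

test_that("retained plans never lose plan-quality points across a refinement round", {
  entries <- small_world(513, n = 10, sigma = 0.15)
  m <- suppressWarnings(fit_kbp_model(entries, coarse_kbp_cfg()))
  before <- vapply(entries, function(e) score_plan(e$plan)$total, numeric(1))
  res <- suppressWarnings(
    run_refinement_round(plan_database(entries), m, list(),
                         refinement_config(), coarse_kbp_cfg()))
  after <- vapply(res$db$entries, function(e) score_plan(e$plan)$total, numeric(1))
  expect_true(all(after >= before - 1e-9))
  expect_gt(length(res$flagged), 0)  # the high-noise world has flaggable plans
})

test_that("the evolution run is deterministic under a fixed seed", {
  cfg <- refinement_config(initial_size = 6, additions_per_round = 2,
                           n_rounds = 2, seed = 514)
  run_once <- function() {
    initial <- generate_cohort(coarse_cfg(6, 514))
    eval_cohort <- generate_cohort(coarse_cfg(4, 515, sigma_eps = 0))
    stream <- make_candidate_stream(516, template = coarse_cfg(1, 1))
    suppressWarnings(run_evolution(plan_database(initial), stream, eval_cohort,
                                   cfg, coarse_kbp_cfg()))
  }
  r1 <- run_once()
  r2 <- run_once()
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$models$C2$oars$Rectum$beta, r2$models$C2$oars$Rectum$beta)
})
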