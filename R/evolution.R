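#' A versioned plan database for model training
#'
#' @param entries List of database entries (each a list with `plan` and
#'   `features`, as produced by [generate_cohort()]).
#' @param version Integer refinement-round index (0 for the initial database).
#' @return An object of class `plan_database`.
#' @export
plan_database <- function(entries, version = 0L) {
  if (!is.list(entries) || length(entries) < 2L) {
    stop("a plan database needs at least 2 entries", call. = FALSE)
  }
  ids <- vapply(entries, function(e) e$plan$patient_id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate patient ids in database: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(entries = entries, version = as.integer(version)),
            class = "plan_database")
}

#' @export
print.plan_database <- function(x, ...) {
  cat(sprintf("<plan_database> %d plans, round %d\n",
              length(x$entries), x$version))
  invisible(x)
}

#' Configuration of the closed-loop model-evolution run
#'
#' Defaults reproduce the 25-to-100-plan trajectory: an initial database of
#' 25 plans, one pure closed-loop refinement round, then five adding rounds
#' of 15 gate-passing plans each (database sizes 25, 25, 40, 55, 70, 85,
#' 100 for models C0 through C6).
#'
#' @param initial_size Initial database size (default 25).
#' @param additions_per_round Gate-passing plans added per adding round
#'   (default 15).
#' @param n_rounds Number of refinement rounds (default 6; round 1 is
#'   closed-loop only, rounds 2..n add plans).
#' @param margin_gy Suboptimality margin for dose endpoints in Gy
#'   (default 0.9, i.e. 2\% of the 45 Gy prescription).
#' @param margin_pct Suboptimality margin for volume endpoints in
#'   percentage points (default 2).
#' @param reopt_factor Multiplicative shrink of the excess-dose parameter
#'   per re-optimization iteration (default 0.5, in (0, 1)).
#' @param max_reopt_iterations Iteration cap for one re-optimization
#'   (default 8).
#' @param gate_z Width of the estimate band the admission gate compares
#'   against, in residual-projection units (default 1; 0 gates strictly at
#'   the predicted curve).
#' @param seed Integer seed for the run.
#' @return A list of class `refinement_config`.
#' @export
refinement_config <- function(initial_size = 25L, additions_per_round = 15L,
                              n_rounds = 6L, margin_gy = 0.9, margin_pct = 2,
                              reopt_factor = 0.5, max_reopt_iterations = 8L,
                              gate_z = 1, seed = 1L) {
  stopifnot(initial_size >= 2, additions_per_round >= 0, n_rounds >= 1,
            margin_gy >= 0, margin_pct >= 0,
            reopt_factor > 0, reopt_factor < 1, max_reopt_iterations >= 1,
            gate_z >= 0)
  structure(list(initial_size = as.integer(initial_size),
                 additions_per_round = as.integer(additions_per_round),
                 n_rounds = as.integer(n_rounds),
                 margin_gy = margin_gy, margin_pct = margin_pct,
                 reopt_factor = reopt_factor,
                 max_reopt_iterations = as.integer(max_reopt_iterations),
                 gate_z = gate_z,
                 seed = as.integer(seed)),
            class = "refinement_config")
}

# Margin in the endpoint's own units (Gy for dose endpoints, percentage
# points for volume endpoints).
margin_for_endpoint <- function(spec, config) {
  if (spec$kind == "volume_at_dose") config$margin_pct else config$margin_gy
}

# Planned endpoint values of one plan, named by OAR.
planned_endpoint_values <- function(plan, endpoints) {
  vapply(names(endpoints), function(oar)
    evaluate_metric(plan, oar, endpoints[[oar]]), numeric(1))
}

#' Model-predicted endpoint values for one patient
#'
#' Evaluates each OAR's primary endpoint on the model's predicted (center)
#' curve for the given geometry.
#'
#' @param model A [kbp_model()].
#' @param features Named list of per-OAR [geometry_features()].
#' @param z Band width; with `z > 0` and `band = "upper"`/`"lower"` the
#'   endpoint is evaluated on that edge of the estimate band instead of the
#'   predicted curve.
#' @param band Which curve of the estimate to evaluate (default
#'   `"predicted"`).
#' @return Named numeric vector of predicted endpoint values, one per OAR.
#' @export
predict_endpoints <- function(model, features, z = 0,
                              band = c("predicted", "upper", "lower")) {
  band <- match.arg(band)
  vapply(names(model$oars), function(oar) {
    est <- predict_dvh(model, features, oar, z = z)
    evaluate_metric_on_curve(est[[band]], model$endpoints[[oar]])
  }, numeric(1))
}

#' Flag relatively suboptimal database plans
#'
#' A plan is flagged as suboptimal when, for any configured OAR endpoint
#' (all lower-better), its planned value exceeds the model-predicted value
#' by more than the margin.
#'
#' @param db A [plan_database()] (or plain list of entries).
#' @param model A [kbp_model()].
#' @param config A [refinement_config()] supplying the margins.
#' @return Character vector of flagged patient ids (possibly empty).
#' @export
flag_suboptimal <- function(db, model, config = refinement_config()) {
  entries <- if (inherits(db, "plan_database")) db$entries else db
  flagged <- character(0)
  for (entry in entries) {
    predicted <- predict_endpoints(model, entry$features)
    planned <- planned_endpoint_values(entry$plan, model$endpoints)
    margins <- vapply(model$endpoints, margin_for_endpoint, numeric(1),
                      config = config)
    if (any(planned > predicted + margins)) {
      flagged <- c(flagged, entry$plan$patient_id)
    }
  }
  flagged
}

#' Re-optimize a plan under the guidance of predicted DVHs
#'
#' The planner surrogate for synthetic plans: the plan's excess-dose
#' parameter is repeatedly shrunk (`epsilon <- reopt_factor * epsilon`)
#' until every configured OAR endpoint is at or below its predicted value,
#' or the iteration cap is reached. The returned plan is never worse than
#' the input on any configured endpoint.
#'
#' @param plan A synthetic [plan_record()] (carrying `epsilon` and its
#'   achievable curves). Plans without a planner surrogate are not
#'   supported.
#' @param predicted Named numeric vector of predicted endpoint values per
#'   OAR (e.g. from [predict_endpoints()]), or a named list of
#'   `dvh_estimate`s whose predicted curves are then evaluated.
#' @param config A [refinement_config()].
#' @param endpoints Named list of [dose_metric()] endpoints per OAR
#'   (default [default_oar_endpoints()] restricted to `names(predicted)`).
#' @return The re-optimized [plan_record()].
#' @export
reoptimize_plan <- function(plan, predicted, config = refinement_config(),
                            endpoints = NULL) {
  if (is.null(plan$epsilon) || is.null(plan$achievable)) {
    stop(sprintf("plan '%s' has no planner surrogate (not a synthetic plan); re-optimization unsupported",
                 plan$patient_id), call. = FALSE)
  }
  if (is.list(predicted)) {
    stopifnot(!is.null(names(predicted)))
    eps_names <- names(predicted)
    if (is.null(endpoints)) endpoints <- default_oar_endpoints()[eps_names]
    predicted <- vapply(eps_names, function(oar)
      evaluate_metric_on_curve(predicted[[oar]]$predicted, endpoints[[oar]]),
      numeric(1))
  }
  if (is.null(endpoints)) endpoints <- default_oar_endpoints()[names(predicted)]
  rebuild <- function(eps) {
    curves <- plan$curves
    for (oar in names(plan$achievable)) {
      curves[[oar]] <- dilate_curve(plan$achievable[[oar]], eps)
    }
    plan_record(plan$patient_id, curves, plan$prescriptions,
                provenance = plan$provenance, epsilon = eps,
                achievable = plan$achievable)
  }
  eps <- plan$epsilon
  current <- plan
  iter <- 0L
  repeat {
    planned <- planned_endpoint_values(current, endpoints)
    if (all(planned <= predicted[names(endpoints)] + 1e-9)) break
    if (iter >= config$max_reopt_iterations) break
    eps <- config$reopt_factor * eps
    current <- rebuild(eps)
    iter <- iter + 1L
  }
  current
}

#' Self-checking admission gate for new plans
#'
#' A candidate is accepted into the database only if its quality is at least
#' as good as the model's estimate: every configured OAR endpoint
#' (lower-better) must be at or below the estimate evaluated at the upper
#' edge of the band (`predicted + gate_z` residual projections; ties
#' accepted). `gate_z = 0` gates strictly at the predicted curve. The band
#' bar keeps the closed loop stable once the model has converged to the
#' achievable frontier, where a point-prediction bar would reject almost
#' every candidate.
#'
#' @param plan A [plan_record()].
#' @param model A [kbp_model()] covering the plan's OARs.
#' @param features Named list of per-OAR [geometry_features()] for the plan.
#' @param config A [refinement_config()] supplying `gate_z`.
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
self_check_gate <- function(plan, model, features,
                            config = refinement_config()) {
  bar <- if (config$gate_z > 0) {
    predict_endpoints(model, features, z = config$gate_z, band = "upper")
  } else {
    predict_endpoints(model, features)
  }
  planned <- planned_endpoint_values(plan, model$endpoints)
  all(planned <= bar + 1e-9)
}

#' One refinement round: closed-loop repair, gated additions, retrain
#'
#' Flags suboptimal database plans and re-optimizes them under the current
#' model's predictions; re-optimizes each candidate and appends those that
#' pass the self-check gate; refits the model on the updated database and
#' increments the database version.
#'
#' @param db A [plan_database()].
#' @param model The current [kbp_model()].
#' @param new_candidates List of candidate entries (`plan` + `features`);
#'   may be empty.
#' @param config A [refinement_config()].
#' @param fit_config A [kbp_config()] for retraining.
#' @param version_label Label for the refitted model (default bumps the
#'   round index).
#' @return List with the updated `db`, the refitted `model`, the flagged ids
#'   and the accepted candidate ids.
#' @export
run_refinement_round <- function(db, model, new_candidates = list(),
                                 config = refinement_config(),
                                 fit_config = kbp_config(),
                                 version_label = NULL) {
  if (!inherits(db, "plan_database")) stop("expected a 'plan_database'",
                                           call. = FALSE)
  if (is.null(version_label)) version_label <- sprintf("C%d", db$version + 1L)
  entries <- db$entries
  flagged <- flag_suboptimal(entries, model, config)
  for (i in seq_along(entries)) {
    if (entries[[i]]$plan$patient_id %in% flagged) {
      predicted <- predict_endpoints(model, entries[[i]]$features)
      entries[[i]]$plan <- reoptimize_plan(entries[[i]]$plan, predicted,
                                           config, model$endpoints)
    }
  }
  accepted <- character(0)
  for (cand in new_candidates) {
    predicted <- predict_endpoints(model, cand$features)
    cand$plan <- reoptimize_plan(cand$plan, predicted, config, model$endpoints)
    if (self_check_gate(cand$plan, model, cand$features, config)) {
      entries[[length(entries) + 1L]] <- cand
      accepted <- c(accepted, cand$plan$patient_id)
    }
  }
  new_db <- plan_database(entries, db$version + 1L)
  new_model <- fit_kbp_model(entries, fit_config, version_label)
  list(db = new_db, model = new_model, flagged = flagged, accepted = accepted)
}

#' Mean absolute prediction error per OAR on an evaluation cohort
#'
#' For each cohort member the model predicts every OAR DVH from the
#' geometry; the primary endpoint of the predicted curve is compared with
#' the member's reference plan, and the absolute errors are averaged per
#' OAR.
#'
#' @param model A [kbp_model()].
#' @param eval_cohort List of entries (`plan` + `features`).
#' @return Named numeric vector of mean absolute endpoint errors per OAR.
#' @export
evaluate_model_errors <- function(model, eval_cohort) {
  errs <- vapply(eval_cohort, function(entry) {
    predicted <- predict_endpoints(model, entry$features)
    reference <- planned_endpoint_values(entry$plan, model$endpoints)
    abs(predicted - reference)
  }, numeric(length(model$oars)))
  rowMeans(matrix(errs, nrow = length(model$oars),
                  dimnames = list(names(model$oars), NULL)))
}

mean_database_pqm <- function(entries, criteria) {
  mean(vapply(entries, function(e) score_plan(e$plan, criteria)$total,
              numeric(1)))
}

#' Run the full closed-loop model evolution (C0 to Cn)
#'
#' Trains the initial model C0 on the starting database; round 1 is pure
#' closed-loop refinement (flagged plans re-optimized, model retrained as
#' C1, size unchanged); each later round additionally draws candidates from
#' `candidate_stream`, re-optimizes them, and admits plans through the
#' self-check gate until `additions_per_round` are accepted, then retrains.
#' Every model is evaluated on the fixed evaluation cohort to fill the
#' evolution trace.
#'
#' @param initial_db A [plan_database()] or list of entries (the initial
#'   training set, size `initial_size`).
#' @param candidate_stream Function `function(n)` returning `n` fresh
#'   candidate entries (see [make_candidate_stream()]); may be `NULL` when
#'   `n_rounds = 1`.
#' @param eval_cohort List of entries used as the fixed evaluation cohort.
#' @param config A [refinement_config()].
#' @param fit_config A [kbp_config()].
#' @param criteria A [criteria_set()] for the database-quality trace column.
#' @param max_draw_factor Cap on stream consumption per round, as a multiple
#'   of `additions_per_round` (a configuration error names the round when
#'   the quota cannot be filled).
#' @return List of class `evolution_result`: `models` (named list C0..Cn),
#'   `trace` (data frame with one row per model: label, database size, mean
#'   database PQM, per-OAR mean prediction error), and the final `db`.
#' @export
run_evolution <- function(initial_db, candidate_stream = NULL, eval_cohort,
                          config = refinement_config(),
                          fit_config = kbp_config(),
                          criteria = default_criteria(),
                          max_draw_factor = 40L) {
  db <- if (inherits(initial_db, "plan_database")) initial_db
        else plan_database(initial_db, 0L)
  set.seed(config$seed)
  model <- fit_kbp_model(db$entries, fit_config, "C0")
  models <- list(C0 = model)
  trace_rows <- list(trace_row(model, db, eval_cohort, criteria))
  for (round in seq_len(config$n_rounds)) {
    candidates <- list()
    if (round > 1L && config$additions_per_round > 0L) {
      if (is.null(candidate_stream)) {
        stop(sprintf("round %d needs candidates but no candidate stream was supplied",
                     round), call. = FALSE)
      }
      drawn <- 0L
      cap <- max_draw_factor * config$additions_per_round
      while (length(candidates) < config$additions_per_round) {
        if (drawn >= cap) {
          stop(sprintf("round %d: candidate stream exhausted (%d drawn, %d accepted of %d needed)",
                       round, drawn, length(candidates),
                       config$additions_per_round), call. = FALSE)
        }
        batch <- candidate_stream(config$additions_per_round)
        for (cand in batch) {
          if (length(candidates) >= config$additions_per_round) break
          predicted <- predict_endpoints(model, cand$features)
          cand$plan <- reoptimize_plan(cand$plan, predicted, config,
                                       model$endpoints)
          if (self_check_gate(cand$plan, model, cand$features, config)) {
            candidates[[length(candidates) + 1L]] <- cand
          }
        }
        drawn <- drawn + length(batch)
      }
    }
    res <- run_refinement_round(db, model, candidates, config, fit_config,
                                sprintf("C%d", round))
    db <- res$db
    model <- res$model
    models[[sprintf("C%d", round)]] <- model
    trace_rows[[length(trace_rows) + 1L]] <-
      trace_row(model, db, eval_cohort, criteria)
  }
  structure(list(models = models,
                 trace = do.call(rbind, trace_rows),
                 db = db),
            class = "evolution_result")
}

trace_row <- function(model, db, eval_cohort, criteria) {
  errs <- evaluate_model_errors(model, eval_cohort)
  out <- data.frame(label = model$version_label,
                    size = length(db$entries),
                    mean_pqm = mean_database_pqm(db$entries, criteria),
                    stringsAsFactors = FALSE)
  for (oar in names(errs)) out[[paste0("err_", oar)]] <- errs[[oar]]
  out$mean_error <- mean(errs)
  out
}

#' @export
print.evolution_result <- function(x, ...) {
  cat(sprintf("<evolution_result> %d models (%s)\n", length(x$models),
              paste(names(x$models), collapse = ", ")))
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Candidate stream backed by the synthetic cohort generator
#'
#' Returns a closure `function(n)` producing `n` fresh synthetic candidates
#' per call. Each batch uses its own seed derived from `seed` and an
#' internal counter, so the stream is deterministic regardless of the
#' surrounding RNG state.
#'
#' @param seed Integer base seed.
#' @param sigma_eps Planner-skill scale of the candidates (default 0.08).
#' @param template A [cohort_config()] whose anatomy priors and grid the
#'   stream copies (batch size and seed are overridden per call).
#' @return A function `function(n)` returning a list of entries.
#' @export
make_candidate_stream <- function(seed, sigma_eps = 0.08,
                                  template = cohort_config(1)) {
  counter <- 0L
  function(n) {
    counter <<- counter + 1L
    cfg <- cohort_config(n_patients = n,
                         seed = (seed + 7919L * counter) %% .Machine$integer.max,
                         sigma_eps = sigma_eps, h = template$h,
                         grid = template$grid,
                         id_prefix = sprintf("CAND%03d", counter))
    generate_cohort(cfg)
  }
}

#' The default seeded evolution experiment
#'
#' Wires together the study conditions of the default synthetic experiment:
#' an initial database of 25 plans with planner-skill scale
#' `sigma_eps = 0.08`, a synthetic candidate stream, a fixed 35-patient
#' evaluation cohort whose reference plans are best-effort (`epsilon = 0`),
#' and the 25-to-100 refinement trajectory.
#'
#' @param seed Integer seed controlling every random draw.
#' @param config A [refinement_config()] (its `seed` is overridden).
#' @param fit_config A [kbp_config()].
#' @param n_eval Evaluation-cohort size (default 35).
#' @param sigma_eps Planner-skill scale (default 0.08).
#' @return An `evolution_result` (see [run_evolution()]).
#' @export
default_evolution_experiment <- function(seed = 1L,
                                         config = refinement_config(),
                                         fit_config = kbp_config(),
                                         n_eval = 35L, sigma_eps = 0.08) {
  config$seed <- as.integer(seed)
  initial <- generate_cohort(cohort_config(config$initial_size,
                                           seed = seed, sigma_eps = sigma_eps,
                                           id_prefix = "INIT"))
  eval_raw <- generate_cohort(cohort_config(n_eval,
                                            seed = (seed + 500009L) %% .Machine$integer.max,
                                            sigma_eps = 0,
                                            id_prefix = "EVAL"))
  stream <- make_candidate_stream((seed + 104729L) %% .Machine$integer.max,
                                  sigma_eps = sigma_eps)
  run_evolution(plan_database(initial, 0L), stream, eval_raw,
                config = config, fit_config = fit_config)
}
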