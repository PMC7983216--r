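test_that("a zero-variance database is reproduced exactly, with collapsed bands", {
  entries <- identical_entries(n = 6)
  m <- suppressWarnings(fit_kbp_model(entries, coarse_kbp_cfg()))
  expect_equal(m$n_train, 6)
  ref <- resample_dvh(entries[[1]]$plan$curves$Bladder, m$config$grid)
  est <- predict_dvh(m, entries[[1]]$features, "Bladder", z = 1)
  expect_equal(est$predicted$rel_volume, ref$rel_volume, tolerance = 1e-9)
  expect_equal(est$lower$rel_volume, est$upper$rel_volume, tolerance = 1e-9)
})

test_that("z = 0 collapses the estimate band onto the prediction", {
  db <- generate_cohort(coarse_cfg(10, seed = 401))
  m <- suppressWarnings(fit_kbp_model(db, coarse_kbp_cfg()))
  est <- predict_dvh(m, db[[1]]$features, "Rectum", z = 0)
  expect_identical(est$lower$rel_volume, est$predicted$rel_volume)
  expect_identical(est$upper$rel_volume, est$predicted$rel_volume)
  est1 <- predict_dvh(m, db[[1]]$features, "Rectum", z = 1)
  expect_true(all(est1$lower$rel_volume <= est1$predicted$rel_volume + 1e-12))
  expect_true(all(est1$predicted$rel_volume <= est1$upper$rel_volume + 1e-12))
})

test_that("emitted estimates are valid monotone DVH curves", {
  db <- generate_cohort(coarse_cfg(12, seed = 402))
  m <- suppressWarnings(fit_kbp_model(db, coarse_kbp_cfg()))
  for (oar in c("Bladder", "KidneyL", "FemoralHeadR")) {
    est <- predict_dvh(m, db[[3]]$features, oar, z = 2)
    for (cv in list(est$predicted, est$lower, est$upper)) {
      expect_silent(dvh_curve(cv$structure_name, cv$volume_cc, cv$dose_gy,
                              cv$rel_volume))
    }
  }
})

test_that("training is deterministic and records the database size", {
  db <- generate_cohort(coarse_cfg(25, seed = 403))
  m1 <- suppressWarnings(fit_kbp_model(db, coarse_kbp_cfg(), "C0"))
  m2 <- suppressWarnings(fit_kbp_model(db, coarse_kbp_cfg(), "C0"))
  expect_equal(m1$n_train, 25)
  expect_identical(m1$oars$Bladder$beta, m2$oars$Bladder$beta)
  expect_identical(m1$oars$KidneyR$residual_scale, m2$oars$KidneyR$residual_scale)
  expect_error(fit_kbp_model(db[1:3], coarse_kbp_cfg()), "modes")
})

test_that("self-prediction error does not exceed held-out error on average", {
  gap <- vapply(1:8, function(i) {
    s <- 400 + i * 7
    train <- generate_cohort(coarse_cfg(40, seed = s, sigma_eps = 0))
    held <- generate_cohort(coarse_cfg(40, seed = s + 50000, sigma_eps = 0))
    m <- suppressWarnings(fit_kbp_model(train, coarse_kbp_cfg()))
    mean(evaluate_model_errors(m, held)) - mean(evaluate_model_errors(m, train))
  }, numeric(1))
  expect_gte(mean(gap), 0)
})

test_that("predictions converge to achievable DVHs as the training set grows", {
  err_at <- function(n, seed) {
    train <- generate_cohort(coarse_cfg(n, seed, sigma_eps = 0))
    held <- generate_cohort(coarse_cfg(10, seed + 10000, sigma_eps = 0))
    m <- suppressWarnings(fit_kbp_model(train, coarse_kbp_cfg()))
    mean(evaluate_model_errors(m, held))
  }
  errs <- vapply(1:20, function(s) {
    c(small = err_at(10, 420 + s), large = err_at(100, 420 + s))
  }, numeric(2))
  expect_lt(mean(errs["large", ]), mean(errs["small", ]))
})

test_that("objectives come from the lower band and tighten as the band widens", {
  db <- generate_cohort(coarse_cfg(10, seed = 406))
  m <- suppressWarnings(fit_kbp_model(db, coarse_kbp_cfg()))
  eps <- list(dose_metric("dose_at_relative_volume", 35), dose_metric("mean_dose"))
  est0 <- predict_dvh(m, db[[2]]$features, "Bladder", z = 0)
  obj0 <- objectives_from_estimate(est0, eps)
  expect_equal(obj0$objective,
               vapply(eps, function(e)
                 kbplanr:::evaluate_metric_on_curve(est0$predicted, e),
                 numeric(1)))
  prev <- NULL
  for (z in c(0, 0.5, 1, 2)) {
    obj <- objectives_from_estimate(predict_dvh(m, db[[2]]$features, "Bladder", z),
                                    eps)$objective
    if (!is.null(prev)) expect_true(all(obj <= prev + 1e-9))
    prev <- obj
  }
  # hand-computed on a fixture estimate
  grid <- c(0, 20, 40)
  fix <- list(predicted = dvh_curve("Bladder", 100, grid, c(1, 0.5, 0)),
              lower = dvh_curve("Bladder (lower)", 100, grid, c(1, 0.4, 0)),
              upper = dvh_curve("Bladder (upper)", 100, grid, c(1, 0.6, 0)),
              oar = "Bladder", z = 1)
  class(fix) <- "dvh_estimate"
  obj <- objectives_from_estimate(fix, list(dose_metric("dose_at_relative_volume", 40)))
  expect_equal(obj$objective, 20)  # inverse interpolation on the lower curve
})

test_that("prediction error is the symmetric absolute endpoint difference", {
  db <- generate_cohort(coarse_cfg(8, seed = 407))
  m <- suppressWarnings(fit_kbp_model(db, coarse_kbp_cfg()))
  ep <- dose_metric("dose_at_relative_volume", 35)
  est <- predict_dvh(m, db[[1]]$features, "Bladder", z = 0)
  selfplan <- plan_record("self", list(Bladder = est$predicted), c(PCTV = 45))
  expect_equal(prediction_error(est, selfplan, "Bladder", ep), 0)
  err <- prediction_error(est, db[[1]]$plan, "Bladder", ep)
  pred_val <- kbplanr:::evaluate_metric_on_curve(est$predicted, ep)
  ref_val <- evaluate_metric(db[[1]]$plan, "Bladder", ep)
  expect_equal(err, abs(pred_val - ref_val))
  expect_equal(err, abs(ref_val - pred_val))
})

test_that("models survive a JSON serialization round trip", {
  db <- generate_cohort(coarse_cfg(8, seed = 408))
  m <- suppressWarnings(fit_kbp_model(db, coarse_kbp_cfg(), "C3"))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  write_kbp_model(m, path)
  m2 <- read_kbp_model(path)
  expect_equal(m2$version_label, "C3")
  expect_equal(m2$n_train, m$n_train)
  for (oar in names(m$oars)) {
    e1 <- predict_dvh(m, db[[2]]$features, oar, z = 1)
    e2 <- predict_dvh(m2, db[[2]]$features, oar, z = 1)
    expect_equal(e1$predicted$rel_volume, e2$predicted$rel_volume, tolerance = 1e-12)
    expect_equal(e1$lower$rel_volume, e2$lower$rel_volume, tolerance = 1e-12)
  }
})
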