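#' Geometry features of one organ at risk
#'
#' The open anatomical parameterization the DVH model regresses on:
#' \describe{
#'   \item{`f`}{overlap fraction of the organ with the high-dose (target)
#'     envelope, in \[0, 1\].}
#'   \item{`tau`}{dose fall-off scale in Gy (> 0), encoding the organ's
#'     proximity to the target: distant organs see a fast exponential dose
#'     decay (small `tau`), abutting organs a slow one.}
#'   \item{`organ_volume`}{absolute organ volume in cc.}
#'   \item{`target_volume`}{combined planning target volume in cc.}
#' }
#'
#' @param f Overlap fraction in \[0, 1\].
#' @param tau Fall-off scale in Gy (> 0).
#' @param organ_volume Organ volume in cc (> 0).
#' @param target_volume Target volume in cc (> 0).
#' @return An object of class `geometry_features`.
#' @export
geometry_features <- function(f, tau, organ_volume, target_volume) {
  stopifnot(is.numeric(f), f >= 0, f <= 1,
            is.numeric(tau), tau > 0,
            is.numeric(organ_volume), organ_volume > 0,
            is.numeric(target_volume), target_volume > 0)
  structure(list(f = f, tau = tau, organ_volume = organ_volume,
                 target_volume = target_volume),
            class = "geometry_features")
}

# Regression basis expansion of the geometry features. The DVH family is
# nonlinear in log(tau); the quadratic and interaction terms keep the linear
# model accurate over realistic tau spreads.
kbp_feature_row <- function(feat) {
  lt <- log(feat$tau)
  c(f = feat$f,
    log_tau = lt,
    log_tau_sq = lt^2,
    f_log_tau = feat$f * lt,
    log_organ_volume = log(feat$organ_volume),
    log_target_volume = log(feat$target_volume))
}

#' Default configuration for DVH-model training
#'
#' @param k Number of principal DVH modes to keep (default 4).
#' @param ridge Ridge penalty on the standardized feature regression
#'   (default 1e-3).
#' @param grid Common dose grid (Gy) all curves are resampled to; default
#'   0 to 75 Gy in 0.05 Gy steps.
#' @param oars Organ-at-risk names the model covers; default the seven pelvic
#'   OARs of [default_oar_endpoints()].
#' @return A list of class `kbp_config`.
#' @export
kbp_config <- function(k = 4, ridge = 1e-3, grid = seq(0, 75, by = 0.05),
                       oars = names(default_oar_endpoints())) {
  stopifnot(k >= 1, ridge >= 0, length(grid) >= 2)
  structure(list(k = as.integer(k), ridge = ridge, grid = grid, oars = oars),
            class = "kbp_config")
}

#' Table-driven primary endpoint per organ at risk
#'
#' The key dosimetric endpoint used for flagging, gating, model ranking and
#' the evolution trace: spinal cord D_0.03cc, bladder D_35\%, rectum D_60\%,
#' kidney V_18Gy, femoral head V_35Gy. All are lower-better.
#'
#' @return Named list of [dose_metric()] specs keyed by OAR name.
#' @export
default_oar_endpoints <- function() {
  list(
    SpinalCord = dose_metric("dose_at_absolute_volume", 0.03),
    Bladder = dose_metric("dose_at_relative_volume", 35),
    Rectum = dose_metric("dose_at_relative_volume", 60),
    KidneyL = dose_metric("volume_at_dose", 18),
    KidneyR = dose_metric("volume_at_dose", 18),
    FemoralHeadL = dose_metric("volume_at_dose", 35),
    FemoralHeadR = dose_metric("volume_at_dose", 35)
  )
}

#' Train the geometry-to-DVH prediction model
#'
#' Per organ at risk: all training DVHs are resampled onto the common grid,
#' the mean-centered curves are decomposed by principal component analysis
#' keeping `k` modes, and a ridge least-squares regression maps the
#' standardized geometry features to the mode scores. The per-mode RMS
#' residual is stored and later drives the estimate band.
#'
#' @param database List of entries, each a list with elements `plan`
#'   (a [plan_record()]) and `features` (named list of [geometry_features()]
#'   per OAR).
#' @param config A [kbp_config()].
#' @param version_label Model label, e.g. `"C0"`.
#' @return An object of class `kbp_model`.
#' @export
fit_kbp_model <- function(database, config = kbp_config(), version_label = "C0") {
  if (!is.list(database) || length(database) < 2L) {
    stop("training requires at least 2 plans", call. = FALSE)
  }
  n <- length(database)
  if (n < config$k + 1L) {
    stop(sprintf("training requires more plans (%d) than modes + 1 (%d)",
                 n, config$k + 1L), call. = FALSE)
  }
  grid <- config$grid
  oar_models <- list()
  for (oar in config$oars) {
    Y <- matrix(0, n, length(grid))
    X <- matrix(0, n, 6L)
    for (i in seq_len(n)) {
      entry <- database[[i]]
      cv <- entry$plan$curves[[oar]]
      if (is.null(cv)) {
        stop(sprintf("plan '%s' lacks OAR '%s' required by the model",
                     entry$plan$patient_id, oar), call. = FALSE)
      }
      Y[i, ] <- resample_dvh(cv, grid)$rel_volume
      feat <- entry$features[[oar]]
      if (is.null(feat)) {
        stop(sprintf("plan '%s' lacks geometry features for OAR '%s'",
                     entry$plan$patient_id, oar), call. = FALSE)
      }
      X[i, ] <- kbp_feature_row(feat)
    }
    colnames(X) <- names(kbp_feature_row(geometry_features(0.5, 10, 100, 100)))
    # drop zero-variance features (cannot be standardized)
    sds <- apply(X, 2, stats::sd)
    keep <- sds > 1e-12
    dropped <- colnames(X)[!keep]
    if (length(dropped)) {
      warning(sprintf("OAR %s: dropping zero-variance feature(s): %s",
                      oar, paste(dropped, collapse = ", ")), call. = FALSE)
    }
    ctr <- colMeans(X)[keep]
    scl <- sds[keep]
    Xs <- scale(X[, keep, drop = FALSE], center = ctr, scale = scl)

    mu <- colMeans(Y)
    Yc <- sweep(Y, 2, mu)
    sv <- svd(Yc, nu = 0, nv = config$k)
    comps <- sv$v                       # grid x k, orthonormal columns
    scores <- Yc %*% comps              # n x k
    ev <- (sv$d^2 / max(n - 1L, 1L))[seq_len(config$k)]

    p <- ncol(Xs)
    intercept <- colMeans(scores)
    Sc <- sweep(scores, 2, intercept)
    beta <- if (p > 0L) {
      solve(crossprod(Xs) + config$ridge * diag(p), crossprod(Xs, Sc))
    } else {
      matrix(0, 0L, config$k)
    }
    fitted <- sweep(if (p > 0L) Xs %*% beta else matrix(0, n, config$k),
                    2, intercept, `+`)
    resid_scale <- sqrt(colMeans((scores - fitted)^2))
    oar_models[[oar]] <- list(
      mean_curve = mu, components = comps, explained_variance = ev,
      feature_names = colnames(X)[keep], center = ctr, scale = scl,
      dropped = dropped, beta = beta, intercept = intercept,
      residual_scale = resid_scale)
  }
  structure(list(version_label = version_label, n_train = n,
                 config = config, oars = oar_models,
                 endpoints = default_oar_endpoints()[config$oars]),
            class = "kbp_model")
}

#' @export
print.kbp_model <- function(x, ...) {
  cat(sprintf("<kbp_model> %s: trained on %d plans, %d OARs, %d modes\n",
              x$version_label, x$n_train, length(x$oars), x$config$k))
  invisible(x)
}

#' Predict an OAR DVH with an estimate band
#'
#' The predicted curve is the training mean plus the regressed principal
#' modes, clipped to \[0, 1\] and re-monotonized by a running minimum from
#' dose 0. The band is the prediction +/- `z` times the residual projection
#' `sqrt(sum_m (s_m P_m(D))^2)` (per-mode RMS residuals `s_m`), processed the
#' same way, so `lower <= predicted <= upper` pointwise. The lower band is
#' the optimistic (better-sparing) side used for optimization objectives.
#'
#' @param model A [kbp_model()].
#' @param features Either a [geometry_features()] for `oar`, or a named list
#'   of per-OAR features from which `oar` is picked.
#' @param oar OAR name configured in the model.
#' @param z Band width multiplier (default 1; 0 collapses the band).
#' @return An object of class `dvh_estimate` with elements `predicted`,
#'   `lower`, `upper` (all [dvh_curve()]s) and `oar`.
#' @export
predict_dvh <- function(model, features, oar, z = 1) {
  if (!inherits(model, "kbp_model")) stop("expected a 'kbp_model'", call. = FALSE)
  om <- model$oars[[oar]]
  if (is.null(om)) {
    stop(sprintf("OAR '%s' is not covered by model %s (has: %s)", oar,
                 model$version_label, paste(names(model$oars), collapse = ", ")),
         call. = FALSE)
  }
  if (!inherits(features, "geometry_features")) {
    features <- features[[oar]]
    if (is.null(features)) stop(sprintf("no features supplied for OAR '%s'", oar),
                                call. = FALSE)
  }
  stopifnot(is.numeric(z), length(z) == 1L, z >= 0)
  xrow <- kbp_feature_row(features)[om$feature_names]
  xs <- (xrow - om$center) / om$scale
  scores <- as.numeric(om$intercept +
                         if (length(xs)) drop(crossprod(om$beta, xs)) else 0)
  grid <- model$config$grid
  pred <- om$mean_curve + drop(om$components %*% scores)
  mk <- function(v, suffix) {
    v[1L] <- 1
    v <- cummin(pmin(pmax(v, 0), 1))
    new_dvh_curve(paste0(oar, suffix), features$organ_volume, grid, v)
  }
  predicted <- mk(pred, "")
  if (z > 0) {
    band <- z * sqrt(drop(om$components^2 %*% om$residual_scale^2))
    lower <- mk(pred - band, " (lower)")
    upper <- mk(pred + band, " (upper)")
  } else {
    lower <- upper <- predicted
  }
  est <- list(predicted = predicted, lower = lower, upper = upper,
              oar = oar, z = z)
  class(est) <- "dvh_estimate"
  est
}

#' @export
print.dvh_estimate <- function(x, ...) {
  cat(sprintf("<dvh_estimate> %s (z = %g): predicted D_mean %.2f Gy, band [%.2f, %.2f] Gy\n",
              x$oar, x$z, mean_dose(x$predicted), mean_dose(x$lower),
              mean_dose(x$upper)))
  invisible(x)
}

#' Optimization objectives from the lower estimate band
#'
#' Evaluates each requested endpoint on the lower band of the estimate — the
#' optimistic side of the prediction range, used by default as the
#' organ-sparing optimization objective.
#'
#' @param estimate A `dvh_estimate` from [predict_dvh()].
#' @param endpoints List of [dose_metric()] specs.
#' @return Data frame with columns `endpoint` and `objective`.
#' @export
objectives_from_estimate <- function(estimate, endpoints) {
  if (!inherits(estimate, "dvh_estimate")) stop("expected a 'dvh_estimate'",
                                                call. = FALSE)
  if (inherits(endpoints, "dose_metric")) endpoints <- list(endpoints)
  data.frame(
    endpoint = vapply(endpoints, format_dose_metric, character(1)),
    objective = vapply(endpoints, function(e)
      evaluate_metric_on_curve(estimate$lower, e), numeric(1)),
    stringsAsFactors = FALSE)
}

#' Absolute prediction error at one endpoint
#'
#' The absolute difference between the endpoint evaluated on the predicted
#' curve and on the reference plan's curve (typically the clinically
#' approved / final plan).
#'
#' @param estimate A `dvh_estimate` from [predict_dvh()].
#' @param reference_plan Reference [plan_record()].
#' @param oar OAR name (must be present in the reference plan).
#' @param endpoint A [dose_metric()].
#' @return Absolute error (Gy or percentage points).
#' @export
prediction_error <- function(estimate, reference_plan, oar, endpoint) {
  if (!inherits(estimate, "dvh_estimate")) stop("expected a 'dvh_estimate'",
                                                call. = FALSE)
  ref <- evaluate_metric(reference_plan, oar, endpoint)
  prd <- evaluate_metric_on_curve(estimate$predicted, endpoint)
  abs(prd - ref)
}

#' Serialize a fitted model to JSON
#'
#' @param model A [kbp_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kbp_model <- function(model, path) {
  if (!inherits(model, "kbp_model")) stop("expected a 'kbp_model'", call. = FALSE)
  obj <- list(
    format = "kbplanr-model-v1",
    version_label = model$version_label,
    n_train = model$n_train,
    config = list(k = model$config$k, ridge = model$config$ridge,
                  grid = model$config$grid, oars = model$config$oars),
    oars = lapply(model$oars, function(om) list(
      mean_curve = om$mean_curve,
      components = om$components,      # grid x k matrix
      explained_variance = om$explained_variance,
      feature_names = om$feature_names,
      center = om$center, scale = om$scale, dropped = om$dropped,
      beta = om$beta, intercept = om$intercept,
      residual_scale = om$residual_scale)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a model written by [write_kbp_model()]
#'
#' @param path JSON model file.
#' @return A [kbp_model()].
#' @export
read_kbp_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "kbplanr-model-v1")) {
    stop(sprintf("'%s' is not a kbplanr model file", path), call. = FALSE)
  }
  config <- kbp_config(k = obj$config$k, ridge = obj$config$ridge,
                       grid = obj$config$grid, oars = obj$config$oars)
  oars <- lapply(obj$oars, function(om) {
    om$components <- matrix(unlist(om$components), ncol = config$k)
    om$beta <- matrix(unlist(om$beta), ncol = config$k)
    om$center <- stats::setNames(as.numeric(om$center), om$feature_names)
    om$scale <- stats::setNames(as.numeric(om$scale), om$feature_names)
    om$dropped <- as.character(om$dropped)
    om
  })
  structure(list(version_label = obj$version_label, n_train = obj$n_train,
                 config = config, oars = oars,
                 endpoints = default_oar_endpoints()[config$oars]),
            class = "kbp_model")
}
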