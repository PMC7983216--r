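#' Rank-points for one patient and one OAR across competing models
#'
#' The absolute prediction errors of `M` models are ranked from small to
#' large; the best model receives `M` points, the second `M - 1`, and so on
#' down to 1. Tied errors receive the average of the points they span, which
#' preserves the per-patient point total `M (M + 1) / 2`.
#'
#' @param errors Numeric vector of finite, non-negative absolute prediction
#'   errors, one per model (names preserved).
#' @return Numeric vector of points per model.
#' @examples
#' rank_models_for_patient(c(C1 = 3, C5 = 1, C6 = 0.2)) # 1, 2, 3
#' rank_models_for_patient(c(0.2, 0.2, 0.5))            # 2.5, 2.5, 1
#' @export
rank_models_for_patient <- function(errors) {
  if (!is.numeric(errors) || !length(errors)) {
    stop("'errors' must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(errors) || any(!is.finite(errors)) || any(errors < 0)) {
    stop("'errors' must be finite and non-negative", call. = FALSE)
  }
  m <- length(errors)
  pts <- m + 1 - rank(errors, ties.method = "average")
  names(pts) <- names(errors)
  pts
}

#' Average rank-points over patients, per model and OAR
#'
#' @param per_patient_points 3-d array of points with dimensions
#'   patients x models x OARs (dimnames used for labels), or a list of
#'   per-patient matrices (models x OARs).
#' @return An object of class `ranking_result`: matrix of mean points
#'   (models x OARs) plus `n_patients`.
#' @export
aggregate_ranking <- function(per_patient_points) {
  if (is.list(per_patient_points) && !is.array(per_patient_points)) {
    dims <- unique(lapply(per_patient_points, dim))
    if (length(dims) != 1L) {
      stop("ragged table: per-patient matrices differ in dimension",
           call. = FALSE)
    }
    arr <- simplify2array(per_patient_points)      # models x OARs x patients
    arr <- aperm(arr, c(3L, 1L, 2L))
    dimnames(arr) <- c(list(NULL), dimnames(per_patient_points[[1L]]))
    per_patient_points <- arr
  }
  if (!is.array(per_patient_points) || length(dim(per_patient_points)) != 3L) {
    stop("'per_patient_points' must be a patients x models x OARs array",
         call. = FALSE)
  }
  if (anyNA(per_patient_points)) stop("ragged table: missing points",
                                      call. = FALSE)
  means <- apply(per_patient_points, c(2L, 3L), mean)
  structure(list(mean_points = means,
                 n_patients = dim(per_patient_points)[1L]),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("<ranking_result> mean rank-points over %d patients\n",
              x$n_patients))
  print(round(x$mean_points, 3))
  invisible(x)
}

#' Rank competing models on an evaluation cohort
#'
#' For every patient and OAR, each model predicts the OAR DVH from the
#' patient's geometry; the absolute error of the primary endpoint against
#' the patient's reference plan is ranked across models and converted to
#' points ([rank_models_for_patient()]), then averaged over patients.
#'
#' @param models Named list of [kbp_model()]s (all covering the same OARs).
#' @param eval_cohort List of entries (`plan` + `features`).
#' @param endpoints Named list of [dose_metric()]s per OAR (default: the
#'   first model's configured endpoints).
#' @return A `ranking_result` (see [aggregate_ranking()]).
#' @export
rank_models <- function(models, eval_cohort, endpoints = NULL) {
  stopifnot(is.list(models), length(models) >= 1L)
  if (is.null(names(models))) {
    names(models) <- vapply(models, function(m) m$version_label, character(1))
  }
  oars <- names(models[[1L]]$oars)
  if (is.null(endpoints)) endpoints <- models[[1L]]$endpoints
  per_patient <- lapply(eval_cohort, function(entry) {
    reference <- planned_endpoint_values(entry$plan, endpoints)
    errs <- vapply(models, function(model) {
      predicted <- predict_endpoints(model, entry$features)
      abs(predicted - reference[names(predicted)])
    }, numeric(length(oars)))                     # OARs x models
    pts <- apply(errs, 1L, rank_models_for_patient) # models x OARs
    if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1L,
                                         dimnames = list(names(models), oars))
    pts
  })
  aggregate_ranking(per_patient)
}
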