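#' One patient plan: DVH curves plus prescriptions
#'
#' A plan record bundles the cumulative DVHs of the targets, organs at risk
#' and (optionally) the external body contour of one treatment plan, together
#' with the prescription doses and a provenance label. Synthetic plans
#' additionally carry the planner-skill parameter `epsilon` and the
#' best-effort (achievable) curves they were derived from, which the
#' re-optimization surrogate needs.
#'
#' @param patient_id Patient/plan identifier.
#' @param curves Named list of [dvh_curve()] objects, keyed by structure name.
#' @param prescriptions Named numeric vector of prescription doses in Gy,
#'   e.g. `c(PGTVnd = 60, PCTV = 45)`.
#' @param provenance One of `"synthetic"`, `"AP"`, `"MP"`, `"CP"` (automatic,
#'   manual, clinically approved).
#' @param epsilon Optional planner-skill excess-dose parameter (>= 0).
#' @param achievable Optional named list of achievable [dvh_curve()]s
#'   (synthetic plans only).
#' @return An object of class `plan_record`.
#' @export
plan_record <- function(patient_id, curves, prescriptions,
                        provenance = c("synthetic", "AP", "MP", "CP"),
                        epsilon = NULL, achievable = NULL) {
  provenance <- match.arg(provenance)
  if (!is.list(curves) || is.null(names(curves)) || any(names(curves) == "")) {
    stop("'curves' must be a named list of dvh_curve objects", call. = FALSE)
  }
  for (nm in names(curves)) {
    if (!is_dvh_curve(curves[[nm]])) {
      stop(sprintf("curve '%s' is not a dvh_curve", nm), call. = FALSE)
    }
  }
  if (!is.numeric(prescriptions) || is.null(names(prescriptions)) ||
      any(prescriptions <= 0)) {
    stop("'prescriptions' must be a named vector of positive doses (Gy)",
         call. = FALSE)
  }
  if (!is.null(epsilon)) {
    stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0)
  }
  structure(
    list(patient_id = as.character(patient_id),
         curves = curves,
         prescriptions = prescriptions,
         provenance = provenance,
         epsilon = epsilon,
         achievable = achievable),
    class = "plan_record"
  )
}

#' @export
print.plan_record <- function(x, ...) {
  cat(sprintf("<plan_record> %s [%s]: %d structures (%s)\n",
              x$patient_id, x$provenance, length(x$curves),
              paste(names(x$curves), collapse = ", ")))
  if (!is.null(x$epsilon)) cat(sprintf("  planner skill epsilon = %.4f\n", x$epsilon))
  invisible(x)
}

plan_curve <- function(plan, structure) {
  cv <- plan$curves[[structure]]
  if (is.null(cv)) {
    stop(sprintf("structure '%s' not found in plan '%s' (available: %s)",
                 structure, plan$patient_id,
                 paste(names(plan$curves), collapse = ", ")), call. = FALSE)
  }
  cv
}

#' Evaluate a dose metric on one structure of a plan
#'
#' Single dispatch for the scalar DVH endpoints (D_x\%, V_xGy, D_mean,
#' D_x cc, D_min). Volume metrics are returned in percent (0-100), dose
#' metrics in Gy.
#'
#' @param plan A [plan_record()].
#' @param structure Structure name present in the plan.
#' @param spec A [dose_metric()].
#' @return The metric value (Gy or percent).
#' @examples
#' cv <- dvh_curve("Rectum", 60, c(0, 10), c(1, 0))
#' pl <- plan_record("p1", list(Rectum = cv), c(PCTV = 45))
#' evaluate_metric(pl, "Rectum", dose_metric("mean_dose"))
#' @export
evaluate_metric <- function(plan, structure, spec) {
  if (!inherits(plan, "plan_record")) {
    stop("expected a 'plan_record'", call. = FALSE)
  }
  evaluate_metric_on_curve(plan_curve(plan, structure), spec)
}
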