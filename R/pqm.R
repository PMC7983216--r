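#' A single plan-quality criterion
#'
#' One row of a plan quality metric (PQM) table: a dosimetric endpoint on one
#' structure with an acceptable threshold (worth 60\% of the criterion's
#' points), an excellent threshold (full points) and a scoring mode.
#'
#' Modes:
#' \describe{
#'   \item{`threshold`}{0 points on the worse side of `acceptable`;
#'     `0.6 * max_points` exactly at `acceptable`; linear up to `max_points`
#'     at/beyond `excellent`.}
#'   \item{`ci_linear`}{`max_points * CI` (conformity index in \[0, 1\]).}
#'   \item{`hi_linear`}{`max_points * max(0, 1 - HI)` (homogeneity index).}
#' }
#'
#' @param structure Structure name the criterion applies to.
#' @param metric A [dose_metric()], or the string `"CI"` / `"HI"` for the
#'   index criteria.
#' @param direction `"higher_better"` or `"lower_better"` (threshold mode).
#' @param acceptable Acceptable-level threshold (endpoint units).
#' @param excellent Excellent-level threshold, on the better side of
#'   `acceptable`.
#' @param max_points Maximum points for this criterion (> 0).
#' @param mode `"threshold"`, `"ci_linear"` or `"hi_linear"`.
#' @param id Optional short identifier; a readable default is built from the
#'   structure and metric.
#' @return An object of class `pqm_criterion`.
#' @export
criterion <- function(structure, metric, direction = c("lower_better", "higher_better"),
                      acceptable = NA_real_, excellent = NA_real_,
                      max_points, mode = c("threshold", "ci_linear", "hi_linear"),
                      id = NULL) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  stopifnot(is.numeric(max_points), length(max_points) == 1L, max_points > 0)
  if (mode == "threshold") {
    if (!inherits(metric, "dose_metric")) {
      stop("threshold criteria need a dose_metric", call. = FALSE)
    }
    if (!is.finite(acceptable) || !is.finite(excellent)) {
      stop("threshold criteria need finite 'acceptable' and 'excellent' levels",
           call. = FALSE)
    }
    ok <- if (direction == "higher_better") excellent >= acceptable else excellent <= acceptable
    if (!ok) {
      stop("'excellent' must be on the better side of 'acceptable'", call. = FALSE)
    }
  } else {
    if (!identical(metric, "CI") && !identical(metric, "HI")) {
      stop(sprintf("mode '%s' requires metric \"CI\" or \"HI\"", mode),
           call. = FALSE)
    }
    if ((mode == "ci_linear") != identical(metric, "CI")) {
      stop("metric/mode mismatch: CI goes with ci_linear, HI with hi_linear",
           call. = FALSE)
    }
  }
  if (is.null(id)) {
    lab <- if (inherits(metric, "dose_metric")) format_dose_metric(metric) else metric
    id <- paste(structure, lab)
  }
  structure(
    list(id = id, structure = structure, metric = metric,
         direction = direction, acceptable = acceptable,
         excellent = excellent, max_points = max_points, mode = mode),
    class = "pqm_criterion"
  )
}

#' A named, ordered set of plan-quality criteria
#'
#' @param name Set label.
#' @param criteria List of [criterion()] objects.
#' @return An object of class `criteria_set`.
#' @seealso [default_criteria()] for the 100-point pelvic VMAT default.
#' @export
criteria_set <- function(name, criteria) {
  if (!length(criteria) || !all(vapply(criteria, inherits, logical(1), "pqm_criterion"))) {
    stop("'criteria' must be a non-empty list of pqm_criterion objects",
         call. = FALSE)
  }
  structure(list(name = name, criteria = criteria), class = "criteria_set")
}

#' @export
print.criteria_set <- function(x, ...) {
  cat(sprintf("<criteria_set> %s: %d criteria, %g points maximum\n",
              x$name, length(x$criteria), max_total_points(x)))
  for (cr in x$criteria) {
    lab <- if (inherits(cr$metric, "dose_metric")) format_dose_metric(cr$metric) else cr$metric
    if (cr$mode == "threshold") {
      cmp <- if (cr$direction == "lower_better") "<=" else ">="
      cat(sprintf("  %-16s %-14s %s %g / %s %g  -> %g/%g pts\n",
                  cr$structure, lab, cmp, cr$acceptable, cmp, cr$excellent,
                  0.6 * cr$max_points, cr$max_points))
    } else {
      cat(sprintf("  %-16s %-14s linear 0-%g pts\n", cr$structure, lab, cr$max_points))
    }
  }
  invisible(x)
}

#' Maximum attainable points of a criteria set
#' @param set A [criteria_set()].
#' @return Total of `max_points` over the criteria.
#' @export
max_total_points <- function(set) {
  sum(vapply(set$criteria, function(cr) cr$max_points, numeric(1)))
}

#' Default 100-point pelvic VMAT criteria set
#'
#' Nineteen criteria covering the two targets (PGTVnd, prescribed 60 Gy, and
#' PCTV, 45 Gy, in 25 fractions) and seven pelvic organs at risk. Every
#' threshold criterion awards 60\% of its points at the acceptable level and
#' full points at the excellent level; target conformity and homogeneity are
#' scored linearly as `points * CI` and `points * (1 - HI)`. The maxima sum
#' to exactly 100.
#'
#' @return A [criteria_set()] with 19 criteria.
#' @examples
#' set <- default_criteria()
#' max_total_points(set) # 100
#' @export
default_criteria <- function() {
  dm <- dose_metric
  crs <- list(
    criterion("PGTVnd", dm("volume_at_dose", 60), "higher_better", 97, 100, 8),
    criterion("PGTVnd", dm("volume_at_dose", 66), "lower_better", 10, 5, 8),
    criterion("PGTVnd", dm("minimum_dose"), "higher_better", 54.6, 55.8, 5),
    criterion("PGTVnd", "CI", max_points = 2, mode = "ci_linear"),
    criterion("PGTVnd", "HI", max_points = 2, mode = "hi_linear"),
    criterion("PCTV", dm("volume_at_dose", 45), "higher_better", 97, 100, 8),
    criterion("PCTV", dm("volume_at_dose", 49.5), "lower_better", 20, 10, 8),
    criterion("PCTV", dm("minimum_dose"), "higher_better", 40.95, 41.85, 5),
    criterion("PCTV", "CI", max_points = 2, mode = "ci_linear"),
    criterion("PCTV", "HI", max_points = 2, mode = "hi_linear"),
    criterion("SpinalCord", dm("dose_at_absolute_volume", 0.03), "lower_better", 45, 40, 10),
    criterion("Bladder", dm("dose_at_relative_volume", 35), "lower_better", 50, 45, 10),
    criterion("Rectum", dm("dose_at_relative_volume", 60), "lower_better", 45, 40, 10),
    criterion("KidneyL", dm("volume_at_dose", 18), "lower_better", 32, 20, 5),
    criterion("KidneyR", dm("volume_at_dose", 18), "lower_better", 32, 20, 5),
    criterion("FemoralHeadL", dm("volume_at_dose", 35), "lower_better", 50, 15, 3),
    criterion("FemoralHeadL", dm("dose_at_absolute_volume", 0.03), "lower_better", 65, 50, 2),
    criterion("FemoralHeadR", dm("volume_at_dose", 35), "lower_better", 50, 15, 3),
    criterion("FemoralHeadR", dm("dose_at_absolute_volume", 0.03), "lower_better", 65, 50, 2)
  )
  criteria_set("pelvic VMAT 100-point", crs)
}

#' Score one measured value against one criterion
#'
#' Threshold mode: values on the worse side of the acceptable level score 0
#' (hard step); exactly acceptable scores `0.6 * max_points`; between the two
#' levels the score interpolates linearly up to `max_points` at/beyond the
#' excellent level. Index modes score `max_points * CI` and
#' `max_points * (1 - HI)`. Results are clipped to \[0, max_points\].
#'
#' @param value Measured endpoint value (Gy, percent, or CI/HI).
#' @param c A [criterion()].
#' @return Points in \[0, `max_points`\].
#' @examples
#' set <- default_criteria()
#' ci_cr <- set$criteria[[4]]
#' score_criterion(0.84, ci_cr) # 1.68
#' @export
score_criterion <- function(value, c) {
  if (!inherits(c, "pqm_criterion")) stop("expected a 'pqm_criterion'", call. = FALSE)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop("'value' must be a single finite number", call. = FALSE)
  }
  pts <- switch(c$mode,
    ci_linear = {
      if (value < -1e-9 || value > 1 + 1e-9) {
        stop("CI must lie in [0, 1]", call. = FALSE)
      }
      c$max_points * value
    },
    hi_linear = {
      if (value < -1e-9) stop("HI must be non-negative", call. = FALSE)
      c$max_points * (1 - value)
    },
    threshold = {
      acc <- c$acceptable
      exc <- c$excellent
      worse <- if (c$direction == "higher_better") value < acc else value > acc
      if (worse) {
        0
      } else if (acc == exc) {
        c$max_points
      } else {
        t <- (value - acc) / (exc - acc) # positive toward excellent for both directions
        c$max_points * (0.6 + 0.4 * min(max(t, 0), 1))
      }
    })
  min(max(pts, 0), c$max_points)
}

#' Score a whole plan against a criteria set
#'
#' Evaluates every criterion through [evaluate_metric()]; conformity and
#' homogeneity criteria use `ci_hi` values when supplied, otherwise they are
#' computed from the plan (HI from the target curve; CI from the target and
#' body curves at `iso_fraction` of the target's prescription).
#'
#' @param plan A [plan_record()] containing every structure the set references.
#' @param set A [criteria_set()] (default [default_criteria()]).
#' @param ci_hi Optional named list, one entry per target, each a list with
#'   elements `ci` and/or `hi`, e.g. `list(PGTVnd = list(ci = 0.84, hi = 0.05))`.
#' @param iso_fraction Reference isodose fraction for derived CI (default 0.95).
#' @return A `pqm_report`: data frame of per-criterion values and points plus
#'   the total.
#' @export
score_plan <- function(plan, set = default_criteria(), ci_hi = NULL,
                       iso_fraction = 0.95) {
  if (!inherits(plan, "plan_record")) stop("expected a 'plan_record'", call. = FALSE)
  if (!inherits(set, "criteria_set")) stop("expected a 'criteria_set'", call. = FALSE)
  needed <- unique(vapply(set$criteria, function(cr) cr$structure, character(1)))
  missing <- setdiff(needed, names(plan$curves))
  if (length(missing)) {
    stop(sprintf("plan '%s' is missing structures required by the criteria set: %s",
                 plan$patient_id, paste(missing, collapse = ", ")), call. = FALSE)
  }
  rows <- lapply(set$criteria, function(cr) {
    value <- if (cr$mode == "threshold") {
      evaluate_metric(plan, cr$structure, cr$metric)
    } else if (cr$mode == "ci_linear") {
      supplied <- ci_hi[[cr$structure]]$ci
      if (!is.null(supplied)) supplied else {
        rx <- plan$prescriptions[[cr$structure]]
        if (is.null(rx)) stop(sprintf("no prescription for target '%s'", cr$structure),
                              call. = FALSE)
        plan_conformity_index(plan_curve(plan, cr$structure),
                              plan_curve(plan, "BODY"), rx, iso_fraction)
      }
    } else {
      supplied <- ci_hi[[cr$structure]]$hi
      if (!is.null(supplied)) supplied else {
        homogeneity_index(plan_curve(plan, cr$structure))
      }
    }
    data.frame(id = cr$id, structure = cr$structure, value = value,
               points = score_criterion(value, cr),
               max_points = cr$max_points, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  structure(list(patient_id = plan$patient_id, per_criterion = per,
                 total = sum(per$points)),
            class = "pqm_report")
}

#' @export
print.pqm_report <- function(x, ...) {
  cat(sprintf("<pqm_report> plan %s: total %.2f / %g\n", x$patient_id,
              x$total, sum(x$per_criterion$max_points)))
  df <- x$per_criterion
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-34s %8.3f -> %5.2f / %g\n", df$id[i], df$value[i],
                df$points[i], df$max_points[i]))
  }
  invisible(x)
}
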