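#' Cumulative dose-volume histogram for one structure
#'
#' A cumulative DVH gives, for each dose level, the fraction of the structure
#' receiving at least that dose. `dvh_curve()` validates and normalizes the
#' curve: the dose grid must be strictly increasing and start at 0 Gy, the
#' relative-volume track must start at 1, stay within \[0, 1\] and be
#' non-increasing. Single increasing glitches no larger than `1e-9` (floating
#' point noise from interchange files) are repaired silently by a running
#' minimum; anything larger is rejected.
#'
#' @param structure_name Structure label, e.g. `"Bladder"`.
#' @param volume_cc Absolute structure volume in cc (> 0).
#' @param dose_gy Strictly increasing dose samples in Gy, first element 0.
#' @param rel_volume Relative volumes (fraction of structure in \[0, 1\]),
#'   same length as `dose_gy`, starting at 1.
#' @return An object of class `dvh_curve`.
#' @examples
#' cv <- dvh_curve("Bladder", 200, c(0, 10, 20), c(1, 0.5, 0))
#' volume_at_dose(cv, 15)
#' @export
dvh_curve <- function(structure_name, volume_cc, dose_gy, rel_volume) {
  if (!is.character(structure_name) || length(structure_name) != 1L) {
    stop("'structure_name' must be a single string", call. = FALSE)
  }
  if (!is.numeric(volume_cc) || length(volume_cc) != 1L ||
      !is.finite(volume_cc) || volume_cc <= 0) {
    stop("'volume_cc' must be a single positive number", call. = FALSE)
  }
  dose_gy <- as.numeric(dose_gy)
  rel_volume <- as.numeric(rel_volume)
  if (length(dose_gy) != length(rel_volume) || length(dose_gy) < 2L) {
    stop("'dose_gy' and 'rel_volume' must have equal length >= 2",
         call. = FALSE)
  }
  if (anyNA(dose_gy) || anyNA(rel_volume)) {
    stop("DVH samples must be finite", call. = FALSE)
  }
  if (abs(dose_gy[1L]) > 1e-12) {
    stop("dose grid must start at 0 Gy", call. = FALSE)
  }
  dose_gy[1L] <- 0
  if (any(diff(dose_gy) <= 0)) {
    stop("dose grid must be strictly increasing", call. = FALSE)
  }
  if (any(rel_volume < -1e-9) || any(rel_volume > 1 + 1e-9)) {
    stop(sprintf("relative volumes outside [0, 1] for structure '%s'",
                 structure_name), call. = FALSE)
  }
  if (abs(rel_volume[1L] - 1) > 1e-9) {
    stop(sprintf("cumulative DVH must start at relative volume 1 (structure '%s')",
                 structure_name), call. = FALSE)
  }
  inc <- diff(rel_volume)
  if (any(inc > 1e-9)) {
    stop(sprintf("non-monotone cumulative DVH for structure '%s' (increase %.3g)",
                 structure_name, max(inc)), call. = FALSE)
  }
  rel_volume[1L] <- 1
  rel_volume <- pmin(pmax(cummin(rel_volume), 0), 1)
  structure(
    list(structure_name = structure_name,
         volume_cc = volume_cc,
         dose_gy = dose_gy,
         rel_volume = rel_volume),
    class = "dvh_curve"
  )
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %s: %.1f cc, %d samples over [0, %.2f] Gy, D_mean %.2f Gy\n",
              x$structure_name, x$volume_cc, length(x$dose_gy),
              max(x$dose_gy), mean_dose(x)))
  invisible(x)
}

is_dvh_curve <- function(x) inherits(x, "dvh_curve")

# Fast internal constructor for curves whose invariants hold by
# construction (resampling, dilation, model output post-processing).
new_dvh_curve <- function(structure_name, volume_cc, dose_gy, rel_volume) {
  structure(list(structure_name = structure_name, volume_cc = volume_cc,
                 dose_gy = dose_gy, rel_volume = rel_volume),
            class = "dvh_curve")
}

assert_dvh_curve <- function(x) {
  if (!is_dvh_curve(x)) stop("expected a 'dvh_curve' object", call. = FALSE)
  invisible(x)
}

#' Fraction of a structure receiving at least a given dose
#'
#' Linear interpolation of the cumulative DVH; doses beyond the end of the
#' grid return the last tabulated value.
#'
#' @param curve A [dvh_curve()].
#' @param dose Dose in Gy (>= 0).
#' @return Fraction of the structure volume in \[0, 1\].
#' @export
volume_at_dose <- function(curve, dose) {
  assert_dvh_curve(curve)
  if (!is.numeric(dose) || any(dose < 0) || anyNA(dose)) {
    stop("'dose' must be non-negative", call. = FALSE)
  }
  stats::approx(curve$dose_gy, curve$rel_volume, xout = dose,
                method = "linear", rule = 2, ties = "ordered")$y
}

#' Largest dose at which relative volume still reaches a given fraction
#'
#' Inverse linear interpolation of the cumulative DVH (the D_x% family of
#' metrics). `fraction = 1` returns the end of the full-coverage plateau
#' (largest dose with relative volume >= 1 - 1e-9).
#'
#' @param curve A [dvh_curve()].
#' @param fraction Volume fraction in \[0, 1\].
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(curve, fraction) {
  assert_dvh_curve(curve)
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction > 1) {
    stop("'fraction' must be a single value in [0, 1]", call. = FALSE)
  }
  d <- curve$dose_gy
  v <- curve$rel_volume
  f <- if (fraction >= 1) 1 - 1e-9 else fraction
  n <- length(v)
  if (f <= v[n]) return(d[n])
  i <- max(which(v >= f))          # v[i] >= f > v[i + 1]
  d[i] + (v[i] - f) / (v[i] - v[i + 1L]) * (d[i + 1L] - d[i])
}

#' Mean structure dose from a cumulative DVH
#'
#' Trapezoid-rule integral of the cumulative curve over dose, which equals the
#' mean of the corresponding differential DVH.
#'
#' @param curve A [dvh_curve()].
#' @return Mean dose in Gy.
#' @export
mean_dose <- function(curve) {
  assert_dvh_curve(curve)
  d <- curve$dose_gy
  v <- curve$rel_volume
  sum(diff(d) * (v[-length(v)] + v[-1L]) / 2)
}

#' Near-maximum dose: dose to the hottest absolute sub-volume
#'
#' The D_x cc family (e.g. spinal cord D_0.03cc): the minimum dose received by
#' the hottest `cc` of the structure, via [dose_at_volume()] at the fraction
#' `cc / volume_cc`.
#'
#' @param curve A [dvh_curve()].
#' @param cc Absolute volume in cc, 0 < cc <= `curve$volume_cc`.
#' @return Dose in Gy.
#' @export
dose_at_absolute_volume <- function(curve, cc) {
  assert_dvh_curve(curve)
  if (!is.numeric(cc) || length(cc) != 1L || is.na(cc) || cc <= 0) {
    stop("'cc' must be a single positive volume", call. = FALSE)
  }
  if (cc > curve$volume_cc) {
    stop(sprintf("requested sub-volume %.3f cc exceeds structure volume %.3f cc",
                 cc, curve$volume_cc), call. = FALSE)
  }
  dose_at_volume(curve, cc / curve$volume_cc)
}

#' Minimum structure dose
#'
#' The end of the full-coverage plateau: the largest dose at which the
#' relative volume is still >= 1 - 1e-6.
#'
#' @param curve A [dvh_curve()].
#' @return Dose in Gy.
#' @export
minimum_dose <- function(curve) {
  assert_dvh_curve(curve)
  d <- curve$dose_gy
  v <- curve$rel_volume
  f <- 1 - 1e-6
  n <- length(v)
  if (f <= v[n]) return(d[n])
  i <- max(which(v >= f))
  d[i] + (v[i] - f) / (v[i] - v[i + 1L]) * (d[i + 1L] - d[i])
}

#' Resample a DVH onto a new dose grid
#'
#' Linear re-interpolation onto `grid`; monotonicity and the \[0, 1\] bounds
#' are preserved by construction.
#'
#' @param curve A [dvh_curve()].
#' @param grid Ascending dose grid starting at 0 Gy.
#' @return A [dvh_curve()] on `grid`.
#' @export
resample_dvh <- function(curve, grid) {
  assert_dvh_curve(curve)
  grid <- as.numeric(grid)
  if (length(grid) < 2L || abs(grid[1L]) > 1e-12 || any(diff(grid) <= 0)) {
    stop("'grid' must be strictly increasing from 0", call. = FALSE)
  }
  v <- stats::approx(curve$dose_gy, curve$rel_volume, xout = grid,
                     method = "linear", rule = 2, ties = "ordered")$y
  v[1L] <- 1
  new_dvh_curve(curve$structure_name, curve$volume_cc, grid, v)
}

#' Specification of a scalar dose metric
#'
#' A `dose_metric` names one of the standard DVH endpoints:
#' \describe{
#'   \item{`dose_at_relative_volume`}{D_x\% — dose to the hottest x\% of the
#'     structure; `parameter` = x in percent.}
#'   \item{`volume_at_dose`}{V_xGy — percent of the structure receiving at
#'     least x Gy; `parameter` = x in Gy.}
#'   \item{`mean_dose`}{D_mean; no parameter.}
#'   \item{`dose_at_absolute_volume`}{D_x cc; `parameter` = x in cc.}
#'   \item{`minimum_dose`}{D_min; no parameter.}
#' }
#'
#' @param kind One of the five endpoint kinds above.
#' @param parameter Numeric parameter as required by `kind` (percent in
#'   \[0, 100\], Gy >= 0 or cc > 0); ignored for `mean_dose`/`minimum_dose`.
#' @return An object of class `dose_metric`.
#' @examples
#' dose_metric("volume_at_dose", 18)          # V_18Gy
#' dose_metric("dose_at_relative_volume", 35) # D_35%
#' @export
dose_metric <- function(kind, parameter = NA_real_) {
  kind <- match.arg(kind, c("dose_at_relative_volume", "volume_at_dose",
                            "mean_dose", "dose_at_absolute_volume",
                            "minimum_dose"))
  parameter <- as.numeric(parameter)
  ok <- switch(kind,
    dose_at_relative_volume = is.finite(parameter) && parameter >= 0 && parameter <= 100,
    volume_at_dose = is.finite(parameter) && parameter >= 0,
    dose_at_absolute_volume = is.finite(parameter) && parameter > 0,
    TRUE)
  if (!ok) stop(sprintf("parameter %s out of domain for metric '%s'",
                        format(parameter), kind), call. = FALSE)
  structure(list(kind = kind, parameter = parameter), class = "dose_metric")
}

#' @export
print.dose_metric <- function(x, ...) {
  cat(format_dose_metric(x), "\n")
  invisible(x)
}

format_dose_metric <- function(x) {
  switch(x$kind,
    dose_at_relative_volume = sprintf("D_%g%% (Gy)", x$parameter),
    volume_at_dose = sprintf("V_%gGy (%%)", x$parameter),
    mean_dose = "D_mean (Gy)",
    dose_at_absolute_volume = sprintf("D_%gcc (Gy)", x$parameter),
    minimum_dose = "D_min (Gy)")
}

# Evaluate a dose_metric on a single curve. V_xGy is reported in percent
# (0-100) to match clinical tables; doses in Gy.
evaluate_metric_on_curve <- function(curve, spec) {
  if (!inherits(spec, "dose_metric")) {
    stop("expected a 'dose_metric' specification", call. = FALSE)
  }
  switch(spec$kind,
    dose_at_relative_volume = dose_at_volume(curve, spec$parameter / 100),
    volume_at_dose = 100 * volume_at_dose(curve, spec$parameter),
    mean_dose = mean_dose(curve),
    dose_at_absolute_volume = dose_at_absolute_volume(curve, spec$parameter),
    minimum_dose = minimum_dose(curve))
}
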