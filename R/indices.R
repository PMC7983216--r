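#' Conformity index of a target dose distribution
#'
#' CI = (V_Tref / V_T) x (V_Tref / V_ref): the product of target coverage and
#' dose selectivity at the reference isodose. `V_T` is the target volume,
#' `V_Tref` the target volume covered by the reference isodose and `V_ref`
#' the total volume enclosed by the reference isodose. CI lies in \[0, 1\]
#' and equals 1 only for perfect conformity.
#'
#' @param v_t Target volume in cc (> 0).
#' @param v_tref Target volume covered by the reference isodose, cc;
#'   0 <= `v_tref` <= min(`v_t`, `v_ref`).
#' @param v_ref Total volume of the reference isodose in cc (> 0).
#' @return Dimensionless CI in \[0, 1\].
#' @examples
#' conformity_index(v_t = 100, v_tref = 90, v_ref = 150) # 0.54
#' @export
conformity_index <- function(v_t, v_tref, v_ref) {
  stopifnot(is.numeric(v_t), is.numeric(v_tref), is.numeric(v_ref))
  if (!is.finite(v_t) || v_t <= 0 || !is.finite(v_ref) || v_ref <= 0) {
    stop("'v_t' and 'v_ref' must be positive", call. = FALSE)
  }
  if (!is.finite(v_tref) || v_tref < 0 || v_tref > min(v_t, v_ref) + 1e-9) {
    stop("'v_tref' must satisfy 0 <= v_tref <= min(v_t, v_ref)", call. = FALSE)
  }
  (v_tref / v_t) * (v_tref / v_ref)
}

#' Conformity-index volumes from plan DVHs
#'
#' Derives the three CI volumes at `iso_fraction` of the prescription dose:
#' `V_T` from the target's absolute volume, `V_Tref` from the target DVH and
#' `V_ref` from the body (external contour) DVH. The same reference isodose
#' fraction (default 95\%) is applied to both the covered-target volume and
#' the reference-isodose volume.
#'
#' @param target Target [dvh_curve()].
#' @param body Body [dvh_curve()] carrying the external-contour volume.
#' @param rx Prescription dose in Gy (> 0).
#' @param iso_fraction Reference isodose as a fraction of `rx` (default 0.95).
#' @return A list with `v_t`, `v_tref`, `v_ref` (cc).
#' @export
ci_inputs_from_plan <- function(target, body, rx, iso_fraction = 0.95) {
  assert_dvh_curve(target)
  if (!is_dvh_curve(body)) {
    stop("a body (external contour) curve is required to derive V_ref",
         call. = FALSE)
  }
  stopifnot(is.numeric(rx), length(rx) == 1L, rx > 0,
            is.numeric(iso_fraction), iso_fraction >= 0, iso_fraction <= 1)
  iso_dose <- iso_fraction * rx
  v_t <- target$volume_cc
  v_tref <- v_t * volume_at_dose(target, iso_dose)
  v_ref <- body$volume_cc * volume_at_dose(body, iso_dose)
  list(v_t = v_t, v_tref = min(v_tref, v_ref), v_ref = v_ref)
}

#' Conformity index of a plan target
#'
#' Convenience wrapper: [ci_inputs_from_plan()] followed by
#' [conformity_index()].
#'
#' @inheritParams ci_inputs_from_plan
#' @return Dimensionless CI in \[0, 1\].
#' @export
plan_conformity_index <- function(target, body, rx, iso_fraction = 0.95) {
  ins <- ci_inputs_from_plan(target, body, rx, iso_fraction)
  conformity_index(ins$v_t, ins$v_tref, ins$v_ref)
}

#' Homogeneity index of a target dose distribution
#'
#' HI = (D_2\% - D_98\%) / D_50\%, where D_x\% is the dose received by the
#' hottest x\% of the target. HI is 0 for a perfectly uniform target dose
#' and grows with the dose spread.
#'
#' @param curve Target [dvh_curve()].
#' @return Dimensionless HI (>= 0 for valid monotone curves).
#' @examples
#' # near-rectangular target: small HI
#' cv <- dvh_curve("PGTVnd", 100, c(0, 58, 62), c(1, 1, 0))
#' homogeneity_index(cv)
#' @export
homogeneity_index <- function(curve) {
  assert_dvh_curve(curve)
  d2 <- dose_at_volume(curve, 0.02)
  d98 <- dose_at_volume(curve, 0.98)
  d50 <- dose_at_volume(curve, 0.50)
  if (d50 <= 0) stop("D_50% is zero; homogeneity index undefined", call. = FALSE)
  (d2 - d98) / d50
}
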