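#' Configuration of the synthetic pelvic cohort
#'
#' The generator emulates a pelvic VMAT cohort: two targets (PGTVnd
#' prescribed 60 Gy and PCTV 45 Gy, in 25 fractions), seven organs at risk
#' (spinal cord, bladder, rectum, kidneys L/R, femoral heads L/R) and a body
#' contour, with per-patient anatomy drawn from the distributions below and
#' planner skill modeled as a single excess-dose parameter `epsilon`
#' (half-normal with scale `sigma_eps`).
#'
#' Per-OAR anatomy priors (overlap fraction `f` = scale x Beta(a, b); fall-off
#' scale `tau` log-normal; organ volume uniform):
#' bladder/rectum `f ~ 0.6 Beta(4, 4)`, femoral heads `f ~ 0.2 Beta(2, 8)`,
#' kidneys `f ~ 0.03 Beta(2, 8)` (essentially no overlap), spinal cord
#' `f = 0`.
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer seed making the cohort reproducible.
#' @param sigma_eps Scale of the half-normal planner-skill distribution
#'   (default 0.08, i.e. typical excess dose of a few percent).
#' @param h Target dose-spread half-width as a fraction of prescription
#'   (default 0.03, giving near-rectangular target DVHs with HI around 0.05).
#' @param grid Dose grid in Gy for all generated curves.
#' @param id_prefix Prefix for patient identifiers.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, seed = 1L, sigma_eps = 0.08, h = 0.03,
                          grid = seq(0, 75, by = 0.05), id_prefix = "SYN") {
  stopifnot(n_patients >= 1, sigma_eps >= 0, h > 0, h < 0.5)
  oars <- list(
    SpinalCord   = list(f_scale = 0,    f_a = 1, f_b = 1, tau_meanlog = log(2),  tau_sdlog = 0.30, vol_min = 25,  vol_max = 45),
    Bladder      = list(f_scale = 0.6,  f_a = 4, f_b = 4, tau_meanlog = log(15), tau_sdlog = 0.25, vol_min = 100, vol_max = 400),
    Rectum       = list(f_scale = 0.6,  f_a = 4, f_b = 4, tau_meanlog = log(15), tau_sdlog = 0.25, vol_min = 40,  vol_max = 100),
    KidneyL      = list(f_scale = 0.03, f_a = 2, f_b = 8, tau_meanlog = log(4),  tau_sdlog = 0.30, vol_min = 120, vol_max = 200),
    KidneyR      = list(f_scale = 0.03, f_a = 2, f_b = 8, tau_meanlog = log(4),  tau_sdlog = 0.30, vol_min = 120, vol_max = 200),
    FemoralHeadL = list(f_scale = 0.2,  f_a = 2, f_b = 8, tau_meanlog = log(9),  tau_sdlog = 0.25, vol_min = 80,  vol_max = 150),
    FemoralHeadR = list(f_scale = 0.2,  f_a = 2, f_b = 8, tau_meanlog = log(9),  tau_sdlog = 0.25, vol_min = 80,  vol_max = 150)
  )
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    sigma_eps = sigma_eps, h = h, grid = grid, id_prefix = id_prefix,
    prescriptions = c(PGTVnd = 60, PCTV = 45),
    oars = oars,
    pgtv_vol = c(40, 150), pctv_vol = c(800, 1600),
    body_vol = c(6000, 9000), tau_body = 13
  ), class = "cohort_config")
}

# Near-rectangular cumulative target-region curve used inside achievable OAR
# DVHs: full coverage up to rx*(1-h), linear fall to zero at rx*(1+h).
target_region_curve <- function(dose, rx, h) {
  lo <- rx * (1 - h)
  hi <- rx * (1 + h)
  pmin(pmax((hi - dose) / (hi - lo), 0), 1)
}

#' Best-effort (achievable) OAR DVH from geometry features
#'
#' The ground-truth dose-limit model of the synthetic world:
#' `V(D) = f T(D) + (1 - f) exp(-D / tau)`, where `T(D)` is the cumulative
#' target-region curve (full coverage up to `rx (1 - h)`, linear to zero at
#' `rx (1 + h)`). The overlap fraction `f` pins part of the organ to
#' target-level doses; the rest sees an exponential fall-off with scale
#' `tau`.
#'
#' @param features A [geometry_features()] for the organ.
#' @param rx Prescription dose in Gy governing the target-region curve.
#' @param grid Dose grid in Gy.
#' @param h Target dose-spread half-width (default 0.03).
#' @param structure_name Structure label for the returned curve.
#' @return A [dvh_curve()].
#' @export
achievable_dvh <- function(features, rx, grid = seq(0, 75, by = 0.05),
                           h = 0.03, structure_name = "OAR") {
  if (!inherits(features, "geometry_features")) {
    stop("expected 'geometry_features'", call. = FALSE)
  }
  if (features$tau <= 0) stop("'tau' must be positive", call. = FALSE)
  grid <- as.numeric(grid)
  v <- features$f * target_region_curve(grid, rx, h) +
    (1 - features$f) * exp(-grid / features$tau)
  v[1L] <- 1
  new_dvh_curve(structure_name, features$organ_volume, grid,
                pmin(pmax(v, 0), 1))
}

# Target-structure DVH: near-rectangular plateau centered slightly above the
# prescription so that coverage at rx is realistic (~98-99%).
target_structure_curve <- function(rx, volume_cc, grid, h, structure_name) {
  mu <- rx * (1 + h)
  v <- target_region_curve(grid, mu, h)
  new_dvh_curve(structure_name, volume_cc, as.numeric(grid), v)
}

# Body DVH: volume-weighted mix of the two target curves plus an exponential
# background fall-off, so conformity indices are computable and land in a
# plausible 0.5-0.85 range.
body_curve <- function(patient, config) {
  grid <- config$grid
  w <- patient$body_volume
  vt1 <- patient$target_volumes[["PGTVnd"]]
  vt2 <- patient$target_volumes[["PCTV"]]
  bg <- w - vt1 - vt2
  v <- (vt1 * patient$target_curves$PGTVnd$rel_volume +
          vt2 * patient$target_curves$PCTV$rel_volume +
          bg * exp(-grid / config$tau_body)) / w
  new_dvh_curve("BODY", w, as.numeric(grid), pmin(pmax(v, 0), 1))
}

#' Sample one synthetic patient's geometry
#'
#' Draws per-OAR geometry features and target/body volumes from the cohort
#' priors using the current RNG state, and derives the achievable DVHs.
#'
#' @param config A [cohort_config()].
#' @param patient_id Identifier for the patient.
#' @return A list of class `synthetic_patient` with `features` (per-OAR
#'   [geometry_features()]), `target_volumes`, `body_volume`, `target_curves`,
#'   `achievable` (per-OAR curves) and `body`.
#' @export
sample_geometry <- function(config, patient_id = "SYN-1") {
  if (!inherits(config, "cohort_config")) stop("expected a 'cohort_config'",
                                               call. = FALSE)
  vt1 <- stats::runif(1, config$pgtv_vol[1], config$pgtv_vol[2])
  vt2 <- stats::runif(1, config$pctv_vol[1], config$pctv_vol[2])
  wb <- stats::runif(1, config$body_vol[1], config$body_vol[2])
  target_total <- vt1 + vt2
  features <- list()
  for (oar in names(config$oars)) {
    pr <- config$oars[[oar]]
    f <- if (pr$f_scale > 0) pr$f_scale * stats::rbeta(1, pr$f_a, pr$f_b) else 0
    tau <- stats::rlnorm(1, pr$tau_meanlog, pr$tau_sdlog)
    vol <- stats::runif(1, pr$vol_min, pr$vol_max)
    features[[oar]] <- geometry_features(f, tau, vol, target_total)
  }
  rx_oar <- config$prescriptions[["PCTV"]]
  achievable <- lapply(names(features), function(oar)
    achievable_dvh(features[[oar]], rx_oar, config$grid, config$h, oar))
  names(achievable) <- names(features)
  target_curves <- list(
    PGTVnd = target_structure_curve(config$prescriptions[["PGTVnd"]], vt1,
                                    config$grid, config$h, "PGTVnd"),
    PCTV = target_structure_curve(config$prescriptions[["PCTV"]], vt2,
                                  config$grid, config$h, "PCTV"))
  patient <- list(patient_id = patient_id, features = features,
                  target_volumes = c(PGTVnd = vt1, PCTV = vt2),
                  body_volume = wb, target_curves = target_curves,
                  achievable = achievable,
                  prescriptions = config$prescriptions)
  patient$body <- body_curve(patient, config)
  class(patient) <- "synthetic_patient"
  patient
}

# Dose-axis dilation of an achievable curve by (1 + epsilon): the planned
# curve delivers every volume level at (1 + epsilon) times the achievable
# dose, i.e. V_planned(D) = V_achievable(D / (1 + epsilon)).
dilate_curve <- function(curve, epsilon) {
  if (epsilon == 0) return(curve)
  v <- stats::approx(curve$dose_gy, curve$rel_volume,
                     xout = curve$dose_gy / (1 + epsilon),
                     method = "linear", rule = 2, ties = "ordered")$y
  v[1L] <- 1
  new_dvh_curve(curve$structure_name, curve$volume_cc, curve$dose_gy,
                pmin(pmax(cummin(v), 0), 1))
}

#' Realize a plan from a synthetic patient at a given skill level
#'
#' Planner skill is a single excess-dose parameter: every OAR curve is the
#' achievable curve dilated along the dose axis by `1 + epsilon` (a perfect
#' planner, `epsilon = 0`, delivers the achievable DVHs exactly). Target and
#' body curves are left unchanged — target coverage is preserved regardless
#' of skill.
#'
#' @param patient A `synthetic_patient` from [sample_geometry()].
#' @param epsilon Excess-dose parameter (>= 0).
#' @return A [plan_record()] carrying `epsilon` and the achievable curves.
#' @export
plan_with_skill <- function(patient, epsilon) {
  if (!inherits(patient, "synthetic_patient")) {
    stop("expected a 'synthetic_patient'", call. = FALSE)
  }
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0)
  curves <- c(
    patient$target_curves,
    lapply(patient$achievable, dilate_curve, epsilon = epsilon),
    list(BODY = patient$body))
  plan_record(patient$patient_id, curves, patient$prescriptions,
              provenance = "synthetic", epsilon = epsilon,
              achievable = patient$achievable)
}

#' Generate a synthetic plan database
#'
#' Samples `n_patients` anatomies, draws planner skill
#' `epsilon ~ half-normal(sigma_eps)` for each, and emits database entries
#' ready for [fit_kbp_model()]. Deterministic under the config seed.
#'
#' @param config A [cohort_config()].
#' @return List of entries, each with elements `plan` ([plan_record()]),
#'   `features` (per-OAR [geometry_features()]) and `patient`
#'   (`synthetic_patient`).
#' @examples
#' db <- generate_cohort(cohort_config(n_patients = 5, seed = 42))
#' length(db)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("expected a 'cohort_config'",
                                               call. = FALSE)
  set.seed(config$seed)
  lapply(seq_len(config$n_patients), function(i) {
    patient <- sample_geometry(config, sprintf("%s-%03d", config$id_prefix, i))
    eps <- abs(stats::rnorm(1, 0, config$sigma_eps))
    if (config$sigma_eps == 0) eps <- 0
    list(plan = plan_with_skill(patient, eps),
         features = patient$features,
         patient = patient)
  })
}
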