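# Shared fixtures, all built in code.

simple_curve <- function() {
  dvh_curve("S", 60, c(0, 10, 20), c(1, 0.5, 0))
}

# Random piecewise-linear cumulative DVH with nodes on 0.001 Gy multiples
# (so a 0.001 Gy brute-force grid reproduces it exactly).
random_curve <- function(n_nodes = 8, max_dose = 60) {
  d <- sort(sample(seq(0.001, max_dose, by = 0.001), n_nodes - 1L))
  v <- sort(stats::runif(n_nodes - 1L, 0, 0.999), decreasing = TRUE)
  dvh_curve("R", stats::runif(1, 50, 300), c(0, d), c(1, v))
}

# Coarse-grid cohort config for tests that do not probe grid resolution.
coarse_cfg <- function(n, seed, sigma_eps = 0.08) {
  cohort_config(n, seed = seed, sigma_eps = sigma_eps,
                grid = seq(0, 75, by = 0.25))
}

coarse_kbp_cfg <- function(...) {
  kbp_config(grid = seq(0, 75, by = 0.25), ...)
}

# Database of n copies of one plan (distinct ids): zero-variance world where
# the model must reproduce the training curve exactly.
identical_entries <- function(n = 6, seed = 5) {
  set.seed(seed)
  patient <- sample_geometry(coarse_cfg(1, seed), "TWIN")
  lapply(seq_len(n), function(i) {
    plan <- plan_with_skill(patient, 0)
    plan$patient_id <- sprintf("TWIN-%02d", i)
    list(plan = plan, features = patient$features, patient = patient)
  })
}

# An all-excellent plan: every threshold criterion at/beyond its excellent
# level (CI/HI supplied separately when scoring).
all_excellent_plan <- function() {
  cv <- function(name, vol, d, v) dvh_curve(name, vol, d, v)
  curves <- list(
    PGTVnd = cv("PGTVnd", 100, c(0, 61, 61.5), c(1, 1, 0)),
    PCTV = cv("PCTV", 1000, c(0, 46, 46.4), c(1, 1, 0)),
    SpinalCord = cv("SpinalCord", 30, c(0, 10, 20), c(1, 0.5, 0)),
    Bladder = cv("Bladder", 200, c(0, 40, 44), c(1, 0.4, 0)),
    Rectum = cv("Rectum", 60, c(0, 30, 40), c(1, 0.5, 0)),
    KidneyL = cv("KidneyL", 150, c(0, 15, 20), c(1, 0.1, 0)),
    KidneyR = cv("KidneyR", 150, c(0, 15, 20), c(1, 0.1, 0)),
    FemoralHeadL = cv("FemoralHeadL", 100, c(0, 15, 20), c(1, 0.1, 0)),
    FemoralHeadR = cv("FemoralHeadR", 100, c(0, 15, 20), c(1, 0.1, 0)))
  plan_record("EXC", curves, c(PGTVnd = 60, PCTV = 45), provenance = "CP")
}

# A plan failing every acceptable threshold.
all_failing_plan <- function() {
  cv <- function(name, vol, d, v) dvh_curve(name, vol, d, v)
  curves <- list(
    PGTVnd = cv("PGTVnd", 100, c(0, 66, 70), c(1, 0.12, 0)),
    PCTV = cv("PCTV", 1000, c(0, 49.5, 60), c(1, 0.25, 0)),
    SpinalCord = cv("SpinalCord", 30, c(0, 46, 47), c(1, 1, 0)),
    Bladder = cv("Bladder", 200, c(0, 52, 53), c(1, 1, 0)),
    Rectum = cv("Rectum", 60, c(0, 52, 53), c(1, 1, 0)),
    KidneyL = cv("KidneyL", 150, c(0, 30, 40), c(1, 1, 0)),
    KidneyR = cv("KidneyR", 150, c(0, 30, 40), c(1, 1, 0)),
    FemoralHeadL = cv("FemoralHeadL", 100, c(0, 66, 67), c(1, 1, 0)),
    FemoralHeadR = cv("FemoralHeadR", 100, c(0, 66, 67), c(1, 1, 0)))
  plan_record("BAD", curves, c(PGTVnd = 60, PCTV = 45), provenance = "MP")
}

# Independent tie-averaged rank-point oracle: explicit loop over distinct
# error values.
oracle_rank_points <- function(errors) {
  m <- length(errors)
  pts <- numeric(m)
  pos <- 1L
  for (e in sort(unique(errors))) {
    idx <- which(errors == e)
    span <- pos:(pos + length(idx) - 1L)
    pts[idx] <- mean(m + 1 - span)
    pos <- pos + length(idx)
  }
  pts
}
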