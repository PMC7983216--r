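test_that("volume_at_dose interpolates linearly and saturates beyond the grid", {
  cv <- simple_curve()
  expect_equal(volume_at_dose(cv, 0), 1)
  expect_equal(volume_at_dose(cv, 25), 0)
  expect_equal(volume_at_dose(cv, 15), 0.25)
})

test_that("dose_at_volume inverts the curve, including the full-coverage edge", {
  cv <- simple_curve()
  expect_equal(dose_at_volume(cv, 0.5), 10)
  expect_equal(dose_at_volume(cv, 1), 0, tolerance = 1e-6)
  expect_equal(dose_at_volume(cv, 0.25), 15)
  expect_error(dose_at_volume(cv, 1.2), "\\[0, 1\\]")
})

test_that("volume_at_dose and dose_at_volume are mutual inverses on strictly decreasing curves", {
  set.seed(101)
  for (i in 1:25) {
    cv <- random_curve()
    for (f in stats::runif(5, min(cv$rel_volume) + 1e-6, 1 - 1e-6)) {
      d <- dose_at_volume(cv, f)
      expect_equal(volume_at_dose(cv, d), f, tolerance = 1e-9)
    }
  }
})

test_that("mean_dose equals the trapezoid integral and scales with the dose axis", {
  expect_equal(mean_dose(dvh_curve("S", 60, c(0, 10), c(1, 0))), 5)
  expect_equal(mean_dose(dvh_curve("S", 60, c(0, 10, 20), c(1, 1, 0))), 15)
  expect_equal(mean_dose(dvh_curve("S", 60, c(0, 1), c(1, 1))), 1)
  set.seed(102)
  for (i in 1:10) {
    cv <- random_curve()
    k <- stats::runif(1, 0.5, 2)
    scaled <- dvh_curve(cv$structure_name, cv$volume_cc, k * cv$dose_gy,
                        cv$rel_volume)
    expect_equal(mean_dose(scaled), k * mean_dose(cv), tolerance = 1e-12)
  }
})

test_that("dose_at_absolute_volume handles the near-maximum endpoint", {
  cv <- dvh_curve("S", 60, c(0, 50), c(1, 0))
  expect_equal(dose_at_absolute_volume(cv, 0.03), 49.975)
  # whole structure -> back at the full-coverage edge
  expect_equal(dose_at_absolute_volume(simple_curve(), 60), 0, tolerance = 1e-6)
  cv2 <- dvh_curve("S", 60, c(0, 10, 20), c(1, 0.5, 0))
  expect_equal(dose_at_absolute_volume(cv2, 30), 10)
  expect_error(dose_at_absolute_volume(cv2, 61), "exceeds structure volume")
})

test_that("minimum_dose finds the end of the full-coverage plateau", {
  expect_equal(minimum_dose(dvh_curve("S", 60, c(0, 10, 20), c(1, 1, 0))), 10,
               tolerance = 1e-4)
  expect_equal(minimum_dose(simple_curve()), 0, tolerance = 1e-4)
  # near-rectangular target with full coverage until 58 Gy
  grid <- seq(0, 75, by = 0.05)
  v <- pmin(pmax((62 - grid) / 4, 0), 1)
  cv <- dvh_curve("T", 100, grid, v)
  expect_equal(minimum_dose(cv), 58, tolerance = 1e-3)
})

test_that("curve validation repairs tiny glitches and rejects real violations", {
  expect_silent(dvh_curve("G", 10, c(0, 1, 2), c(1, 0.5, 0.5 + 1e-10)))
  expect_error(dvh_curve("G", 10, c(0, 1, 2), c(1, 0.5, 0.6)),
               "non-monotone.*'G'")
  expect_error(dvh_curve("G", 10, c(0, 2, 1), c(1, 0.5, 0)), "increasing")
  expect_error(dvh_curve("G", 10, c(1, 2, 3), c(1, 0.5, 0)), "start at 0")
  expect_error(dvh_curve("G", 10, c(0, 1, 2), c(0.9, 0.5, 0)), "start at relative volume 1")
  expect_error(dvh_curve("G", -1, c(0, 1), c(1, 0)), "positive")
})

test_that("evaluate_metric agrees with a 0.001 Gy brute-force recomputation", {
  set.seed(103)
  for (i in 1:8) {
    cv <- random_curve()
    pl <- plan_record("p", list(R = cv), c(PCTV = 45))
    fine <- resample_dvh(cv, seq(0, max(cv$dose_gy), by = 0.001))
    specs <- list(dose_metric("dose_at_relative_volume", 35),
                  dose_metric("volume_at_dose", 18),
                  dose_metric("mean_dose"),
                  dose_metric("dose_at_absolute_volume", 0.03 * cv$volume_cc))
    for (spec in specs) {
      expect_equal(evaluate_metric(pl, "R", spec),
                   kbplanr:::evaluate_metric_on_curve(fine, spec),
                   tolerance = 1e-6)
    }
  }
})

test_that("evaluate_metric reports V_xGy in percent and errors on unknown structures", {
  kid <- dvh_curve("KidneyL", 150, c(0, 10, 15), c(1, 0.2, 0))
  pl <- plan_record("p", list(KidneyL = kid), c(PCTV = 45))
  expect_equal(evaluate_metric(pl, "KidneyL", dose_metric("volume_at_dose", 18)), 0)
  expect_equal(evaluate_metric(pl, "KidneyL", dose_metric("volume_at_dose", 10)), 20)
  expect_error(evaluate_metric(pl, "Bladder", dose_metric("mean_dose")),
               "not found")
})

test_that("resampling is the identity on its own grid and preserves metrics", {
  cv <- simple_curve()
  expect_equal(resample_dvh(cv, cv$dose_gy)$rel_volume, cv$rel_volume)
  rect <- dvh_curve("R", 50, c(0, 10), c(1, 0))
  expect_equal(resample_dvh(rect, c(0, 5, 10))$rel_volume, c(1, 0.5, 0))
  set.seed(104)
  for (i in 1:10) {
    # smooth overlap/fall-off curves, resolved on the coarse grid
    cv <- achievable_dvh(geometry_features(stats::runif(1, 0, 0.6),
                                           stats::runif(1, 4, 18), 100, 1000),
                         45, seq(0, 75, by = 0.02))
    coarse <- seq(0, 75, by = 0.5)
    rt <- resample_dvh(resample_dvh(cv, coarse), cv$dose_gy)
    expect_equal(mean_dose(rt), mean_dose(cv), tolerance = 5e-3)
    expect_equal(dose_at_volume(rt, 0.35), dose_at_volume(cv, 0.35),
                 tolerance = 5e-3)
  }
})
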