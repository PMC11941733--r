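test_that("pressure-strain modulus follows the defining algebra", {
  # Dsys = 2 Ddias cancels the diameter: Ppsm = pulse pressure
  expect_equal(pressure_strain_modulus(50, 100, 0, 12, "kPa"), 12)
  # homogeneous of degree 0 in the diameters
  p1 <- pressure_strain_modulus(48, 60, 80, 130)
  p2 <- pressure_strain_modulus(3 * 48, 3 * 60, 80, 130)
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(pressure_strain_modulus(50, 55, 0, 10, "kPa"), 100)
  # mmHg input converts before evaluating
  expect_equal(pressure_strain_modulus(50, 55, 123, 230),
               50 * (107 * 133.322 / 1000) / 5, tolerance = 1e-12)
  expect_error(pressure_strain_modulus(50, 50, 0, 10, "kPa"), "undefined")
  expect_error(pressure_strain_modulus(50, 55, 10, 10, "kPa"), "p_sys")
})

test_that("the saturating curve is calibrated by least squares and audited", {
  pairs <- calibration_pairs()
  curve <- calibrate_risk_curve(pairs)
  expect_gt(curve$rate_k, 0)
  expect_lte(curve$fit_residual, 5e-4)
  # parameter recovery from synthetic pairs
  set.seed(9)
  pp <- runif(20, 10, 300)
  k0 <- 0.0123
  rec <- calibrate_risk_curve(data.frame(ppsm_kpa = pp, risk = 1 - exp(-k0 * pp)))
  expect_equal(rec$rate_k, k0, tolerance = 1e-6)
  expect_lt(rec$fit_residual, 1e-9)
  # two consistent pairs: exact interpolation
  two <- calibrate_risk_curve(
    data.frame(ppsm_kpa = c(50, 100), risk = 1 - exp(-0.017 * c(50, 100))))
  expect_equal(two$rate_k, 0.017, tolerance = 1e-8)
  # validation
  expect_error(calibrate_risk_curve(data.frame(ppsm_kpa = 50, risk = 0.5)),
               "at least 2")
  expect_error(calibrate_risk_curve(
    data.frame(ppsm_kpa = c(50, 100), risk = c(0.5, 1.2))), "in \\(0, 1\\)")
  expect_error(calibrate_risk_curve(
    data.frame(ppsm_kpa = c(50, 100, 150), risk = c(0.5, 0.8, 0.6))),
    "non-monotone")
})

test_that("the one-parameter exponential fits the cohort; the hyperbola does not", {
  # the model-selection step behind the curve choice, kept as a build oracle:
  # best-fit risk = P/(P+c) misses the printed risks by whole percentage
  # points, the exponential by < 0.01 pp
  pairs <- calibration_pairs()
  curve <- calibrate_risk_curve(pairs)
  expect_lt(100 * max(abs(rupture_risk(curve, pairs$ppsm_kpa) - pairs$risk)),
            0.01)
  sse_h <- function(cc) sum((pairs$ppsm_kpa / (pairs$ppsm_kpa + cc) - pairs$risk)^2)
  c_best <- optimize(sse_h, c(1, 500), tol = 1e-12)$minimum
  worst_h <- 100 * max(abs(pairs$ppsm_kpa / (pairs$ppsm_kpa + c_best) - pairs$risk))
  expect_gt(worst_h, 1)
})

test_that("rupture risk is monotone, origin-anchored and saturating", {
  curve <- calibrate_risk_curve(calibration_pairs())
  expect_equal(rupture_risk(curve, 0), 0)
  expect_equal(100 * rupture_risk(curve, 140.00), 90.74, tolerance = 0.01 / 90.74)
  expect_equal(100 * rupture_risk(curve, 47.43), 55.35, tolerance = 0.01 / 55.35)
  x <- seq(0, 400, by = 5)
  r <- rupture_risk(curve, x)
  expect_true(all(diff(r) > 0))
  expect_true(all(r < 1))
  expect_error(rupture_risk(curve, -1), "non-negative")
})

test_that("risk_report annotates thresholds and preserves ordering", {
  curve <- calibrate_risk_curve(calibration_pairs())
  lc <- load_case()
  recs <- list(
    list(case_id = "stiff", diagnostic_diameter = 50, systolic_diameter = 52),
    list(case_id = "soft", diagnostic_diameter = 50, systolic_diameter = 62))
  rep_ <- risk_report(recs, lc, curve)
  expect_identical(nrow(rep_), 2L)
  # stiffer vessel (small dilation) -> higher Ppsm -> higher risk
  expect_gt(rep_$ppsm_kpa[1], rep_$ppsm_kpa[2])
  expect_gt(rep_$risk_percent[1], rep_$risk_percent[2])
  expect_match(rep_$annotation[rep_$ppsm_kpa > 200], "severe")
  expect_match(rep_$annotation[rep_$ppsm_kpa < 50], "resilient")
  # sorted by Ppsm means sorted by risk: the curve is monotone
  o <- order(rep_$ppsm_kpa)
  expect_identical(order(rep_$risk_percent), o)
  empty <- risk_report(list(), lc, curve)
  expect_identical(nrow(empty), 0L)
})

test_that("packaged calibration and maxima fixtures are consistent", {
  calib <- risk_calibration_table()
  maxima <- cohort_reference_maxima()
  expect_identical(nrow(calib), 12L)
  expect_identical(sort(calib$case_id), sort(maxima$case_id))
  # the printed bookkeeping Dsys = Ddias + u_max holds for exactly 8 cases
  merged <- merge(maxima, calib, by = "case_id")
  ok <- merged$diagnostic_diameter_mm + merged$max_displacement_mm ==
    merged$systolic_diameter_mm
  expect_identical(sum(ok), 8L)
})
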