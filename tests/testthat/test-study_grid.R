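test_that("case grid enumerates the Cartesian product deterministically", {
  grid <- enumerate_cases()
  expect_equal(nrow(grid), 45)
  expect_equal(unname(table(grid$cardiac_output_l_min)), rep(15L, 3),
               ignore_attr = TRUE)
  expect_false(anyDuplicated(grid$case_id) > 0)
  # ordering: dysfunction outer, diameter middle, flow inner
  expect_equal(grid$dysfunction_pct[1:15], rep(0, 15))
  expect_equal(grid$lvot_diameter_mm[1:6], c(27, 27, 27, 25, 25, 25))
  expect_equal(grid$cardiac_output_l_min[1:3], c(3, 5, 7))
  expect_equal(grid$case_id[1], "d27_f0_q3")

  single <- enumerate_cases(27, 0, 5)
  expect_equal(nrow(single), 1)
  expect_equal(single$case_id, "d27_f0_q5")

  sub <- enumerate_cases(c(27, 19), c(0, 100), c(3, 7))
  expect_equal(nrow(sub), 2 * 2 * 2)

  expect_error(enumerate_cases(lvot_diameters_mm = c(27, 30)), "invalid")
  expect_error(enumerate_cases(dysfunction_pct = numeric(0)), "non-empty")
  expect_error(enumerate_cases(cardiac_outputs_l_min = c(3, 3)),
               "duplicates")
})

test_that("stenosis area reduction follows the circular cross-section", {
  expect_equal(stenosis_area_reduction(27), 0)
  # 19 mm against the 27 mm annulus is the 50% maximum reduction
  expect_equal(round(stenosis_area_reduction(19), 2), 0.5)
  expect_equal(stenosis_area_reduction(19), 1 - (19 / 27)^2)
  expect_equal(stenosis_area_reduction(23), 1 - (23 / 27)^2,
               tolerance = 1e-12)
  # strictly decreasing in diameter
  d <- seq(1, 27, by = 0.5)
  expect_true(all(diff(stenosis_area_reduction(d)) < 0))
  expect_error(stenosis_area_reduction(0), "must lie")
  expect_error(stenosis_area_reduction(28), "must lie")
})

test_that("one-leaflet dysfunction maps linearly to total valve area", {
  expect_equal(valve_area_restriction(0), 0)
  expect_equal(valve_area_restriction(50), 0.25)
  expect_equal(valve_area_restriction(100), 0.5)
  x <- seq(0, 100, by = 5)
  expect_equal(valve_area_restriction(x), x / 200)
  expect_true(all(valve_area_restriction(x) >= 0 &
                    valve_area_restriction(x) <= 0.5))
  expect_error(valve_area_restriction(-1), "must lie")
  expect_error(valve_area_restriction(101), "must lie")
})

test_that("Reynolds and Womersley numbers follow their definitions", {
  expect_equal(reynolds_number(0, 0.027), 0)
  expect_equal(reynolds_number(1, 0.027), 1060 * 1 * 0.027 / 0.0035)
  expect_equal(reynolds_number(2, 0.027), 2 * reynolds_number(1, 0.027))

  a <- womersley_number(0.0135, 70)
  expect_equal(a, 0.0135 * sqrt(2 * pi * (70 / 60) / (0.0035 / 1060)))
  expect_equal(round(a, 1), 20.1)
  # quadrupling kinematic viscosity halves alpha
  thick <- blood_properties(density = 1060, dynamic_viscosity = 4 * 0.0035)
  expect_equal(womersley_number(0.0135, 70, thick), a / 2)
  expect_equal(womersley_number(0, 70), 0)

  nd <- nondimensional_summary(case_spec(27, 0, 5))
  expect_true(nd$re_peak >= nd$re_mean && nd$re_mean > 0)
  expect_gt(nd$womersley_alpha, 0)
})

test_that("case validation rejects out-of-study values", {
  expect_error(case_spec(30, 0, 5), "lvot_diameter_mm")
  expect_error(case_spec(27, 25, 5), "dysfunction_pct")
  expect_error(case_spec(27, 0, 4), "cardiac_output_l_min")
  expect_error(case_spec(27, 0, 5, systole_duration_s = 1), "systole")
  c1 <- case_spec(21, 50, 3)
  expect_equal(case_id(c1), "d21_f50_q3")
})
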