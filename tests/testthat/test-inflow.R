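test_that("half-sine waveform preserves the cycle-mean cardiac output", {
  wf <- pulsatile_waveform(case_spec(27, 0, 5))
  expect_equal(wf$period_s, 60 / 70)
  expect_equal(max(wf$q), 5 * (60 / 70) / 0.3 * pi / 2, tolerance = 1e-3)
  expect_equal(round(wf$q_peak_l_min, 1), 22.4)
  # dense quadrature of the closed form recovers the mean to < 0.1%
  tq <- seq(0, wf$period_s, length.out = 20001)
  q <- waveform_flow(wf, tq)
  mean_q <- mean((q[-1] + q[-length(q)]) / 2)
  expect_lt(abs(mean_q - 5) / 5, 1e-3)
  expect_true(all(q >= 0))
  expect_true(all(waveform_flow(wf, seq(0.31, 0.85, by = 0.01)) == 0))
})

test_that("waveform mean preservation holds across the study grid", {
  for (co in c(3, 5, 7)) {
    wf <- pulsatile_waveform(case_spec(27, 0, co))
    tq <- seq(0, wf$period_s, length.out = 20001)
    q <- waveform_flow(wf, tq)
    expect_lt(abs(mean((q[-1] + q[-length(q)]) / 2) - co) / co, 1e-3)
  }
  wf0 <- pulsatile_waveform(case_spec(27, 0, 5))
  wf0$q_peak_l_min <- 0  # degenerate zero-output waveform
  expect_true(all(waveform_flow(wf0, seq(0, 0.8, 0.01)) == 0))
  expect_error(pulsatile_waveform(case_spec(27, 0, 5), n_samples = 10),
               ">= 50")
})

test_that("inlet velocity converts flow through the circular LVOT area", {
  wf <- pulsatile_waveform(case_spec(27, 0, 5))
  expect_equal(inlet_velocity(wf, 27, 0.6), 0)  # diastole
  # 22.4 L/min through a 27 mm circle is ~0.65 m/s
  u <- inlet_velocity(wf, 27, 0.15)
  expect_equal(u, (wf$q_peak_l_min / 60000) / (pi * 0.0135^2),
               tolerance = 1e-6)
  expect_equal(round(u, 2), 0.65)
  # halving the diameter quadruples the velocity at fixed flow
  expect_equal(inlet_velocity(wf, 13.5, 0.15) / u, 4, tolerance = 1e-9)
})

test_that("closed-form Womersley profile matches the independent series", {
  y <- seq(-1, 1, length.out = 41)
  for (alpha in c(1, 5, 10)) {
    for (phase in c(0, 1.1, pi)) {
      u_cf <- womersley_profile(2.0, alpha, phase, y)
      u_sr <- womersley_series_oracle(2.0, alpha, phase, y)
      expect_lt(max(abs(u_cf - u_sr)), 1e-8)
    }
  }
  # no-slip at the walls
  expect_equal(womersley_profile(2.0, 5, 0.3, c(-1, 1)), c(0, 0))
})

test_that("Womersley profile reduces to Poiseuille as alpha -> 0", {
  y <- seq(-0.9, 0.9, length.out = 31)
  u_w <- womersley_profile(1.0, 0.1, 0, y)
  u_p <- poiseuille_profile(1.0, 0.1, 0, y)
  expect_lt(max(abs(u_w - u_p)) / max(abs(u_p)), 0.01)
  # alpha = 10: centerline amplitude well below the quasi-steady value
  amp_w <- max(abs(womersley_profile(1.0, 10, seq(0, 2 * pi, 0.05), 0)))
  amp_p <- poiseuille_profile(1.0, 10, 0, 0)
  expect_lt(amp_w, 0.2 * amp_p)
})

test_that("synthetic jet fields honor the prescribed maxima exactly", {
  m <- coarse_mask(27, 0, 5)
  f <- synthetic_jet_field(3.0, 1.0, m)
  down <- region_cells(m, c("SINUS", "AORTA"))
  lvot <- region_cells(m, "LVOT")
  expect_lt(abs(max(sqrt(f$u^2 + f$v^2)[down]) - 3.0), 1e-9)
  expect_lt(abs(max(sqrt(f$u^2 + f$v^2)[lvot]) - 1.0), 1e-9)
  expect_true(all(f$u[m$solid] == 0))

  f0 <- synthetic_jet_field(0, 0, m)
  expect_true(all(f0$u == 0) && all(f0$v == 0))
  expect_error(synthetic_jet_field(1, 2, m), "vpeak_target")

  # DVI follows by arithmetic from the prescribed maxima
  f2 <- synthetic_jet_field(4.37, 1.2, m)
  vpk <- max(sqrt(f2$u^2 + f2$v^2)[down])
  vlv <- max(sqrt(f2$u^2 + f2$v^2)[lvot])
  expect_equal(round(dvi(vlv, vpk), 4), 0.2746)
})
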