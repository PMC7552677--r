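# Unit contracts of the projection solver and the k-omega closure.

all_fluid_mask <- function(nx = 40, ny = 40, h = 1) {
  m <- box_mask(nx, ny, h)
  m$solid[] <- FALSE
  m$region[] <- 4L
  m
}

test_that("CFL number is the advective step ratio", {
  m <- box_mask()
  f <- flow_field(m)
  cfg <- solver_config(dt = 5e-4)
  expect_equal(cfl(f, cfg, 1e-3), 0)
  f$u[] <- 1
  expect_equal(cfl(f, cfg, 1e-3), 0.5)
  expect_equal(cfl(f, solver_config(dt = 1e-3), 1e-3), 1.0)
  f$v[] <- -3
  expect_equal(cfl(f, cfg, 1e-3), 1.5)
})

test_that("advance rejects CFL violations with a dt suggestion", {
  m <- box_mask()
  f <- flow_field(m)
  f$u[] <- 2
  expect_error(advance(f, m, bc = list(inlet = 0),
                       config = solver_config(dt = 5e-3)),
               "reduce dt")
})

test_that("quiescent flow with zero inflow is a fixed point", {
  m <- coarse_mask(27, 0, 5)
  f <- flow_field(m)
  g <- advance(f, m, bc = list(inlet = 0))
  expect_true(all(g$u == 0) && all(g$v == 0))
  expect_equal(attr(g, "max_div_scaled"), 0)
})

test_that("kinetic energy decays with zero inflow and no-slip walls", {
  set.seed(42)
  m <- box_mask(24, 20, 1)
  f <- flow_field(m)
  f$u[2:24, 2:19] <- 0.02 * matrix(runif(23 * 18, -1, 1), 23, 18)
  f$v[2:23, 2:20] <- 0.02 * matrix(runif(22 * 19, -1, 1), 22, 19)
  cfg <- solver_config(dt = 5e-3)
  ke <- numeric(25)
  for (i in seq_along(ke)) {
    f <- advance(f, m, bc = list(inlet = 0, u_ref = 0.02), config = cfg)
    ke[i] <- sum(f$u^2) + sum(f$v^2)
  }
  # after the first projection the energy is non-increasing
  expect_true(all(diff(ke[-1]) <= 1e-15))
  expect_lt(ke[25], ke[2])
})

test_that("projection keeps every fluid cell below the divergence
           tolerance during a pulsatile run", {
  run <- suppressWarnings(run_case(case_spec(27, 0, 5), coarse_geo(),
                                   solver_config(n_cycles = 1)))
  expect_lte(run$max_div_scaled, solver_config()$poisson_tolerance + 1e-12)
  expect_lt(run$mass_error, 0.01)
})

test_that("steady Poiseuille channel reaches the analytic 1.5 ratio", {
  po <- poiseuille_benchmark(ny = 32, t_end = 0.8)
  expect_lt(abs(po$ratio - 1.5) / 1.5, 0.02)
  expect_lt(po$mass_error, 0.01)
  expect_lte(po$max_div_scaled, 1e-6 + 1e-12)
})

test_that("oscillatory channel error shrinks under grid refinement at
           observed order >= 1", {
  e16 <- womersley_benchmark(alpha = 3, ny = 16, n_periods = 2)$rms_error
  e32 <- womersley_benchmark(alpha = 3, ny = 32, n_periods = 2)$rms_error
  expect_lt(e32, e16)
  expect_gte(log2(e16 / e32), 0.9)
})

test_that("five-cycle run is periodic and mass-conserving", {
  run <- run_case(case_spec(27, 0, 5),
                  geometry_params(grid_spacing_mm = 1.2),
                  solver_config(n_cycles = 5))
  expect_lt(run$periodicity, 0.05)
  expect_lt(run$mass_error, 0.01)
  # zero cardiac output has no meaning in the study grid; the waveform
  # degenerate limit is covered by the quiescent fixed point above
  expect_gt(peak_over(run, NULL)$value, 0)
})

test_that("k-omega: no production under uniform flow, laminar contract", {
  m <- all_fluid_mask(30, 24, 1)  # open domain: no walls, no shear
  f <- flow_field(m)
  f$u[] <- 0.5
  turb <- turbulence_state(m, k0 = 1e-4, omega0 = 50)
  cfg <- solver_config(dt = 1e-3, turbulence_mode = "k_omega")
  ctr <- c(15, 12)
  k_trace <- numeric(6)
  for (i in 1:6) {
    turb <- komega_update(f, turb, m, cfg, n_steps = 20)
    k_trace[i] <- turb$k[ctr[1], ctr[2]]
  }
  expect_true(all(diff(k_trace) < 0))  # pure decay, no production
  expect_true(all(turb$k >= 0))
  expect_true(all(turb$omega > 0))
  expect_error(komega_update(f, turb, m, solver_config()), "k_omega")
})

test_that("k-omega equilibrium matches the algebraic
           production-dissipation balance of its constants", {
  gamma <- 100  # 1/s uniform shear
  m <- all_fluid_mask(40, 40, 1)
  f <- flow_field(m)
  yc <- (seq_len(m$ny) - 0.5 - m$ny / 2) * m$spacing / 1000
  f$u <- matrix(rep(gamma * yc, each = m$nx + 1), m$nx + 1, m$ny)
  turb <- turbulence_state(m, k0 = 1e-4, omega0 = 40)
  cfg <- solver_config(dt = 1e-4, turbulence_mode = "k_omega")
  # homogeneous run: no walls, inlet override disabled
  turb <- komega_update(f, turb, m, cfg, n_steps = 2500, inlet_bc = FALSE)
  ctr <- c(20, 20)
  alpha_w <- 5 / 9; beta <- 0.075; beta_star <- 0.09
  omega_eq <- gamma * sqrt(alpha_w / beta)
  expect_lt(abs(turb$omega[ctr[1], ctr[2]] - omega_eq) / omega_eq, 0.01)
  # nu_t = k / omega at the omega fixed point
  nut_eq <- turb$k[ctr[1], ctr[2]] / omega_eq
  expect_lt(abs(turb$nut[ctr[1], ctr[2]] - nut_eq) / nut_eq, 0.01)
  # production / dissipation ratio of the k equation: beta / (alpha beta*)
  prod <- turb$nut[ctr[1], ctr[2]] * gamma^2
  diss <- beta_star * turb$k[ctr[1], ctr[2]] * turb$omega[ctr[1], ctr[2]]
  expect_lt(abs(prod / diss - beta / (alpha_w * beta_star)), 0.015 * 1.5)
})

test_that("k-omega mode runs the masked valve geometry stably", {
  cfg <- solver_config(n_cycles = 1, turbulence_mode = "k_omega")
  run <- suppressWarnings(run_case(case_spec(27, 0, 5),
                                   geometry_params(grid_spacing_mm = 1.2),
                                   cfg))
  expect_true(all(is.finite(vapply(run$snapshots, function(s) max(s$u),
                                   numeric(1)))))
  pk <- which.max(vapply(run$snapshots,
                         function(s) max(cell_velocity(s, run$mask)$speed),
                         numeric(1)))
  snap <- run$snapshots[[pk]]
  expect_true(all(snap$k >= 0))
  expect_true(all(snap$nut >= 0))
  # modeled Reynolds stress is nonzero where the jet shears
  ss <- shear_stresses(snap, snap, blood_properties(), run$mask)
  expect_gt(max(abs(ss$turbulent)), 0)
})
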