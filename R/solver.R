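# R interface to the compiled staggered-grid projection solver.

#' Solver configuration
#'
#' @param dt Macro time step in s (default 0.5 ms). When velocities would
#'   violate the CFL limit at this step, [run_case()] subdivides it
#'   adaptively; [advance()] instead raises an error.
#' @param n_cycles Number of cardiac cycles to simulate; results are
#'   extracted from the final cycle.
#' @param poisson_tolerance Relative divergence tolerance of the pressure
#'   projection: the post-projection discrete divergence of every fluid cell
#'   is at most `poisson_tolerance * U_ref / h`.
#' @param max_inner_iterations Cap on pressure-correction rounds per time
#'   step; each round is a conjugate-gradient solve of up to `cg_max`
#'   iterations.
#' @param convection_scheme `"upwind"` (first-order, default) or
#'   `"central-blend"` (75% central, 25% upwind).
#' @param turbulence_mode `"laminar"` (default) or `"k_omega"` (standard
#'   Wilcox closure with 5% inlet turbulence intensity).
#' @param cfl_limit Maximum advective CFL number per (sub)step.
#' @param cg_max Iteration cap of a single conjugate-gradient solve.
#' @param nut_max_ratio Eddy viscosity is clipped at this multiple of the
#'   molecular kinematic viscosity.
#' @param inlet_intensity Inlet turbulence intensity (fraction).
#' @param snapshot_interval_s Spacing of stored snapshots within the
#'   sampled cycles.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dt = 5e-4, n_cycles = 5, poisson_tolerance = 1e-6,
                          max_inner_iterations = 30,
                          convection_scheme = c("upwind", "central-blend"),
                          turbulence_mode = c("laminar", "k_omega"),
                          cfl_limit = 0.8, cg_max = 4000,
                          nut_max_ratio = 1000, inlet_intensity = 0.05,
                          snapshot_interval_s = 0.015) {
  convection_scheme <- match.arg(convection_scheme)
  turbulence_mode <- match.arg(turbulence_mode)
  stopifnot(dt > 0, n_cycles >= 1,
            poisson_tolerance > 0, poisson_tolerance < 1,
            max_inner_iterations >= 1, cfl_limit > 0, cg_max >= 1,
            nut_max_ratio > 0, inlet_intensity >= 0, snapshot_interval_s > 0)
  structure(list(dt = dt, n_cycles = n_cycles,
                 poisson_tolerance = poisson_tolerance,
                 max_inner_iterations = max_inner_iterations,
                 convection_scheme = convection_scheme,
                 turbulence_mode = turbulence_mode,
                 cfl_limit = cfl_limit, cg_max = cg_max,
                 nut_max_ratio = nut_max_ratio,
                 inlet_intensity = inlet_intensity,
                 snapshot_interval_s = snapshot_interval_s),
            class = "solver_config")
}

cfg_to_cpp <- function(config, inlet_width_m) {
  list(poisson_tol = config$poisson_tolerance,
       max_outer = as.integer(config$max_inner_iterations),
       cg_max = as.integer(config$cg_max),
       convection = if (config$convection_scheme == "upwind") 0L else 1L,
       blend = 0.75,
       turb = if (config$turbulence_mode == "k_omega") 1L else 0L,
       nut_max_ratio = config$nut_max_ratio,
       inlet_intensity = config$inlet_intensity,
       inlet_width_m = inlet_width_m,
       cfl_limit = config$cfl_limit,
       adaptive = 0L)
}

#' Quiescent flow field on a mask
#'
#' @param mask A `solid_mask`.
#' @param t Initial time in s.
#' @return An object of class `flow_field`: staggered `u` ((nx+1) x ny),
#'   `v` (nx x (ny+1)), cell-centered `p` (nx x ny) and time `t`.
#' @export
flow_field <- function(mask, t = 0) {
  structure(list(u = matrix(0, mask$nx + 1, mask$ny),
                 v = matrix(0, mask$nx, mask$ny + 1),
                 p = matrix(0, mask$nx, mask$ny), t = t),
            class = "flow_field")
}

#' Turbulence state on a mask
#'
#' @param mask A `solid_mask`.
#' @param inlet_intensity Inlet turbulence intensity (fraction).
#' @param k0,omega0 Initial turbulent kinetic energy (m2/s2) and specific
#'   dissipation rate (1/s).
#' @return An object of class `turbulence_state` with fields `k`, `omega`,
#'   `nut`, `inlet_intensity`.
#' @export
turbulence_state <- function(mask, inlet_intensity = 0.05, k0 = 1e-6,
                             omega0 = 1) {
  stopifnot(k0 >= 0, omega0 > 0)
  structure(list(k = matrix(k0, mask$nx, mask$ny),
                 omega = matrix(omega0, mask$nx, mask$ny),
                 nut = matrix(k0 / omega0, mask$nx, mask$ny),
                 inlet_intensity = inlet_intensity),
            class = "turbulence_state")
}

#' Advective CFL number of a field
#'
#' @param field A `flow_field`.
#' @param config A [solver_config()].
#' @param spacing_m Grid spacing in m.
#' @return `max(|u|, |v|) * dt / h`.
#' @export
cfl <- function(field, config, spacing_m) {
  umax <- max(abs(field$u), abs(field$v), 0)
  umax * config$dt / spacing_m
}

# inlet face-velocity profile (length ny) for a plug velocity on the inlet rows
inlet_profile <- function(mask, u_plug) {
  prof <- numeric(mask$ny)
  prof[!mask$solid[1, ]] <- u_plug
  prof
}

#' Advance the flow by one time step
#'
#' One explicit-convection, explicit-diffusion, pressure-projection step of
#' size `config$dt`. The advective CFL condition must hold; otherwise an
#' error suggests a suitable step.
#'
#' @param field A `flow_field`.
#' @param mask A `solid_mask`.
#' @param turb A [turbulence_state()] (used when
#'   `config$turbulence_mode == "k_omega"`), or `NULL`.
#' @param bc List of boundary data: `inlet` is either a scalar plug velocity
#'   or a length-`ny` face-velocity profile (m/s); `u_ref` optionally sets
#'   the velocity scale of the divergence tolerance (defaults to the larger
#'   of the inlet and current field speeds).
#' @param config A [solver_config()].
#' @param props A [blood_properties()].
#' @return Updated `flow_field` (with attribute `"turb"` carrying the
#'   updated turbulence state in k-omega mode, and attribute
#'   `"max_div_scaled"` with the post-projection divergence diagnostic).
#' @export
advance <- function(field, mask, turb = NULL, bc = list(inlet = 0),
                    config = solver_config(), props = blood_properties()) {
  h_m <- mask$spacing / 1000
  c_now <- cfl(field, config, h_m)
  if (c_now > config$cfl_limit)
    stop(sprintf(
      "CFL %.3g exceeds limit %.3g; reduce dt to <= %.3g s",
      c_now, config$cfl_limit,
      config$cfl_limit * h_m / max(abs(field$u), abs(field$v), 1e-300)),
      call. = FALSE)
  prof <- bc$inlet
  if (length(prof) == 1L) prof <- inlet_profile(mask, prof)
  stopifnot(length(prof) == mask$ny)
  u_ref <- bc$u_ref
  if (is.null(u_ref))
    u_ref <- max(abs(prof), abs(field$u), abs(field$v), 1e-9)
  turb_on <- config$turbulence_mode == "k_omega"
  if (turb_on && is.null(turb)) turb <- turbulence_state(mask)
  init <- list(u = field$u, v = field$v, p = field$p,
               k = if (turb_on) turb$k else NULL,
               omega = if (turb_on) turb$omega else NULL,
               nut = if (turb_on) turb$nut else NULL)
  cfgl <- cfg_to_cpp(config, mask$case$lvot_diameter_mm / 1000)
  if (turb_on) cfgl$inlet_intensity <- turb$inlet_intensity
  res <- cpp_run(fluid = matrix(as.integer(!mask$solid), mask$nx, mask$ny),
                 h = h_m, dt = config$dt,
                 sched_t = c(field$t, field$t + config$dt),
                 sched_u = rbind(prof, prof),
                 t0 = field$t, t_end = field$t + config$dt,
                 snap_times = numeric(0), init = init, cfg = cfgl,
                 rho = props$density, mu = props$dynamic_viscosity,
                 uref = u_ref, flux_t0 = Inf)
  if (isTRUE(res$poisson_failed))
    stop("pressure Poisson solve did not converge within ",
         config$max_inner_iterations, " correction rounds; ",
         "scaled residual history: ",
         paste(signif(res$residual_history, 3), collapse = ", "),
         call. = FALSE)
  out <- structure(list(u = res$u, v = res$v, p = res$p,
                        t = field$t + config$dt),
                   class = "flow_field")
  attr(out, "max_div_scaled") <- res$max_div_scaled
  if (turb_on) {
    turb$k <- res$k
    turb$omega <- res$omega
    turb$nut <- res$nut
    attr(out, "turb") <- turb
    attr(out, "kfloor_events") <- res$kfloor_events
  }
  out
}

#' One explicit k-omega transport update
#'
#' Standard Wilcox-form update of turbulent kinetic energy and specific
#' dissipation rate on frozen velocities: upwind convection, production
#' `nu_t S^2`, semi-implicit destruction, gradient diffusion; the eddy
#' viscosity `nu_t = k / omega` is clipped at
#' `config$nut_max_ratio * nu_molecular`. Solid-adjacent cells take the
#' near-wall omega asymptote and inlet cells the 5%-intensity inflow value.
#'
#' @param field A `flow_field` (frozen velocities).
#' @param turb A [turbulence_state()].
#' @param mask A `solid_mask`.
#' @param config A [solver_config()] with `turbulence_mode = "k_omega"`.
#' @param props A [blood_properties()].
#' @param bc Boundary data as in [advance()].
#' @param n_steps Number of updates of size `config$dt` to apply.
#' @param inlet_bc Apply the inlet-column override; disable for
#'   homogeneous verification runs that exercise the pointwise model ODEs.
#' @return Updated `turbulence_state` (attribute `"kfloor_events"` counts
#'   negative-k floorings).
#' @export
komega_update <- function(field, turb, mask, config = solver_config(
                            turbulence_mode = "k_omega"),
                          props = blood_properties(), bc = list(inlet = 0),
                          n_steps = 1, inlet_bc = TRUE) {
  if (config$turbulence_mode != "k_omega")
    stop("komega_update requires turbulence_mode = \"k_omega\"",
         call. = FALSE)
  prof <- bc$inlet
  if (length(prof) == 1L) prof <- inlet_profile(mask, prof)
  res <- cpp_komega(fluid = matrix(as.integer(!mask$solid), mask$nx, mask$ny),
                    h = mask$spacing / 1000, dt = config$dt,
                    n_steps = as.integer(n_steps),
                    u = field$u, v = field$v, k0 = turb$k, w0 = turb$omega,
                    rho = props$density, mu = props$dynamic_viscosity,
                    nut_max_ratio = config$nut_max_ratio,
                    inlet_intensity = turb$inlet_intensity,
                    inlet_width_m = mask$case$lvot_diameter_mm / 1000,
                    uin = prof, inlet_bc = as.integer(inlet_bc))
  turb$k <- res$k
  turb$omega <- res$omega
  turb$nut <- res$nut
  attr(turb, "kfloor_events") <- res$kfloor_events
  turb
}

#' Simulate one case over cardiac cycles
#'
#' Advances the masked 2D flow from quiescent initial conditions over
#' `config$n_cycles` cardiac cycles with the case's pulsatile plug inflow,
#' subdividing the macro time step adaptively to respect the CFL and
#' diffusive stability limits. Snapshots of the final cycle are returned
#' together with a cycle-to-cycle periodicity metric (relative L2 velocity
#' difference at matched phases of the last two cycles) and the
#' cycle-integrated inlet/outlet fluxes of the final cycle.
#'
#' @param case A [case_spec()].
#' @param geo A [geometry_params()].
#' @param config A [solver_config()].
#' @param props A [blood_properties()].
#' @return An object of class `case_run`: list with `snapshots` (each a
#'   `flow_field`, plus `k`/`omega`/`nut` matrices in k-omega mode),
#'   `times`, `mask`, `waveform`, `case`, `periodicity`, `flux_in`,
#'   `flux_out`, `mass_error`, `max_div_scaled`, `diagnostics`.
#' @export
run_case <- function(case, geo = geometry_params(),
                     config = solver_config(), props = blood_properties()) {
  mask <- build_geometry(case, geo)
  wf <- pulsatile_waveform(case)
  period <- wf$period_s
  t_end <- config$n_cycles * period
  h_m <- mask$spacing / 1000

  # inlet schedule on a fine grid over one cycle, tiled over all cycles
  tt <- seq(0, t_end, by = min(config$dt, period / 500))
  u_plug <- inlet_velocity(wf, case$lvot_diameter_mm, tt)
  open_rows <- !mask$solid[1, ]
  sched_u <- outer(u_plug, as.numeric(open_rows))

  final_t0 <- (config$n_cycles - 1) * period
  snap_final <- seq(final_t0, t_end, by = config$snapshot_interval_s)
  phase_check <- seq(0, period, length.out = 9)[1:8]
  snap_prev <- if (config$n_cycles >= 2)
    (config$n_cycles - 2) * period + phase_check else numeric(0)
  snap_times <- sort(unique(round(c(snap_prev, final_t0 + phase_check,
                                    snap_final) / config$dt)) * config$dt)
  snap_times <- snap_times[snap_times <= t_end + 1e-12]

  u_ref <- max(u_plug, 1e-9)
  cfgl <- cfg_to_cpp(config, case$lvot_diameter_mm / 1000)
  cfgl$adaptive <- 1L
  res <- cpp_run(fluid = matrix(as.integer(!mask$solid), mask$nx, mask$ny),
                 h = h_m, dt = config$dt, sched_t = tt, sched_u = sched_u,
                 t0 = 0, t_end = t_end, snap_times = snap_times,
                 init = NULL, cfg = cfgl,
                 rho = props$density, mu = props$dynamic_viscosity,
                 uref = u_ref, flux_t0 = final_t0)
  if (isTRUE(res$poisson_failed))
    stop("solver failed: pressure Poisson did not converge (t = ",
         signif(res$t, 4), " s); scaled residual history: ",
         paste(signif(res$residual_history, 3), collapse = ", "),
         call. = FALSE)
  snaps <- res$snapshots
  times <- vapply(snaps, function(s) s$t, numeric(1))
  if (any(!is.finite(unlist(lapply(snaps, `[[`, "u")))))
    stop("solver diverged: non-finite velocities in stored snapshots",
         call. = FALSE)

  # periodicity: matched phases of the last two cycles
  periodicity <- NA_real_
  if (config$n_cycles >= 2) {
    num <- 0; den <- 0
    for (ph in phase_check) {
      ia <- which.min(abs(times - ((config$n_cycles - 2) * period + ph)))
      ib <- which.min(abs(times - ((config$n_cycles - 1) * period + ph)))
      ua <- snaps[[ia]]$u; ub <- snaps[[ib]]$u
      va <- snaps[[ia]]$v; vb <- snaps[[ib]]$v
      num <- num + sum((ua - ub)^2) + sum((va - vb)^2)
      den <- den + sum(ub^2) + sum(vb^2)
    }
    periodicity <- sqrt(num / max(den, 1e-300))
  }
  if (is.finite(periodicity) && periodicity > 0.05)
    warning("periodicity metric ", signif(periodicity, 3),
            " exceeds 5% between the last two cycles", call. = FALSE)

  in_final <- times >= final_t0 - 1e-9
  fields <- lapply(snaps[in_final], function(s) {
    f <- structure(list(u = s$u, v = s$v, p = s$p, t = s$t),
                   class = "flow_field")
    if (nrow(s$k) > 0) { f$k <- s$k; f$omega <- s$omega; f$nut <- s$nut }
    f
  })
  mass_error <- abs(res$flux_in - res$flux_out) /
    max(abs(res$flux_in), 1e-300)
  structure(list(snapshots = fields, times = times[in_final], mask = mask,
                 waveform = wf, case = case, periodicity = periodicity,
                 flux_in = res$flux_in, flux_out = res$flux_out,
                 mass_error = mass_error,
                 max_div_scaled = res$max_div_scaled,
                 diagnostics = list(
                   n_substeps = res$n_substeps,
                   mean_cg_iters = res$mean_cg_iters,
                   kfloor_events = res$kfloor_events,
                   config = config)),
            class = "case_run")
}

#' Straight-channel benchmark runs
#'
#' Internal workhorse shared by the analytic verification benchmarks: a
#' rectangular channel (solid border rows, otherwise fluid) driven by a
#' time-dependent inlet velocity profile.
#'
#' @param nx,ny Interior grid size in cells (two wall rows are added).
#' @param h_m Cell size in m.
#' @param profile_fun `function(t, y)` giving the inlet velocity at height
#'   `y` (m, measured from the channel centerline) and time `t`.
#' @param t_end End time, s.
#' @param dt Macro step, s.
#' @param props A [blood_properties()].
#' @param config A [solver_config()].
#' @param snap_times Snapshot times, s.
#' @param init_from_profile Start from the inlet profile replicated across
#'   the channel (divergence-free) instead of quiescent flow.
#' @return List with `snapshots`, `mask`-like geometry info, and solver
#'   diagnostics (`max_div_scaled`, `flux_in`, `flux_out`).
#' @keywords internal
run_channel <- function(nx, ny, h_m, profile_fun, t_end, dt,
                        props = blood_properties(),
                        config = solver_config(), snap_times = t_end,
                        init_from_profile = FALSE) {
  nyw <- ny + 2
  fluid <- matrix(1L, nx, nyw)
  fluid[, c(1, nyw)] <- 0L
  y <- ((seq_len(nyw) - 0.5) - nyw / 2) * h_m  # face-row centers vs centerline
  tt <- seq(0, t_end, length.out = max(201, ceiling(t_end / dt) + 1))
  sched_u <- t(vapply(tt, function(t) {
    prof <- profile_fun(t, y)
    prof[c(1, nyw)] <- 0
    prof
  }, numeric(nyw)))
  u_ref <- max(abs(sched_u), 1e-9)
  cfgl <- cfg_to_cpp(config, ny * h_m)
  cfgl$adaptive <- 1L
  init <- NULL
  if (init_from_profile) {
    u0 <- matrix(rep(sched_u[1, ], each = nx + 1), nx + 1, nyw)
    init <- list(u = u0, v = matrix(0, nx, nyw + 1),
                 p = matrix(0, nx, nyw))
  }
  res <- cpp_run(fluid = fluid, h = h_m, dt = dt, sched_t = tt,
                 sched_u = sched_u, t0 = 0, t_end = t_end,
                 snap_times = snap_times, init = init, cfg = cfgl,
                 rho = props$density, mu = props$dynamic_viscosity,
                 uref = u_ref, flux_t0 = 0)
  if (isTRUE(res$poisson_failed))
    stop("channel benchmark: Poisson solve failed", call. = FALSE)
  res$y <- y
  res$fluid <- fluid
  res
}

#' Steady plane-Poiseuille verification benchmark
#'
#' Feeds the exact parabolic profile into a straight channel, runs to
#' steady state and reports the centerline-to-mean velocity ratio at a
#' downstream section (analytic value 1.5) along with mass-conservation
#' and divergence diagnostics.
#'
#' @param ny Channel width in cells.
#' @param aspect Channel length as a multiple of its width.
#' @param u_max Centerline velocity, m/s.
#' @param width_m Channel width, m.
#' @param t_end Integration time, s.
#' @param props,config See [run_case()].
#' @return List with `ratio` (centerline/mean), `mass_error`,
#'   `max_div_scaled`.
#' @export
poiseuille_benchmark <- function(ny = 64, aspect = 2, u_max = 0.01,
                                 width_m = 0.0128, t_end = 1.5,
                                 props = blood_properties(),
                                 config = solver_config()) {
  h_m <- width_m / ny
  nx <- round(aspect * ny)
  half <- width_m / 2
  res <- run_channel(nx, ny, h_m,
                     function(t, y) u_max * pmax(1 - (y / half)^2, 0),
                     t_end = t_end, dt = 5e-3, props = props,
                     config = config, init_from_profile = TRUE)
  snap <- res$snapshots[[length(res$snapshots)]]
  ucol <- snap$u[round(0.75 * nx), ]
  ucol <- ucol[res$fluid[round(0.75 * nx), ] == 1L]
  list(ratio = max(ucol) / mean(ucol),
       mass_error = abs(res$flux_in - res$flux_out) / abs(res$flux_in),
       max_div_scaled = res$max_div_scaled)
}

#' Oscillatory-channel (Womersley) verification benchmark
#'
#' Feeds the exact oscillatory profile at the inlet and compares the
#' simulated cross-stream profile at a downstream section against
#' [womersley_profile()] over the final forcing period.
#'
#' @param alpha Womersley number of the forcing.
#' @param ny Channel width in cells.
#' @param aspect Channel length as a multiple of its width.
#' @param grad_amp Kinematic pressure-gradient amplitude, m/s2.
#' @param n_periods Number of forcing periods to integrate (the last one is
#'   assessed).
#' @param n_phases Number of equispaced phases compared in the last period.
#' @param width_m Channel width, m.
#' @param props,config See [run_case()].
#' @return List with `rms_error` (RMS of the velocity error over the final
#'   period divided by the RMS of the analytic solution), `max_div_scaled`.
#' @export
womersley_benchmark <- function(alpha = 5, ny = 48, aspect = 2,
                                grad_amp = 0.15, n_periods = 3, n_phases = 8,
                                width_m = 0.01,
                                props = blood_properties(),
                                config = solver_config()) {
  half <- width_m / 2
  omega <- alpha^2 * props$nu / half^2
  period <- 2 * pi / omega
  h_m <- width_m / ny
  nx <- round(aspect * ny)
  prof_fun <- function(t, y)
    womersley_profile(grad_amp, alpha, omega * t,
                      pmin(pmax(y, -half), half), half, omega)
  phases <- seq(0, period, length.out = n_phases + 1)[seq_len(n_phases)]
  snap_times <- (n_periods - 1) * period + phases
  res <- run_channel(nx, ny, h_m, prof_fun, t_end = n_periods * period,
                     dt = period / 200, props = props, config = config,
                     snap_times = snap_times, init_from_profile = TRUE)
  icol <- round(0.75 * nx)
  err2 <- 0; ref2 <- 0
  for (s in res$snapshots) {
    rows <- res$fluid[icol, ] == 1L
    u_num <- s$u[icol, rows]
    u_ana <- womersley_profile(grad_amp, alpha, omega * s$t,
                               res$y[rows], half, omega)
    err2 <- err2 + sum((u_num - u_ana)^2)
    ref2 <- ref2 + sum(u_ana^2)
  }
  list(rms_error = sqrt(err2 / ref2), max_div_scaled = res$max_div_scaled)
}
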