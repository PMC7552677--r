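# Synthetic-data stage: pulsatile inflow waveform, analytic oscillatory
# channel (Womersley) oracle, and synthetic jet fields with prescribed
# maxima for exercising the Doppler stage without the solver.

#' Pulsatile systolic inflow waveform
#'
#' Half-sine pulse over the 0.3 s systole, zero in diastole, scaled so the
#' cycle mean equals the case's cardiac output. The peak flow is therefore
#' `CO * (period / systole) * (pi / 2)`.
#'
#' @param case A [case_spec()].
#' @param n_samples Number of uniform time samples over one cycle (>= 50).
#' @return An object of class `waveform`: list with `t` (s), `q` (L/min),
#'   `systole_duration_s`, `period_s`, `q_peak_l_min`.
#' @export
#' @examples
#' wf <- pulsatile_waveform(case_spec(27, 0, 5))
#' max(wf$q)  # ~22.4 L/min
pulsatile_waveform <- function(case, n_samples = 200) {
  if (n_samples < 50) stop("n_samples must be >= 50", call. = FALSE)
  period <- 60 / case$heart_rate_bpm
  ts <- case$systole_duration_s
  q_peak <- case$cardiac_output_l_min * (period / ts) * (pi / 2)
  t <- seq(0, period, length.out = n_samples + 1)[seq_len(n_samples)]
  q <- ifelse(t < ts, q_peak * sin(pi * t / ts), 0)
  structure(list(t = t, q = q, systole_duration_s = ts, period_s = period,
                 q_peak_l_min = q_peak),
            class = "waveform")
}

#' Volumetric flow at an arbitrary time
#'
#' Evaluates the closed-form half-sine waveform (periodic continuation).
#'
#' @param waveform A [pulsatile_waveform()] object.
#' @param t Time(s) in seconds.
#' @return Flow in L/min.
#' @export
waveform_flow <- function(waveform, t) {
  tp <- t %% waveform$period_s
  ifelse(tp < waveform$systole_duration_s,
         waveform$q_peak_l_min * sin(pi * tp / waveform$systole_duration_s),
         0)
}

# L/min through a circular cross-section of diameter d_mm -> plug velocity m/s
flow_to_velocity <- function(q_l_min, diameter_mm) {
  area <- pi * (diameter_mm / 2000)^2
  (q_l_min / 60000) / area
}

#' Plug inlet velocity from the waveform
#'
#' The 3D-equivalent volumetric flow is converted through the circular LVOT
#' cross-section, `U = Q / (pi D^2 / 4)`, and applied uniformly across the
#' 2D inlet opening.
#'
#' @param waveform A [pulsatile_waveform()] object.
#' @param diameter_mm LVOT hydraulic diameter in mm (> 0).
#' @param t Time(s) in seconds.
#' @return Plug velocity in m/s.
#' @export
#' @examples
#' wf <- pulsatile_waveform(case_spec(27, 0, 5))
#' inlet_velocity(wf, 27, 0.15)  # peak systole, ~0.65 m/s
inlet_velocity <- function(waveform, diameter_mm, t) {
  stopifnot(diameter_mm > 0)
  flow_to_velocity(waveform_flow(waveform, t), diameter_mm)
}

#' Oscillatory plane-channel (Womersley) velocity profile
#'
#' Exact periodic solution of `du/dt = G cos(phase) + nu d2u/dy2` with
#' no-slip at `y = +/- half_width`, evaluated via the complex closed form
#' `u = Re[(G / (i w)) (1 - cosh(sqrt(i w / nu) y) / cosh(sqrt(i w / nu) H))
#' e^{i phase}]`. The viscosity is implied by the Womersley number:
#' `nu = omega * half_width^2 / alpha^2`.
#'
#' @param grad_amp Amplitude of the kinematic pressure-gradient forcing
#'   (m/s2).
#' @param alpha Womersley number (> 0).
#' @param phase Phase `omega * t` in radians.
#' @param y Cross-stream positions in m, `|y| <= half_width` (wall values
#'   return exactly 0).
#' @param half_width Channel half-width in m.
#' @param omega Angular frequency in rad/s.
#' @return Velocity in m/s at each `y`.
#' @export
womersley_profile <- function(grad_amp, alpha, phase, y, half_width = 1,
                              omega = 2 * pi) {
  stopifnot(alpha > 0, half_width > 0, omega > 0)
  nu <- omega * half_width^2 / alpha^2
  beta <- sqrt(complex(real = 0, imaginary = omega / nu))
  amp <- (grad_amp / complex(real = 0, imaginary = omega)) *
    (1 - cosh(beta * y) / cosh(beta * half_width))
  out <- Re(amp * exp(complex(real = 0, imaginary = phase)))
  out[abs(abs(y) - half_width) < .Machine$double.eps * 100] <- 0
  out
}

#' Quasi-steady (Poiseuille) limit of the oscillatory channel profile
#'
#' @inheritParams womersley_profile
#' @return `G * cos(phase) * (H^2 - y^2) / (2 nu)` with
#'   `nu = omega H^2 / alpha^2`.
#' @export
poiseuille_profile <- function(grad_amp, alpha, phase, y, half_width = 1,
                               omega = 2 * pi) {
  nu <- omega * half_width^2 / alpha^2
  grad_amp * cos(phase) * (half_width^2 - y^2) / (2 * nu)
}

#' Synthetic velocity field with prescribed jet maxima
#'
#' Builds a smooth, solver-free velocity snapshot whose maximum speed in the
#' downstream (sinus plus aorta) region equals `vpeak_target` and whose
#' maximum in the LVOT equals `vlvot_target`, exactly, with zero velocity on
#' solid cells. Used as a fixture generator for the Doppler stage. The jet
#' core is placed slightly off the centerline so the field resembles a
#' lateralized transvalvular jet.
#'
#' @param vpeak_target Downstream maximum speed, m/s (>= `vlvot_target`).
#' @param vlvot_target LVOT maximum speed, m/s (>= 0).
#' @param mask A `solid_mask` from [build_geometry()].
#' @return An object of class `analytic_field`: list with cell-centered `u`,
#'   `v` (nx x ny, m/s), `t` and `provenance`.
#' @export
#' @examples
#' m <- build_geometry(case_spec(27, 0, 5), geometry_params(grid_spacing_mm = 0.9))
#' f <- synthetic_jet_field(3, 1, m)
#' max(f$u[region_cells(m, c("SINUS", "AORTA"))])  # exactly 3
synthetic_jet_field <- function(vpeak_target, vlvot_target, mask) {
  if (!(vpeak_target >= vlvot_target && vlvot_target >= 0))
    stop("need vpeak_target >= vlvot_target >= 0", call. = FALSE)
  d <- mask$case$lvot_diameter_mm
  y_jet <- mask$centerline_mm + d / 8
  sigma <- max(d / 6, 2 * mask$spacing)
  shape <- outer(rep(1, mask$nx), exp(-((mask$yc - y_jet) / sigma)^2 / 2))
  shape[mask$solid] <- 0

  u <- matrix(0, mask$nx, mask$ny)
  down <- region_cells(mask, c("SINUS", "AORTA"))
  lvot <- region_cells(mask, "LVOT")
  valve <- region_cells(mask, "VALVE_PLANE")
  scale_region <- function(cells, target) {
    m <- max(shape[cells])
    if (m > 0 && target > 0) u[cells] <<- shape[cells] * (target / m)
  }
  scale_region(down, vpeak_target)
  scale_region(lvot, vlvot_target)
  scale_region(valve, vlvot_target)
  structure(list(u = u, v = matrix(0, mask$nx, mask$ny), t = 0,
                 provenance = list(kind = "synthetic_jet_field",
                                   vpeak_target = vpeak_target,
                                   vlvot_target = vlvot_target)),
            class = "analytic_field")
}

#' Export a waveform as a two-column CSV
#' @param waveform A [pulsatile_waveform()] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(waveform, path) {
  write.csv(data.frame(t_s = waveform$t, q_l_min = waveform$q), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
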