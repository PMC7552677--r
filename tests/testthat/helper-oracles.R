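# Independent oracles used across the suite.

# Oscillatory plane-channel solution by Fourier cosine eigenfunction series:
# u_t = G cos(phase) + nu u_yy, u(+-H) = 0. Independent of the closed-form
# cosh evaluation in the package.
womersley_series_oracle <- function(grad_amp, alpha, phase, y, half_width = 1,
                                    omega = 2 * pi, n_terms = 20000) {
  nu <- omega * half_width^2 / alpha^2
  n <- seq_len(n_terms) - 1
  lambda <- ((2 * n + 1) * pi / (2 * half_width))^2
  cn <- 4 * (-1)^n / ((2 * n + 1) * pi)
  bn <- grad_amp * cn / complex(real = nu * lambda, imaginary = omega)
  phi <- cos(outer(y, (2 * n + 1) * pi / (2 * half_width)))
  drop(Re(phi %*% (bn * exp(complex(real = 0, imaginary = phase)))))
}

# Brute-force confusion counting by explicit iteration over cases.
brute_confusion <- function(flags, labels) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(flags)) {
    if (flags[i] && labels[i]) tp <- tp + 1L
    else if (flags[i] && !labels[i]) fp <- fp + 1L
    else if (!flags[i] && labels[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(sens = 100 * tp / (tp + fn), spec = 100 * tn / (tn + fp),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

# Small coarse geometry shared by fixture-level tests.
coarse_geo <- function() geometry_params(grid_spacing_mm = 0.9)

coarse_mask <- function(d = 27, f = 0, q = 5)
  build_geometry(case_spec(d, f, q), coarse_geo())

# Open rectangular mask (solid border, fluid interior) for operator tests.
box_mask <- function(nx = 24, ny = 20, h = 1) {
  solid <- matrix(FALSE, nx, ny)
  solid[c(1, nx), ] <- TRUE
  solid[, c(1, ny)] <- TRUE
  region <- matrix(REGION_CODES_TEST[["AORTA"]], nx, ny)
  region[solid] <- REGION_CODES_TEST[["SOLID"]]
  structure(list(solid = solid, region = region, origin = c(0, 0),
                 spacing = h, nx = nx, ny = ny,
                 xc = (seq_len(nx) - 0.5) * h, yc = (seq_len(ny) - 0.5) * h,
                 centerline_mm = ny * h / 2,
                 valve_x_mm = nx * h / 2,
                 valve_band_mm = c(nx * h / 2, nx * h / 2 + 2 * h),
                 case = case_spec(27, 0, 5),
                 params = coarse_geo()),
            class = "solid_mask")
}

REGION_CODES_TEST <- c(SOLID = 0L, LVOT = 1L, VALVE_PLANE = 2L, SINUS = 3L,
                       AORTA = 4L)

# cell-centered analytic snapshot on a mask
analytic_snapshot <- function(mask, u, v, t = 0)
  structure(list(u = u, v = v, t = t,
                 provenance = list(kind = "test")),
            class = "analytic_field")
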