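# Post-processing of flow snapshots: cell-centered velocities, vorticity,
# viscous and turbulent (modeled Reynolds) shear stress, and peak search
# over regions and time.

#' Cell-centered velocity components of a snapshot
#'
#' Staggered `flow_field`s are averaged to cell centers; `analytic_field`s
#' are already cell-centered. Solid cells are zero.
#'
#' @param field A `flow_field` or `analytic_field`.
#' @param mask A `solid_mask`.
#' @return List with `u`, `v`, `speed` (nx x ny matrices, m/s).
#' @export
cell_velocity <- function(field, mask) {
  if (inherits(field, "analytic_field") ||
      (nrow(field$u) == mask$nx && ncol(field$v) == mask$ny)) {
    u <- field$u
    v <- field$v
  } else {
    nx <- mask$nx; ny <- mask$ny
    u <- 0.5 * (field$u[1:nx, , drop = FALSE] +
                  field$u[2:(nx + 1), , drop = FALSE])
    v <- 0.5 * (field$v[, 1:ny, drop = FALSE] +
                  field$v[, 2:(ny + 1), drop = FALSE])
  }
  u[mask$solid] <- 0
  v[mask$solid] <- 0
  list(u = u, v = v, speed = sqrt(u^2 + v^2))
}

# cell-centered derivative with no-slip one-sided differences at walls:
# a solid (or out-of-domain) neighbour contributes the mirrored value -q,
# placing the zero-velocity wall halfway between the cell centers
masked_gradient <- function(q, mask, dim) {
  nx <- mask$nx; ny <- mask$ny
  h <- mask$spacing / 1000
  shift <- function(m, di, dj, fill) {
    out <- matrix(fill, nx, ny)
    si <- seq_len(nx) + di
    sj <- seq_len(ny) + dj
    ok_i <- si >= 1 & si <= nx
    ok_j <- sj >= 1 & sj <= ny
    out[ok_i, ok_j] <- m[si[ok_i], sj[ok_j]]
    out
  }
  di <- if (dim == 1) 1 else 0
  dj <- if (dim == 1) 0 else 1
  fl <- !mask$solid
  qp <- shift(q, di, dj, 0); fp <- shift(fl, di, dj, FALSE)
  qm <- shift(q, -di, -dj, 0); fm <- shift(fl, -di, -dj, FALSE)
  qp[!fp] <- -q[!fp]
  qm[!fm] <- -q[!fm]
  g <- (qp - qm) / (2 * h)
  g[mask$solid] <- 0
  g
}

#' Out-of-plane vorticity of a snapshot
#'
#' `omega_z = dv/dx - du/dy` on interpolated cell-center velocities by
#' centered differences, one-sided (no-slip) at solid boundaries.
#'
#' @param field A `flow_field` or `analytic_field`.
#' @param mask A `solid_mask`.
#' @return nx x ny matrix in 1/s (zero on solids).
#' @export
vorticity <- function(field, mask) {
  cv <- cell_velocity(field, mask)
  masked_gradient(cv$v, mask, 1) - masked_gradient(cv$u, mask, 2)
}

#' Viscous and turbulent shear-stress fields
#'
#' Viscous shear `mu (du/dy + dv/dx)`; turbulent shear is the modeled
#' Reynolds shear stress of the eddy-viscosity closure,
#' `rho nu_t (du/dy + dv/dx)`, identically zero in laminar mode.
#'
#' @param field A `flow_field` or `analytic_field`.
#' @param turb A [turbulence_state()] or a snapshot carrying `nut`; `NULL`
#'   in laminar mode.
#' @param props A [blood_properties()].
#' @param mask A `solid_mask`.
#' @return List with `viscous` and `turbulent` nx x ny matrices (Pa).
#' @export
shear_stresses <- function(field, turb = NULL, props = blood_properties(),
                           mask) {
  cv <- cell_velocity(field, mask)
  strain <- masked_gradient(cv$u, mask, 2) + masked_gradient(cv$v, mask, 1)
  nut <- NULL
  if (!is.null(turb) && !is.null(turb$nut)) nut <- turb$nut
  if (is.null(nut) && !is.null(field$nut)) nut <- field$nut
  turbulent <- if (is.null(nut)) matrix(0, mask$nx, mask$ny)
               else props$density * nut * strain
  list(viscous = props$dynamic_viscosity * strain, turbulent = turbulent)
}

quantity_field <- function(field, mask, quantity, props) {
  switch(quantity,
         speed = cell_velocity(field, mask)$speed,
         u = cell_velocity(field, mask)$u,
         v = cell_velocity(field, mask)$v,
         vorticity = vorticity(field, mask),
         abs_vorticity = abs(vorticity(field, mask)),
         viscous_shear = shear_stresses(field, NULL, props, mask)$viscous,
         turbulent_shear = shear_stresses(field, NULL, props,
                                          mask)$turbulent,
         pressure = field$p,
         stop("unknown quantity: ", quantity, call. = FALSE))
}

#' Peak of a quantity over a region and a snapshot series
#'
#' Maximum over all snapshots and all cells of the region, with a
#' deterministic tie-break: earliest snapshot time first, then lowest cell
#' index (column-major).
#'
#' @param series A `case_run`, a list of snapshots, or a single snapshot.
#' @param mask A `solid_mask`.
#' @param region Character vector of region labels, or a logical nx x ny
#'   matrix of cells.
#' @param quantity One of `"speed"`, `"u"`, `"v"`, `"vorticity"`,
#'   `"abs_vorticity"`, `"viscous_shear"`, `"turbulent_shear"`,
#'   `"pressure"`.
#' @param props A [blood_properties()] (for stress quantities).
#' @return List with `value`, `i`, `j` (cell indices), `time`.
#' @export
peak_over <- function(series, mask, region = c("SINUS", "AORTA"),
                      quantity = "speed", props = blood_properties()) {
  if (inherits(series, "case_run")) { mask <- series$mask
                                      series <- series$snapshots }
  if (inherits(series, c("flow_field", "analytic_field")))
    series <- list(series)
  cells <- if (is.matrix(region)) region else region_cells(mask, region)
  if (!any(cells)) stop("empty region", call. = FALSE)
  # order by time; ties resolved by original order then linear index
  times <- vapply(series, function(s) if (is.null(s$t)) 0 else s$t,
                  numeric(1))
  ord <- order(times)
  best <- list(value = -Inf, i = NA_integer_, j = NA_integer_,
               time = NA_real_)
  for (s in ord) {
    qf <- quantity_field(series[[s]], mask, quantity, props)
    qf[!cells] <- -Inf
    m <- max(qf)
    if (m > best$value) {
      idx <- which(qf == m)[1]
      best <- list(value = m,
                   i = ((idx - 1) %% mask$nx) + 1L,
                   j = ((idx - 1) %/% mask$nx) + 1L,
                   time = times[s])
    }
  }
  best
}

#' Cross-stream jet profile just downstream of the valve
#'
#' Speed profile across the channel a few cells downstream of the valve
#' band, used to characterise the jet arrangement (three jets for a healthy
#' valve, a dominant lateral jet for a fully dysfunctional leaflet).
#'
#' @param field A snapshot.
#' @param mask A `solid_mask`.
#' @param offset_mm Distance downstream of the valve band, mm.
#' @return Data.frame with `y_mm` (relative to the centerline) and `speed`.
#' @export
jet_profile <- function(field, mask, offset_mm = 2) {
  x_target <- mask$valve_band_mm[2] + offset_mm
  i <- which.min(abs(mask$xc - x_target))
  sp <- cell_velocity(field, mask)$speed[i, ]
  data.frame(y_mm = mask$yc - mask$centerline_mm, speed = sp)
}

#' Count distinct jets in a cross-stream profile
#'
#' A jet is a contiguous run of cells whose speed exceeds `frac` times the
#' profile maximum.
#'
#' @param field A snapshot.
#' @param mask A `solid_mask`.
#' @param offset_mm Distance downstream of the valve band, mm.
#' @param frac Threshold fraction of the profile maximum.
#' @return Integer jet count.
#' @export
jet_count <- function(field, mask, offset_mm = 2, frac = 0.35) {
  prof <- jet_profile(field, mask, offset_mm)
  thr <- frac * max(prof$speed)
  r <- rle(prof$speed > thr)
  sum(r$values)
}
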