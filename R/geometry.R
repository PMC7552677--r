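# Parametric 2D channel geometry: tunnel subaortic stenosis in the LVOT,
# an expansion cone to the 27 mm annulus, two rigid leaflets at
# dysfunction-dependent angles, a sinus bulge and the ascending aorta,
# rasterized to a masked-cell representation on a uniform Cartesian grid.

REGION_CODES <- c(SOLID = 0L, LVOT = 1L, VALVE_PLANE = 2L, SINUS = 3L,
                  AORTA = 4L)

#' Geometry parameters of the outflow tract and valve
#'
#' Defaults are representative of a 27 mm bileaflet mechanical valve in a
#' straight outflow tract: leaflets 12 mm long and 0.8 mm thick pivoting at
#' hinge points offset 4 mm from the centerline, opening travel from 25
#' (closed) to 85 degrees (fully open) measured from the valve plane, a
#' 4 mm deep sinus bulge over 25 mm, and LVOT/expansion/aorta segment
#' lengths of 30/20/80 mm.
#'
#' @param aorta_width_mm Aorta (annulus) width in mm.
#' @param lvot_length_mm Length of the tunnel-shaped stenotic LVOT segment.
#' @param stenosis_length_mm Length of the conical expansion from the tunnel
#'   width to the annulus width, immediately upstream of the valve plane.
#' @param sinus_length_mm,aorta_length_mm Lengths of the sinus and aorta
#'   segments downstream of the valve plane.
#' @param sinus_bulge_depth_mm Depth of the (two-sided) sinus bulge.
#' @param leaflet_length_mm,leaflet_thickness_mm Leaflet dimensions.
#' @param hinge_offset_mm Distance of each hinge point from the centerline.
#' @param open_angle_deg,closed_angle_deg Leaflet angle from the valve plane
#'   when fully open / fully closed; `0 < closed < open <= 90`.
#' @param grid_spacing_mm Uniform cell size of the Cartesian mask.
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(aorta_width_mm = 27,
                            lvot_length_mm = 30,
                            stenosis_length_mm = 20,
                            sinus_length_mm = 25,
                            aorta_length_mm = 80,
                            sinus_bulge_depth_mm = 4,
                            leaflet_length_mm = 12,
                            leaflet_thickness_mm = 0.8,
                            hinge_offset_mm = 4,
                            open_angle_deg = 85,
                            closed_angle_deg = 25,
                            grid_spacing_mm = 0.45) {
  p <- list(aorta_width_mm = aorta_width_mm,
            lvot_length_mm = lvot_length_mm,
            stenosis_length_mm = stenosis_length_mm,
            sinus_length_mm = sinus_length_mm,
            aorta_length_mm = aorta_length_mm,
            sinus_bulge_depth_mm = sinus_bulge_depth_mm,
            leaflet_length_mm = leaflet_length_mm,
            leaflet_thickness_mm = leaflet_thickness_mm,
            hinge_offset_mm = hinge_offset_mm,
            open_angle_deg = open_angle_deg,
            closed_angle_deg = closed_angle_deg,
            grid_spacing_mm = grid_spacing_mm)
  lens <- p[c("aorta_width_mm", "lvot_length_mm", "stenosis_length_mm",
              "sinus_length_mm", "aorta_length_mm", "sinus_bulge_depth_mm",
              "leaflet_length_mm", "leaflet_thickness_mm", "hinge_offset_mm",
              "grid_spacing_mm")]
  if (any(!vapply(lens, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x) && x > 0, logical(1))))
    stop("all geometry lengths must be positive scalars", call. = FALSE)
  if (!(closed_angle_deg > 0 && closed_angle_deg < open_angle_deg &&
        open_angle_deg <= 90))
    stop("need 0 < closed_angle_deg < open_angle_deg <= 90", call. = FALSE)
  structure(p, class = "geometry_params")
}

#' Leaflet angles for a given dysfunction level
#'
#' The functional leaflet always sits at the fully open angle; the affected
#' leaflet is linearly interpolated from the open angle (0% dysfunction) to
#' the fully closed angle (100%).
#'
#' @param dysfunction_pct One-leaflet opening restriction in percent, 0-100.
#' @param params A [geometry_params()] object.
#' @return Named numeric vector `c(functional = , affected = )` in degrees
#'   from the valve plane.
#' @export
leaflet_angles <- function(dysfunction_pct, params = geometry_params()) {
  if (!is.finite(dysfunction_pct) || dysfunction_pct < 0 ||
      dysfunction_pct > 100)
    stop("dysfunction_pct must lie in [0, 100]", call. = FALSE)
  aff <- params$open_angle_deg +
    (params$closed_angle_deg - params$open_angle_deg) * dysfunction_pct / 100
  c(functional = params$open_angle_deg, affected = aff)
}

#' Rasterize thick line segments onto a boolean grid
#'
#' A cell is marked solid iff its center lies within the thickness envelope
#' (capsule) of some segment. Deterministic in the segment order.
#'
#' @param segments List of segments, each a list with `x0, y0, x1, y1,
#'   thickness` (all in mm, domain coordinates).
#' @param nx,ny Grid dimensions (cells).
#' @param spacing Cell size in mm.
#' @param origin Coordinates of the lower-left domain corner, mm.
#' @return An `nx` x `ny` logical matrix (TRUE = solid).
#' @export
rasterize_segments <- function(segments, nx, ny, spacing, origin = c(0, 0)) {
  solid <- matrix(FALSE, nx, ny)
  if (length(segments) == 0L) return(solid)
  xc <- origin[1] + (seq_len(nx) - 0.5) * spacing
  yc <- origin[2] + (seq_len(ny) - 0.5) * spacing
  X <- matrix(xc, nx, ny)
  Y <- matrix(yc, nx, ny, byrow = TRUE)
  for (s in segments) {
    dx <- s$x1 - s$x0
    dy <- s$y1 - s$y0
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      hit <- (X - s$x0)^2 + (Y - s$y0)^2 <= (s$thickness / 2)^2 + 1e-12
    } else {
      # rectangle envelope: within the segment extent longitudinally and
      # within half the thickness perpendicular to it (no end caps)
      tt <- ((X - s$x0) * dx + (Y - s$y0) * dy) / len2
      d2 <- (X - (s$x0 + tt * dx))^2 + (Y - (s$y0 + tt * dy))^2
      hit <- tt >= -1e-12 & tt <= 1 + 1e-12 &
        d2 <= (s$thickness / 2)^2 + 1e-12
    }
    solid <- solid | hit
  }
  solid
}

#' Build the rasterized case geometry
#'
#' Lays out, along the streamwise x axis: a tunnel-shaped stenotic LVOT at
#' the case's hydraulic diameter, a conical expansion to the annulus width,
#' the valve plane with two rigid leaflets at dysfunction-dependent angles,
#' a sinus bulge and the ascending aorta. Walls and leaflets are rasterized
#' as solid cells; thin structures are inflated to at least two cells so the
#' mask stays watertight on coarse grids.
#'
#' @param case A [case_spec()].
#' @param params A [geometry_params()].
#' @return An object of class `solid_mask`: list with `solid` (nx x ny
#'   logical), `region` (nx x ny integer, see `REGION_CODES`), `origin`,
#'   `spacing` (mm), cell-center coordinates `xc`, `yc` (mm), `valve_x_mm`,
#'   `valve_band_mm`, `centerline_mm` and the generating `case`/`params`.
#' @export
build_geometry <- function(case, params = geometry_params()) {
  h <- params$grid_spacing_mm
  d <- case$lvot_diameter_mm
  half_a <- params$aorta_width_mm / 2
  x_valve <- params$lvot_length_mm + params$stenosis_length_mm
  lx <- x_valve + params$sinus_length_mm + params$aorta_length_mm
  wall_margin <- 2  # mm of solid wall beyond the widest fluid section
  ly <- params$aorta_width_mm + 2 * params$sinus_bulge_depth_mm +
    2 * wall_margin
  nx <- round(lx / h)
  ny <- round(ly / h)
  yc_mid <- ny * h / 2
  xc <- (seq_len(nx) - 0.5) * h
  # centered ordinates so the channel is exactly mirror-symmetric in
  # floating point: dyc[ny + 1 - j] == -dyc[j]
  dyc <- (seq_len(ny) - 0.5 - ny / 2) * h
  yc <- yc_mid + dyc

  half_width <- function(x) {
    hw <- numeric(length(x))
    tun <- x <= params$lvot_length_mm
    hw[tun] <- d / 2
    cone <- x > params$lvot_length_mm & x <= x_valve
    f <- (x[cone] - params$lvot_length_mm) / params$stenosis_length_mm
    hw[cone] <- d / 2 + f * (half_a - d / 2)
    sinus <- x > x_valve & x <= x_valve + params$sinus_length_mm
    hw[sinus] <- half_a + params$sinus_bulge_depth_mm *
      sin(pi * (x[sinus] - x_valve) / params$sinus_length_mm)
    ao <- x > x_valve + params$sinus_length_mm
    hw[ao] <- half_a
    hw
  }
  hw <- half_width(xc)
  fluid <- outer(seq_len(nx), seq_len(ny),
                 function(i, j) abs(dyc[j]) < hw[i] - 1e-9)

  # leaflets: rigid segments pivoted at the hinge points on the valve
  # plane. Both are rasterized in the upper half and the functional one is
  # mirrored, so a healthy valve is exactly mirror-symmetric cell-wise.
  ang <- leaflet_angles(case$dysfunction_pct, params)
  t_eff <- max(params$leaflet_thickness_mm, 2 * h)
  upper_seg <- function(theta_deg) {
    th <- theta_deg * pi / 180
    y0 <- yc_mid + params$hinge_offset_mm
    list(x0 = x_valve, y0 = y0,
         x1 = x_valve + params$leaflet_length_mm * sin(th),
         y1 = y0 + params$leaflet_length_mm * cos(th),
         thickness = t_eff)
  }
  leaf_aff <- rasterize_segments(list(upper_seg(ang[["affected"]])),
                                 nx, ny, h)
  leaf_fun <- rasterize_segments(list(upper_seg(ang[["functional"]])),
                                 nx, ny, h)[, rev(seq_len(ny)), drop = FALSE]
  solid <- !fluid | leaf_aff | leaf_fun

  min_gap <- min(d, 2 * params$hinge_offset_mm - t_eff)
  if (min_gap < 3 * h)
    stop("grid too coarse: spacing ", h,
         " mm cannot resolve the narrowest gap (", round(min_gap, 2), " mm)",
         call. = FALSE)

  valve_band <- c(x_valve,
                  x_valve + params$leaflet_length_mm *
                    sin(params$open_angle_deg * pi / 180) + t_eff)
  region <- matrix(REGION_CODES[["AORTA"]], nx, ny)
  region[xc <= x_valve + params$sinus_length_mm, ] <- REGION_CODES[["SINUS"]]
  region[xc >= valve_band[1] & xc <= valve_band[2], ] <-
    REGION_CODES[["VALVE_PLANE"]]
  region[xc < x_valve, ] <- REGION_CODES[["LVOT"]]
  region[solid] <- REGION_CODES[["SOLID"]]

  structure(list(solid = solid, region = region,
                 origin = c(0, 0), spacing = h, nx = nx, ny = ny,
                 xc = xc, yc = yc, centerline_mm = yc_mid,
                 valve_x_mm = x_valve, valve_band_mm = valve_band,
                 case = case, params = params),
            class = "solid_mask")
}

#' Fluid-gap widths across the valve plane
#'
#' A cross-stream row counts as open iff it is fluid at every streamwise
#' position within the valve band (the x range swept by a fully open
#' leaflet), so a leaflet blocks a row wherever it crosses it. Contiguous
#' runs of open rows are the valve orifices.
#'
#' @param mask A `solid_mask`.
#' @return Numeric vector of gap widths in mm, ordered bottom to top.
#' @export
#' @examples
#' m <- build_geometry(case_spec(27, 0, 5), geometry_params(grid_spacing_mm = 0.9))
#' length(orifice_widths(m))  # 3: two lateral orifices and one central
orifice_widths <- function(mask) {
  band <- mask$xc >= mask$valve_band_mm[1] & mask$xc <= mask$valve_band_mm[2]
  if (!any(band)) stop("valve band not on the grid", call. = FALSE)
  open_row <- apply(!mask$solid[band, , drop = FALSE], 2, all)
  if (!any(open_row))
    stop("fully occluded valve: no fluid gap across the valve plane",
         call. = FALSE)
  r <- rle(open_row)
  widths <- r$lengths[r$values] * mask$spacing
  as.numeric(widths)
}

#' Cells belonging to a set of named regions
#' @param mask A `solid_mask`.
#' @param labels Character vector of region names (e.g. `c("SINUS","AORTA")`).
#' @return Logical nx x ny matrix.
#' @export
region_cells <- function(mask, labels) {
  codes <- REGION_CODES[labels]
  if (anyNA(codes)) stop("unknown region label", call. = FALSE)
  matrix(mask$region %in% codes, mask$nx, mask$ny)
}

#' Fraction of the domain that is solid
#' @param mask A `solid_mask`.
#' @return Scalar in (0, 1).
#' @export
solid_fraction <- function(mask) mean(mask$solid)
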