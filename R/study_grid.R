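#' @useDynLib bmhvflow, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd approx
#' @importFrom utils write.csv read.csv modifyList
"_PACKAGE"

LVOT_DIAMETERS_MM <- c(27, 25, 23, 21, 19)
DYSFUNCTION_LEVELS_PCT <- c(0, 50, 100)
CARDIAC_OUTPUTS_L_MIN <- c(3, 5, 7)
ANNULUS_DIAMETER_MM <- 27

#' Blood properties
#'
#' Newtonian blood at the values used throughout the study: density
#' 1060 kg/m3 and dynamic viscosity 0.0035 Pa s.
#'
#' @param density Blood density in kg/m3.
#' @param dynamic_viscosity Dynamic viscosity in Pa s.
#' @return An object of class `blood_properties` with fields `density`,
#'   `dynamic_viscosity` and the derived kinematic viscosity `nu` (m2/s).
#' @export
#' @examples
#' blood_properties()
blood_properties <- function(density = 1060, dynamic_viscosity = 0.0035) {
  stopifnot(is.numeric(density), length(density) == 1L, density > 0,
            is.numeric(dynamic_viscosity), length(dynamic_viscosity) == 1L,
            dynamic_viscosity > 0)
  structure(list(density = density,
                 dynamic_viscosity = dynamic_viscosity,
                 nu = dynamic_viscosity / density),
            class = "blood_properties")
}

#' Define one case of the study grid
#'
#' A case is one combination of outflow-tract (LVOT) hydraulic diameter,
#' one-leaflet dysfunction level and mean cardiac output, at a fixed heart
#' rate of 70 bpm with a 0.3 s systole.
#'
#' @param lvot_diameter_mm LVOT hydraulic diameter in mm; one of 19, 21, 23,
#'   25, 27 (27 mm = no subaortic stenosis).
#' @param dysfunction_pct Opening restriction of one leaflet in percent; one
#'   of 0 (normal), 50 (intermediate) or 100 (fully closed).
#' @param cardiac_output_l_min Cycle-mean volumetric flow in L/min; one of
#'   3, 5 or 7.
#' @param heart_rate_bpm Heart rate in beats per minute.
#' @param systole_duration_s Duration of the systolic ejection phase in
#'   seconds; must be shorter than the cycle period.
#' @return An object of class `case_spec`.
#' @export
#' @examples
#' case_spec(27, 0, 5)
case_spec <- function(lvot_diameter_mm, dysfunction_pct, cardiac_output_l_min,
                      heart_rate_bpm = 70, systole_duration_s = 0.3) {
  if (!lvot_diameter_mm %in% LVOT_DIAMETERS_MM)
    stop("lvot_diameter_mm must be one of ",
         paste(LVOT_DIAMETERS_MM, collapse = ", "), call. = FALSE)
  if (!dysfunction_pct %in% DYSFUNCTION_LEVELS_PCT)
    stop("dysfunction_pct must be one of ",
         paste(DYSFUNCTION_LEVELS_PCT, collapse = ", "), call. = FALSE)
  if (!cardiac_output_l_min %in% CARDIAC_OUTPUTS_L_MIN)
    stop("cardiac_output_l_min must be one of ",
         paste(CARDIAC_OUTPUTS_L_MIN, collapse = ", "), call. = FALSE)
  stopifnot(heart_rate_bpm > 0)
  period <- 60 / heart_rate_bpm
  if (!(systole_duration_s > 0 && systole_duration_s < period))
    stop("systole_duration_s must lie in (0, cycle period)", call. = FALSE)
  structure(list(lvot_diameter_mm = lvot_diameter_mm,
                 dysfunction_pct = dysfunction_pct,
                 cardiac_output_l_min = cardiac_output_l_min,
                 heart_rate_bpm = heart_rate_bpm,
                 systole_duration_s = systole_duration_s),
            class = "case_spec")
}

#' Stable identifier for a case
#'
#' @param case A `case_spec`.
#' @return A string such as `"d27_f0_q5"` (diameter, dysfunction, flow).
#' @export
case_id <- function(case) {
  sprintf("d%d_f%d_q%d", case$lvot_diameter_mm, case$dysfunction_pct,
          case$cardiac_output_l_min)
}

#' Enumerate the study case grid
#'
#' Cartesian product of the parameter lists in a fixed deterministic order:
#' dysfunction level outermost, LVOT diameter next, cardiac output innermost.
#' The default grid is the full 45-case study (3 dysfunction levels x 5
#' diameters x 3 outputs).
#'
#' @param lvot_diameters_mm LVOT diameters in mm (subset of 19, 21, 23, 25, 27).
#' @param dysfunction_pct Dysfunction levels in percent (subset of 0, 50, 100).
#' @param cardiac_outputs_l_min Cardiac outputs in L/min (subset of 3, 5, 7).
#' @param heart_rate_bpm,systole_duration_s Shared timing parameters.
#' @return A data.frame with one row per case (columns `case_id`,
#'   `lvot_diameter_mm`, `dysfunction_pct`, `cardiac_output_l_min`,
#'   `heart_rate_bpm`, `systole_duration_s`).
#' @export
#' @examples
#' nrow(enumerate_cases())  # 45
enumerate_cases <- function(lvot_diameters_mm = LVOT_DIAMETERS_MM,
                            dysfunction_pct = DYSFUNCTION_LEVELS_PCT,
                            cardiac_outputs_l_min = CARDIAC_OUTPUTS_L_MIN,
                            heart_rate_bpm = 70, systole_duration_s = 0.3) {
  check_subset <- function(x, allowed, name) {
    if (length(x) == 0)
      stop(name, " must be non-empty", call. = FALSE)
    bad <- setdiff(x, allowed)
    if (length(bad))
      stop("invalid ", name, ": ", paste(bad, collapse = ", "),
           " (allowed: ", paste(allowed, collapse = ", "), ")", call. = FALSE)
    if (anyDuplicated(x))
      stop(name, " contains duplicates", call. = FALSE)
  }
  check_subset(lvot_diameters_mm, LVOT_DIAMETERS_MM, "lvot_diameters_mm")
  check_subset(dysfunction_pct, DYSFUNCTION_LEVELS_PCT, "dysfunction_pct")
  check_subset(cardiac_outputs_l_min, CARDIAC_OUTPUTS_L_MIN,
               "cardiac_outputs_l_min")
  grid <- expand.grid(cardiac_output_l_min = cardiac_outputs_l_min,
                      lvot_diameter_mm = lvot_diameters_mm,
                      dysfunction_pct = dysfunction_pct,
                      KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(
    case_id = sprintf("d%d_f%d_q%d", grid$lvot_diameter_mm,
                      grid$dysfunction_pct, grid$cardiac_output_l_min),
    lvot_diameter_mm = grid$lvot_diameter_mm,
    dysfunction_pct = grid$dysfunction_pct,
    cardiac_output_l_min = grid$cardiac_output_l_min,
    heart_rate_bpm = heart_rate_bpm,
    systole_duration_s = systole_duration_s,
    stringsAsFactors = FALSE)
  out
}

#' Row of the case manifest as a case_spec
#' @param row One-row data.frame from [enumerate_cases()].
#' @return A `case_spec`.
#' @export
as_case_spec <- function(row) {
  case_spec(row$lvot_diameter_mm, row$dysfunction_pct,
            row$cardiac_output_l_min, row$heart_rate_bpm,
            row$systole_duration_s)
}

#' Cross-sectional area reduction of the subaortic stenosis
#'
#' The hydraulic inlet diameter is interpreted as a circular cross-section,
#' so a 19 mm LVOT against the 27 mm annulus is a 50% area reduction.
#'
#' @param d_mm LVOT hydraulic diameter in mm, in (0, 27].
#' @return Fractional area reduction `1 - (d/27)^2`.
#' @export
#' @examples
#' stenosis_area_reduction(19)  # ~0.505
stenosis_area_reduction <- function(d_mm) {
  if (any(!is.finite(d_mm)) || any(d_mm <= 0) || any(d_mm > ANNULUS_DIAMETER_MM))
    stop("d_mm must lie in (0, ", ANNULUS_DIAMETER_MM, "]", call. = FALSE)
  1 - (d_mm / ANNULUS_DIAMETER_MM)^2
}

#' Total valve-area restriction from one-leaflet dysfunction
#'
#' One of the two symmetric leaflets is restricted, so a 50% restriction of
#' one leaflet opening removes 25% of the total valve area and a fully
#' closed leaflet removes 50%.
#'
#' @param dysfunction_pct One-leaflet opening restriction in percent, 0-100.
#' @return Fraction of total valve area restricted (`dysfunction_pct / 200`).
#' @export
valve_area_restriction <- function(dysfunction_pct) {
  if (any(!is.finite(dysfunction_pct)) || any(dysfunction_pct < 0) ||
      any(dysfunction_pct > 100))
    stop("dysfunction_pct must lie in [0, 100]", call. = FALSE)
  dysfunction_pct / 200
}

#' Reynolds number
#'
#' @param velocity Characteristic velocity in m/s.
#' @param diameter Characteristic length in m (> 0).
#' @param props A [blood_properties()] object.
#' @return `rho * V * D / mu`.
#' @export
reynolds_number <- function(velocity, diameter, props = blood_properties()) {
  stopifnot(all(diameter > 0))
  props$density * velocity * diameter / props$dynamic_viscosity
}

#' Womersley number
#'
#' Standard definition `R * sqrt(omega / nu)` with the angular frequency
#' `omega = 2 * pi * f` of the cardiac cycle and kinematic viscosity
#' `nu = mu / rho`.
#'
#' @param radius Characteristic radius in m (> 0 allowed to be 0 for the
#'   degenerate limit).
#' @param heart_rate_bpm Heart rate in beats per minute (> 0).
#' @param props A [blood_properties()] object.
#' @return The dimensionless Womersley number.
#' @export
#' @examples
#' womersley_number(0.0135, 70)  # ~20.1
womersley_number <- function(radius, heart_rate_bpm,
                             props = blood_properties()) {
  stopifnot(all(radius >= 0), heart_rate_bpm > 0)
  f <- heart_rate_bpm / 60
  radius * sqrt(2 * pi * f / props$nu)
}

#' Nondimensional characterization of a case
#'
#' Peak and cycle-mean Reynolds numbers from the pulsatile inflow through
#' the circular LVOT cross-section, plus the Womersley number at the LVOT
#' radius.
#'
#' @param case A `case_spec`.
#' @param props A [blood_properties()] object.
#' @return A list with `re_peak`, `re_mean` and `womersley_alpha`.
#' @export
nondimensional_summary <- function(case, props = blood_properties()) {
  d <- case$lvot_diameter_mm / 1000
  wf <- pulsatile_waveform(case)
  u_peak <- flow_to_velocity(max(wf$q), case$lvot_diameter_mm)
  u_mean <- flow_to_velocity(case$cardiac_output_l_min, case$lvot_diameter_mm)
  list(re_peak = reynolds_number(u_peak, d, props),
       re_mean = reynolds_number(u_mean, d, props),
       womersley_alpha = womersley_number(d / 2, case$heart_rate_bpm, props))
}

#' Export the case manifest as CSV
#' @param cases Data.frame from [enumerate_cases()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_case_manifest <- function(cases, path) {
  write.csv(cases, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
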