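# Clinical Doppler surrogates per case: transvalvular peak velocity,
# LVOT velocity, simplified-Bernoulli pressure gradients, Doppler velocity
# index and effective orifice area.

#' Simplified-Bernoulli transvalvular pressure gradient
#'
#' Clinical convention `TPG = 4 V^2` (mmHg with V in m/s).
#'
#' @param v Velocity in m/s (>= 0).
#' @return Pressure gradient in mmHg.
#' @export
#' @examples
#' bernoulli_tpg(2)  # 16 mmHg
bernoulli_tpg <- function(v) {
  if (any(!is.finite(v)) || any(v < 0))
    stop("v must be non-negative", call. = FALSE)
  4 * v^2
}

#' Mean transvalvular pressure gradient over systole
#'
#' Trapezoidal time-average of the instantaneous simplified-Bernoulli
#' gradient over the systolic window.
#'
#' @param t Sample times in s (at least 2, strictly increasing).
#' @param v Velocities in m/s at `t`.
#' @return Mean gradient in mmHg.
#' @export
tpg_mean <- function(t, v) {
  if (length(t) < 2 || length(t) != length(v))
    stop("need at least 2 paired (t, v) samples within systole",
         call. = FALSE)
  if (any(diff(t) <= 0)) stop("t must be strictly increasing", call. = FALSE)
  g <- bernoulli_tpg(v)
  sum(diff(t) * (g[-1] + g[-length(g)]) / 2) / (max(t) - min(t))
}

#' Doppler velocity index
#'
#' `DVI = V_LVOT / V_peak`; no clamping.
#'
#' @param v_lvot LVOT peak velocity, m/s.
#' @param v_peak Transvalvular peak velocity, m/s (> 0).
#' @return Dimensionless ratio.
#' @export
dvi <- function(v_lvot, v_peak) {
  if (any(v_peak <= 0))
    stop("DVI undefined: v_peak must be positive", call. = FALSE)
  v_lvot / v_peak
}

#' Effective orifice area
#'
#' Continuity-equation estimate `EOA = Q / V_peak` with the peak systolic
#' volumetric flow.
#'
#' @param q_peak Peak systolic flow in cm3/s (>= 0).
#' @param v_peak Transvalvular peak velocity in cm/s (> 0).
#' @return Effective orifice area in cm2.
#' @export
#' @examples
#' eoa(373, 136)  # ~2.74 cm2
eoa <- function(q_peak, v_peak) {
  if (any(v_peak <= 0))
    stop("EOA undefined: v_peak must be positive", call. = FALSE)
  if (any(q_peak < 0)) stop("q_peak must be non-negative", call. = FALSE)
  q_peak / v_peak
}

#' Percent change between two values
#'
#' @param baseline Reference value (non-zero).
#' @param new New value.
#' @return `100 * (new - baseline) / baseline`.
#' @export
#' @examples
#' percent_change(1.36, 1.81)  # ~ +33
percent_change <- function(baseline, new) {
  if (any(baseline == 0))
    stop("baseline must be non-zero", call. = FALSE)
  100 * (new - baseline) / baseline
}

#' Assemble the Doppler report of a case
#'
#' `v_peak` is the peak speed over the valve region, sinus and aorta across
#' the sampled systole; `v_lvot` is the peak speed in an LVOT probe band one
#' LVOT diameter upstream of the valve plane (mimicking the echo sample
#' volume); `tpg_mean` averages the simplified-Bernoulli gradient of the
#' downstream peak-speed trace over the systolic window; `dvi` and `eoa`
#' follow by arithmetic with the waveform's peak systolic flow.
#'
#' @param series A `case_run`, or a list of snapshots.
#' @param mask A `solid_mask` (taken from the `case_run` if omitted).
#' @param waveform A [pulsatile_waveform()] (taken from the `case_run` if
#'   omitted).
#' @param case A [case_spec()] (taken from the `case_run` if omitted).
#' @param probe_offset_mm Distance of the LVOT probe upstream of the valve
#'   plane; default one LVOT diameter.
#' @param probe_halfwidth_mm Streamwise half-width of the probe band, mm.
#' @return An object of class `doppler_report`: list with `case_id`,
#'   `v_peak`, `v_lvot`, `tpg_mean`, `dvi`, `eoa` and probe metadata.
#' @export
doppler_report <- function(series, mask = NULL, waveform = NULL, case = NULL,
                           probe_offset_mm = NULL, probe_halfwidth_mm = 2) {
  if (inherits(series, "case_run")) {
    mask <- series$mask; waveform <- series$waveform; case <- series$case
    series <- series$snapshots
  }
  if (inherits(series, c("flow_field", "analytic_field")))
    series <- list(series)
  stopifnot(!is.null(mask), !is.null(waveform), !is.null(case))
  if (is.null(probe_offset_mm)) probe_offset_mm <- case$lvot_diameter_mm

  down <- region_cells(mask, c("VALVE_PLANE", "SINUS", "AORTA"))
  x_probe <- mask$valve_x_mm - probe_offset_mm
  probe <- region_cells(mask, "LVOT") &
    matrix(abs(mask$xc - x_probe) <= probe_halfwidth_mm, mask$nx, mask$ny)
  if (!any(probe))
    stop("LVOT probe band lies outside the grid; reduce probe_offset_mm",
         call. = FALSE)

  pk <- peak_over(series, mask, down, "speed")
  if (!is.finite(pk$value) || pk$value <= 0)
    stop("Doppler metrics undefined: no positive downstream velocity",
         call. = FALSE)
  pl <- peak_over(series, mask, probe, "speed")

  # downstream peak-speed trace over the systolic window of the last cycle
  times <- vapply(series, function(s) if (is.null(s$t)) 0 else s$t,
                  numeric(1))
  phase <- times %% waveform$period_s
  in_sys <- phase <= waveform$systole_duration_s + 1e-9
  idx <- which(in_sys)[!duplicated(round(phase[in_sys], 9))]
  tpg <- if (length(idx) >= 2) {
    tr <- vapply(idx, function(ii) {
      max(cell_velocity(series[[ii]], mask)$speed[down])
    }, numeric(1))
    ord <- order(phase[idx])
    tpg_mean(phase[idx][ord], tr[ord])
  } else {
    bernoulli_tpg(pk$value)
  }

  q_peak_cm3s <- waveform$q_peak_l_min * 1000 / 60
  structure(list(case_id = case_id(case),
                 v_peak = pk$value,
                 v_lvot = pl$value,
                 tpg_mean = tpg,
                 dvi = dvi(pl$value, pk$value),
                 eoa = eoa(q_peak_cm3s, 100 * pk$value),
                 q_peak_cm3s = q_peak_cm3s,
                 probe_offset_mm = probe_offset_mm,
                 peak_time = pk$time),
            class = "doppler_report")
}

#' Doppler reports as a data.frame
#' @param reports A list of `doppler_report`s (optionally with matching
#'   `cases` rows from [enumerate_cases()] to carry the grid coordinates).
#' @param cases Optional data.frame of case rows aligned with `reports`.
#' @return Data.frame with one row per report.
#' @export
reports_to_df <- function(reports, cases = NULL) {
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(case_id = r$case_id, v_peak = r$v_peak, v_lvot = r$v_lvot,
               tpg_mean = r$tpg_mean, dvi = r$dvi, eoa = r$eoa,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(cases)) {
    stopifnot(identical(cases$case_id, df$case_id))
    df <- cbind(cases[c("lvot_diameter_mm", "dysfunction_pct",
                        "cardiac_output_l_min")], df)
  }
  df
}
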