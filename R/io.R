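# Configuration files, snapshot/table export, run manifests and the thin
# command-line dispatcher.

#' Default pipeline configuration
#'
#' The full study: the 45-case grid, standard blood properties, the default
#' valve/outflow-tract geometry and solver settings.
#'
#' @return Nested configuration list with sections `grid`, `properties`,
#'   `geometry`, `solver`.
#' @export
default_config <- function() {
  list(
    grid = list(lvot_diameters_mm = LVOT_DIAMETERS_MM,
                dysfunction_pct = DYSFUNCTION_LEVELS_PCT,
                cardiac_outputs_l_min = CARDIAC_OUTPUTS_L_MIN,
                heart_rate_bpm = 70,
                systole_duration_s = 0.3),
    properties = list(density = 1060, dynamic_viscosity = 0.0035),
    geometry = unclass(geometry_params()),
    solver = unclass(solver_config()))
}

#' Load and validate a pipeline configuration
#'
#' YAML file with any subset of the sections and keys of
#' [default_config()]; missing keys take their defaults, unknown keys are
#' rejected, and values are validated by the corresponding constructors.
#' An empty file yields the full default configuration.
#'
#' @param path Path to a YAML configuration file.
#' @return Validated configuration list (as [default_config()], with
#'   classed `geometry`/`solver` components resolved on use).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("config must be a YAML mapping", call. = FALSE)
  validate_config(user)
}

#' @rdname load_config
#' @param config Partial configuration list to validate and complete.
#' @export
validate_config <- function(config) {
  def <- default_config()
  bad <- setdiff(names(config), names(def))
  if (length(bad))
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (sec in names(config)) {
    if (!is.list(config[[sec]]))
      stop("configuration section '", sec, "' must be a mapping",
           call. = FALSE)
    badk <- setdiff(names(config[[sec]]), names(def[[sec]]))
    if (length(badk))
      stop("unknown key(s) in '", sec, "': ", paste(badk, collapse = ", "),
           call. = FALSE)
  }
  cfg <- modifyList(def, config)
  # validate through the constructors (they raise on invalid values)
  enumerate_cases(cfg$grid$lvot_diameters_mm, cfg$grid$dysfunction_pct,
                  cfg$grid$cardiac_outputs_l_min, cfg$grid$heart_rate_bpm,
                  cfg$grid$systole_duration_s)
  do.call(blood_properties, cfg$properties)
  do.call(geometry_params, cfg$geometry)
  do.call(solver_config, cfg$solver)
  cfg
}

#' Save a configuration as YAML
#' @param config Configuration list.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a snapshot as a legacy-ASCII VTK structured-points file
#'
#' Cell-centered speed, velocity components, pressure and region labels on
#' the uniform grid, readable by standard VTK viewers.
#'
#' @param field A snapshot (`flow_field` or `analytic_field`).
#' @param mask A `solid_mask`.
#' @param path Output `.vtk` file.
#' @return `path`, invisibly.
#' @export
write_field_vtk <- function(field, mask, path) {
  cv <- cell_velocity(field, mask)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("bmhvflow snapshot t=%g", field$t %||% 0),
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", mask$nx, mask$ny),
               sprintf("ORIGIN %g %g 0", mask$origin[1] + mask$spacing / 2,
                       mask$origin[2] + mask$spacing / 2),
               sprintf("SPACING %g %g 1", mask$spacing, mask$spacing),
               sprintf("POINT_DATA %d", mask$nx * mask$ny)), con)
  scalar <- function(name, m) {
    writeLines(c(sprintf("SCALARS %s float 1", name),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(as.vector(m), digits = 7, trim = TRUE,
                      scientific = FALSE), con)
  }
  scalar("speed", cv$speed)
  scalar("u", cv$u)
  scalar("v", cv$v)
  if (!is.null(field$p) && length(field$p)) scalar("pressure", field$p)
  scalar("region", mask$region)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run manifest for a pipeline invocation
#'
#' @param config Configuration list.
#' @param cases Case manifest data.frame.
#' @param outputs Character vector of files produced.
#' @param diagnostics Optional list of solver diagnostics/warning counts.
#' @return Manifest list.
#' @export
run_manifest <- function(config, cases, outputs = character(),
                         diagnostics = list()) {
  list(package = "bmhvflow",
       version = as.character(utils::packageVersion("bmhvflow")),
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       config = config,
       case_ids = cases$case_id,
       outputs = outputs,
       diagnostics = diagnostics)
}

#' Write a manifest as JSON
#' @param manifest From [run_manifest()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run all configured cases and collect Doppler metrics
#'
#' Executes every case of the configured grid with [run_case()], writes one
#' metrics CSV row per case under `out_dir` and a combined `metrics.csv`,
#' and records a JSON manifest. With `resume = TRUE`, cases whose per-case
#' CSV already exists are skipped and their stored metrics reused.
#'
#' @param config Configuration list (see [load_config()]).
#' @param out_dir Output directory (created if needed).
#' @param resume Skip cases with existing outputs.
#' @param quiet Suppress progress messages.
#' @return Data.frame of per-case Doppler metrics (invisibly also written
#'   to `out_dir/metrics.csv`).
#' @export
run_grid <- function(config = default_config(), out_dir, resume = TRUE,
                     quiet = FALSE) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cases <- enumerate_cases(config$grid$lvot_diameters_mm,
                           config$grid$dysfunction_pct,
                           config$grid$cardiac_outputs_l_min,
                           config$grid$heart_rate_bpm,
                           config$grid$systole_duration_s)
  geo <- do.call(geometry_params, config$geometry)
  scfg <- do.call(solver_config, config$solver)
  props <- do.call(blood_properties, config$properties)
  rows <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    cid <- cases$case_id[i]
    f <- file.path(out_dir, paste0("metrics_", cid, ".csv"))
    if (resume && file.exists(f)) {
      rows[[i]] <- read.csv(f, stringsAsFactors = FALSE)
      if (!quiet) message("skipping completed case ", cid)
      next
    }
    if (!quiet) message("running case ", cid)
    run <- run_case(as_case_spec(cases[i, ]), geo, scfg, props)
    rep <- doppler_report(run)
    row <- cbind(cases[i, c("lvot_diameter_mm", "dysfunction_pct",
                            "cardiac_output_l_min")],
                 reports_to_df(list(rep)),
                 periodicity = run$periodicity,
                 mass_error = run$mass_error)
    write.csv(row, f, row.names = FALSE, quote = FALSE)
    rows[[i]] <- read.csv(f, stringsAsFactors = FALSE)
  }
  metrics <- do.call(rbind, rows)
  write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE,
            quote = FALSE)
  write_case_manifest(cases, file.path(out_dir, "cases.csv"))
  write_manifest(run_manifest(config, cases,
                              outputs = c("metrics.csv", "cases.csv")),
                 file.path(out_dir, "manifest.json"))
  invisible(metrics)
}

#' Accuracy and summary tables from a metrics CSV
#'
#' @param metrics Data.frame of per-case metrics (from [run_grid()]) or a
#'   path to such a CSV.
#' @param out_dir Optional directory to write `accuracy.csv` and
#'   `summary_by_lvot.csv`.
#' @return List with `accuracy` and `summary` data.frames.
#' @export
accuracy_from_metrics <- function(metrics, out_dir = NULL) {
  if (is.character(metrics)) metrics <- read.csv(metrics,
                                                 stringsAsFactors = FALSE)
  acc <- accuracy_table(metrics)
  smry <- summarize_by_lvot(metrics)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(acc, file.path(out_dir, "accuracy.csv"), row.names = FALSE,
              quote = FALSE)
    write.csv(smry, file.path(out_dir, "summary_by_lvot.csv"),
              row.names = FALSE, quote = FALSE)
  }
  list(accuracy = acc, summary = smry)
}

#' Analytic verification gate
#'
#' Runs the plane-Poiseuille and oscillatory-channel benchmarks and checks
#' them against their analytic solutions.
#'
#' @param quick Use reduced problem sizes.
#' @return List with the benchmark results and a logical `ok`.
#' @export
verify_solver <- function(quick = FALSE) {
  po <- poiseuille_benchmark(ny = if (quick) 32 else 64,
                             t_end = if (quick) 0.8 else 1.5)
  wo <- womersley_benchmark(ny = if (quick) 32 else 48,
                            n_periods = if (quick) 2 else 3)
  ok <- abs(po$ratio - 1.5) / 1.5 < 0.02 && po$mass_error < 0.01 &&
    wo$rms_error < 0.05
  list(poiseuille = po, womersley = wo, ok = ok)
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions; used by the
#' `inst/cli/bmhvflow.R` script. Commands: `verify`, `run-case`,
#' `run-grid`, `metrics`, `accuracy`, `report`.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the command's result. Errors on unknown commands.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop("usage: bmhvflow <verify|run-case|run-grid|metrics|accuracy|",
         "report> [--config FILE] [--out DIR] [--case ID]", call. = FALSE)
  cmd <- args[1]
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  cfg <- if (!is.null(opt("config"))) load_config(opt("config"))
         else default_config()
  out <- opt("out", "bmhvflow_out")
  res <- switch(
    cmd,
    "verify" = {
      v <- verify_solver(quick = !is.null(opt("quick", NULL)) ||
                           any(args == "--quick"))
      message(sprintf(
        "Poiseuille centerline/mean ratio: %.4f (analytic 1.5)",
        v$poiseuille$ratio))
      message(sprintf("Womersley profile RMS error: %.2f%%",
                      100 * v$womersley$rms_error))
      message(sprintf("mass-conservation error: %.3g",
                      v$poiseuille$mass_error))
      if (!v$ok) stop("verification failed", call. = FALSE)
      message("verification passed")
      v
    },
    "run-case" = {
      cid <- opt("case")
      if (is.null(cid)) stop("run-case requires --case ID", call. = FALSE)
      cases <- enumerate_cases(cfg$grid$lvot_diameters_mm,
                               cfg$grid$dysfunction_pct,
                               cfg$grid$cardiac_outputs_l_min,
                               cfg$grid$heart_rate_bpm,
                               cfg$grid$systole_duration_s)
      row <- cases[cases$case_id == cid, ]
      if (nrow(row) != 1) stop("unknown case id: ", cid, call. = FALSE)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      run <- run_case(as_case_spec(row),
                      do.call(geometry_params, cfg$geometry),
                      do.call(solver_config, cfg$solver),
                      do.call(blood_properties, cfg$properties))
      rep <- doppler_report(run)
      write.csv(reports_to_df(list(rep)),
                file.path(out, paste0("metrics_", cid, ".csv")),
                row.names = FALSE, quote = FALSE)
      pk <- which.max(vapply(run$snapshots, function(s)
        max(cell_velocity(s, run$mask)$speed), numeric(1)))
      write_field_vtk(run$snapshots[[pk]], run$mask,
                      file.path(out, paste0("peak_", cid, ".vtk")))
      saveRDS(run, file.path(out, paste0("run_", cid, ".rds")))
      rep
    },
    "run-grid" = run_grid(cfg, out, resume = !any(args == "--no-resume")),
    "metrics" = {
      rds <- opt("run")
      if (is.null(rds)) stop("metrics requires --run FILE.rds",
                             call. = FALSE)
      run <- readRDS(rds)
      rep <- doppler_report(run)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write.csv(reports_to_df(list(rep)),
                file.path(out, paste0("metrics_", rep$case_id, ".csv")),
                row.names = FALSE, quote = FALSE)
      rep
    },
    "accuracy" = {
      m <- opt("metrics")
      if (is.null(m)) stop("accuracy requires --metrics FILE.csv ",
                           "(produce it with run-grid)", call. = FALSE)
      accuracy_from_metrics(m, out)
    },
    "report" = {
      m <- opt("metrics")
      if (is.null(m)) stop("report requires --metrics FILE.csv",
                           call. = FALSE)
      tabs <- accuracy_from_metrics(m, out)
      message("accuracy table:")
      message(paste(utils::capture.output(print(
        tabs$accuracy[c("label", "grouping", "sensitivity",
                        "specificity")])), collapse = "\n"))
      tabs
    },
    stop("unknown command: ", cmd, call. = FALSE))
  invisible(res)
}
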