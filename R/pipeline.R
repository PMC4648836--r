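#' Configuration for a pipeline run
#'
#' Flat key-value configuration validated up front; unknown keys are an
#' error. `overrides` (e.g. from CLI flags) take precedence.
#'
#' @param ... configuration values; see Defaults below.
#' @param overrides named list applied on top of `...`.
#' @return validated configuration list of class `run_config`.
#'
#' @section Defaults:
#' \describe{
#'   \item{n_tunnels}{24 phantoms per simulated cohort.}
#'   \item{diameter_grid}{5.0-9.0 mm in 0.5 mm steps.}
#'   \item{seed}{1.}
#'   \item{threshold_low / threshold_high}{bone density range (150, Inf).}
#'   \item{closing_mm}{cavity-closing ball radius, 6 mm.}
#'   \item{station}{transverse-section arc-length fraction, 0.5.}
#'   \item{trim_fraction}{axial end-trim before mesh measurement, 0.15.}
#'   \item{smooth_sigma_voxels}{iso-surfacing smoothing, 1 voxel.}
#'   \item{exclusion_mm}{wall-thickness self-intersection radius, 1 mm.}
#'   \item{out_dir}{output directory (`NULL` = no files written).}
#'   \item{keep_volumes}{write phantom NIfTI volumes (default FALSE; the
#'     meshes and CSVs are the analysis artifacts).}
#' }
#' @export
run_config <- function(..., overrides = list()) {
  defaults <- list(
    n_tunnels = 24L,
    diameter_grid = seq(5, 9, by = 0.5),
    seed = 1L,
    threshold_low = 150,
    threshold_high = Inf,
    closing_mm = 6,
    station = 0.5,
    trim_fraction = 0.15,
    smooth_sigma_voxels = 1,
    exclusion_mm = 1,
    out_dir = NULL,
    keep_volumes = FALSE,
    volume = NULL,          # real-volume mode: input path
    seed_point_mm = NULL,   # real-volume mode: cavity seed
    drill_record = NULL     # real-volume mode: optional truth CSV
  )
  user <- modifyList(list(...), overrides)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(defaults, user)
  stopifnot(cfg$n_tunnels >= 2, length(cfg$diameter_grid) >= 1,
            cfg$threshold_low < cfg$threshold_high, cfg$closing_mm > 0,
            cfg$station > 0, cfg$station < 1,
            cfg$trim_fraction >= 0, cfg$trim_fraction < 0.45)
  structure(cfg, class = "run_config")
}

#' Measure one tunnel cavity from a segmented volume
#'
#' volume -> bone mask -> cavity mask -> iso-surface mesh -> end trim ->
#' all four measurement methods. The shared workhorse of the simulated and
#' real-volume pipelines.
#'
#' @param volume a [ct_volume()].
#' @param seed_point_mm world point inside the tunnel cavity.
#' @param config a [run_config()].
#' @param truth optional [ground_truth()].
#' @param id record identifier.
#' @return list with `records` (from [measure_all()]), `mesh`, `cavity`.
#' @export
measure_volume_tunnel <- function(volume, seed_point_mm, config = run_config(),
                                  truth = NULL, id = "tunnel") {
  bone <- threshold_segment(volume, config$threshold_low, config$threshold_high)
  cavity <- extract_tunnel_cavity(bone, config$closing_mm, seed_point_mm)
  mesh <- mask_to_mesh(cavity, smooth_sigma_voxels = config$smooth_sigma_voxels)
  trimmed <- trim_tunnel_ends(mesh, config$trim_fraction)
  records <- measure_all(trimmed, mask = cavity, truth = truth, id = id,
                         station = config$station,
                         exclusion_radius_mm = config$exclusion_mm)
  list(records = records, mesh = trimmed, cavity = cavity)
}

#' Simulated end-to-end measurement study
#'
#' Generates a phantom cohort with known drill diameters, runs segmentation,
#' meshing and all four measurement methods on every phantom, and compiles
#' the per-method agreement report against the drill sizes. With a fixed
#' seed the measurement CSV/JSON outputs are bit-identical across runs.
#' Per-tunnel failures are recorded and do not abort the cohort.
#'
#' @param config a [run_config()].
#' @return list with `measurements` (long data.frame), `report`
#'   (see [agreement_report()]), `manifest`, `config`, and `out_dir` (path
#'   or `NULL`). Artifacts written under `out_dir`: `config.json`,
#'   `manifest.csv`, `measurements.csv`, `report.csv` / `report.json`,
#'   `log.txt`, plus meshes (`.stl`) and optionally volumes.
#' @export
run_simulated_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  cfg_json <- jsonlite::toJSON(unclass(config)[!vapply(config, is.null,
                                                       logical(1))],
                               auto_unbox = TRUE, digits = NA)
  say("config hash: %s", substr(digest_string(cfg_json), 1, 12))

  cohort <- make_cohort(config$n_tunnels, config$diameter_grid,
                        spec_template = phantom_spec(), seed = config$seed)
  say("generated %d phantoms (%.1f s)", config$n_tunnels,
      proc.time()[["elapsed"]] - t0)

  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  all_records <- vector("list", config$n_tunnels)
  for (i in seq_along(cohort$phantoms)) {
    ph <- cohort$phantoms[[i]]
    ti <- proc.time()[["elapsed"]]
    res <- tryCatch(
      measure_volume_tunnel(ph$volume, ph$truth$axis_point, config,
                            truth = ph$truth, id = ph$truth$id),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      say("%s: FAILED (%s)", ph$truth$id, conditionMessage(res))
      all_records[[i]] <- data.frame(
        id = ph$truth$id, method = "all", diameter_mm = NA_real_,
        true_diameter_mm = ph$truth$true_diameter_mm, error_mm = NA_real_,
        axial_mm = NA_real_, coronal_mm = NA_real_, sagittal_mm = NA_real_,
        note = conditionMessage(res), stringsAsFactors = FALSE)
      next
    }
    all_records[[i]] <- res$records
    say("%s: d=%.1f mm, %d faces, %.1f s", ph$truth$id,
        ph$truth$true_diameter_mm, nrow(res$mesh$faces),
        proc.time()[["elapsed"]] - ti)
    if (!is.null(out_dir)) {
      write_stl(res$mesh, file.path(out_dir,
                                    sprintf("%s.stl", ph$truth$id)))
      if (isTRUE(config$keep_volumes)) {
        write_phantom(ph, file.path(out_dir, ph$truth$id))
      }
    }
  }
  measurements <- do.call(rbind, all_records)
  truths <- data.frame(id = cohort$manifest$id,
                       true_diameter_mm = cohort$manifest$true_diameter_mm,
                       stringsAsFactors = FALSE)
  report <- agreement_report(measurements, truths)
  say("total %.1f s", proc.time()[["elapsed"]] - t0)

  if (!is.null(out_dir)) {
    writeLines(as.character(cfg_json), file.path(out_dir, "config.json"))
    write.csv(cohort$manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
    meas_out <- measurements
    meas_out$diameter_mm <- round(meas_out$diameter_mm, 2)
    meas_out$error_mm <- round(meas_out$error_mm, 2)
    write.csv(meas_out, file.path(out_dir, "measurements.csv"),
              row.names = FALSE)
    write_agreement_report(report, file.path(out_dir, "report"))
    jsonlite::write_json(measurements, file.path(out_dir, "measurements.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    writeLines(log_lines, file.path(out_dir, "log.txt"))
  }
  list(measurements = measurements, report = report,
       manifest = cohort$manifest, config = config, out_dir = out_dir)
}

#' Measure a tunnel in a CT volume from disk
#'
#' volume file -> segmentation -> cavity -> mesh -> measurements; the
#' agreement stage runs only when a drill-record CSV (columns `id`,
#' `true_diameter_mm`) is supplied in the config.
#'
#' @param config a [run_config()] with `volume` (path) and `seed_point_mm`
#'   set; optional `drill_record` CSV path.
#' @param id tunnel id (matched against the drill record).
#' @return list with `records`, `mesh`, and `difference` (when a drill
#'   record was supplied).
#' @export
run_measurement <- function(config, id = "tunnel") {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$volume)) {
    stop("config$volume (input volume path) is required", call. = FALSE)
  }
  if (is.null(config$seed_point_mm)) {
    stop("config$seed_point_mm (a point inside the tunnel) is required",
         call. = FALSE)
  }
  vol <- read_volume(config$volume)
  truth <- NULL
  drill <- NULL
  if (!is.null(config$drill_record)) {
    drill <- read.csv(config$drill_record, stringsAsFactors = FALSE)
    hit <- drill[drill$id == id, , drop = FALSE]
    if (nrow(hit) == 1L) {
      truth <- ground_truth(id, hit$true_diameter_mm,
                            axis_point = config$seed_point_mm,
                            axis_direction = c(0, 0, 1),
                            length_mm = 1)
      truth$length_mm <- NA_real_
    }
  }
  res <- measure_volume_tunnel(vol, config$seed_point_mm, config,
                               truth = truth, id = id)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    meas_out <- res$records
    meas_out$diameter_mm <- round(meas_out$diameter_mm, 2)
    write.csv(meas_out, file.path(out_dir, "measurements.csv"),
              row.names = FALSE)
    write_stl(res$mesh, file.path(out_dir, sprintf("%s.stl", id)))
  }
  if (!is.null(truth)) {
    ok <- !is.na(res$records$diameter_mm)
    res$difference <- data.frame(
      method = res$records$method[ok],
      diff_mm = res$records$diameter_mm[ok] - truth$true_diameter_mm,
      stringsAsFactors = FALSE)
  }
  res
}

# Small stable string hash (polynomial, mod 2^31) for config
# fingerprinting in logs.
digest_string <- function(s) {
  bytes <- as.integer(charToRaw(as.character(s)))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%012.0f", h * 1)
}
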