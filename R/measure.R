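#' Run all four diameter measurement methods on one tunnel
#'
#' Applies the three 3D-model methods to the mesh and the 2D CT method to
#' the mask, returning one measurement record per method. A method failure
#' is captured as a record with `NA` diameter and the error message in
#' `note`; it never aborts the remaining methods.
#'
#' @param mesh a [tunnel_mesh()] of the tunnel wall.
#' @param mask a [binary_mask()] of the same tunnel (for the 2D CT method);
#'   `NULL` skips that method.
#' @param truth optional [ground_truth()]; when given, each record carries
#'   the signed error `diameter_mm - true_diameter_mm`.
#' @param id tunnel identifier for the records.
#' @param station arc-length fraction for the transverse section (default
#'   0.5, mid-length; also used to place the 2D mid-point).
#' @param exclusion_radius_mm passed to [wall_thickness()].
#' @return `data.frame` with columns `id`, `method`, `diameter_mm`,
#'   `error_mm`, `note`, plus 2D per-plane diagnostics columns.
#' @export
measure_all <- function(mesh, mask = NULL, truth = NULL, id = "tunnel",
                        station = 0.5, exclusion_radius_mm = 1) {
  methods <- c("cylinder_fit", "transverse_section", "wall_thickness", "ct2d")
  rows <- vector("list", length(methods))
  names(rows) <- methods
  diag2d <- c(axial_mm = NA_real_, coronal_mm = NA_real_,
              sagittal_mm = NA_real_)

  centerline <- tryCatch(fit_centerline(mesh), error = function(e) e)

  run <- function(method, expr) {
    out <- tryCatch(list(value = expr, note = ""), error = function(e) {
      list(value = NA_real_, note = conditionMessage(e))
    })
    data.frame(id = id, method = method, diameter_mm = out$value,
               note = out$note, stringsAsFactors = FALSE)
  }

  rows$cylinder_fit <- run("cylinder_fit", fit_cylinder(mesh)$diameter_mm)
  rows$transverse_section <- run("transverse_section", {
    if (inherits(centerline, "error")) stop(conditionMessage(centerline))
    transverse_section_diameter(mesh, centerline, station)$diameter_mm
  })
  rows$wall_thickness <- run("wall_thickness",
                             wall_thickness(mesh, exclusion_radius_mm)$diameter_mm)
  ct2d_rec <- tryCatch({
    if (is.null(mask)) stop("no tunnel mask supplied")
    if (inherits(centerline, "error")) stop(conditionMessage(centerline))
    mid <- centerline_at(centerline, station)$point
    ct2d_diameter(mask, mid)
  }, error = function(e) e)
  if (inherits(ct2d_rec, "error")) {
    rows$ct2d <- data.frame(id = id, method = "ct2d", diameter_mm = NA_real_,
                            note = conditionMessage(ct2d_rec),
                            stringsAsFactors = FALSE)
  } else {
    diag2d <- c(axial_mm = ct2d_rec$axial_mm, coronal_mm = ct2d_rec$coronal_mm,
                sagittal_mm = ct2d_rec$sagittal_mm)
    rows$ct2d <- data.frame(id = id, method = "ct2d",
                            diameter_mm = ct2d_rec$diameter_mm, note = "",
                            stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$axial_mm <- ifelse(out$method == "ct2d", diag2d[["axial_mm"]], NA_real_)
  out$coronal_mm <- ifelse(out$method == "ct2d", diag2d[["coronal_mm"]], NA_real_)
  out$sagittal_mm <- ifelse(out$method == "ct2d", diag2d[["sagittal_mm"]], NA_real_)
  out$error_mm <- if (!is.null(truth)) {
    out$diameter_mm - truth$true_diameter_mm
  } else NA_real_
  out$true_diameter_mm <- if (!is.null(truth)) truth$true_diameter_mm else NA_real_
  out[, c("id", "method", "diameter_mm", "true_diameter_mm", "error_mm",
          "axial_mm", "coronal_mm", "sagittal_mm", "note")]
}
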