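#' Ray-cast wall thickness of a tunnel mesh
#'
#' The wall-thickness measurement: from the centroid of every triangle a ray
#' is cast along the triangle's into-lumen normal and the distance to the
#' first intersection with the opposite wall is recorded. Triangles whose
#' centroid lies within `exclusion_radius_mm` of the ray origin are not
#' eligible hits, so a ray cannot terminate on its own neighbourhood of the
#' wall. Rays that escape through an aperture are recorded as misses and
#' excluded from the summary.
#'
#' Because triangle orientations on a rough (segmented) surface vary, rays
#' deviate from the true diameter direction and traverse chords shorter than
#' the diameter, so the summary systematically underestimates the tunnel
#' diameter on noisy surfaces — the known failure mode of this method.
#'
#' @param mesh a [tunnel_mesh()] with normals oriented into the lumen.
#' @param exclusion_radius_mm self-intersection exclusion radius (mm),
#'   default 1; choose it larger than the typical triangle edge length.
#' @param area_weighted use an area-weighted mean for the summary diameter
#'   instead of the unweighted mean over triangles.
#' @return An object of class `wall_thickness_field`: `thickness_mm`
#'   (per-triangle, `NA` = miss), `miss_fraction`, `mean_mm`, `median_mm`,
#'   `percentiles` (5/25/75/95), `diameter_mm` (the summary mean).
#' @export
wall_thickness <- function(mesh, exclusion_radius_mm = 1,
                           area_weighted = FALSE) {
  stopifnot(inherits(mesh, "tunnel_mesh"))
  if (mesh$orientation != "into_lumen") {
    stop("wall_thickness requires normals oriented into the lumen",
         call. = FALSE)
  }
  cen <- face_centroids(mesh)
  nor <- face_normals(mesh)
  th <- .raycast_first_hit(cen, nor, mesh$vertices, mesh$faces, cen,
                           exclusion_radius_mm)
  hits <- !is.na(th)
  if (!any(hits)) stop("wall thickness: no ray hit the opposite wall",
                       call. = FALSE)
  miss_fraction <- mean(!hits)
  if (miss_fraction > 0.5) {
    warning(sprintf("wall thickness: %.0f%% of rays escaped (aperture-dominated mesh)",
                    100 * miss_fraction), call. = FALSE)
  }
  rec <- th[hits]
  mean_mm <- if (area_weighted) {
    w <- face_areas(mesh)[hits]
    sum(w * rec) / sum(w)
  } else {
    mean(rec)
  }
  structure(list(
    thickness_mm = th,
    miss_fraction = miss_fraction,
    mean_mm = mean_mm,
    median_mm = median(rec),
    percentiles = quantile(rec, c(0.05, 0.25, 0.75, 0.95), names = TRUE),
    diameter_mm = mean_mm
  ), class = "wall_thickness_field")
}

#' @export
print.wall_thickness_field <- function(x, ...) {
  cat(sprintf("<wall_thickness_field> mean %.4f mm, median %.4f mm, %.1f%% misses\n",
              x$mean_mm, x$median_mm, 100 * x$miss_fraction))
  invisible(x)
}
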