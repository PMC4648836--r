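#' Clinical 2D CT diameter at the tunnel mid-point
#'
#' Emulates the straight-line measurement on the original CT images: in each
#' canonical plane (axial z, coronal y, sagittal x) through the tunnel
#' mid-point, the in-slice connected component of the tunnel mask containing
#' the mid-point is extracted, its boundary is traced at the 0.5 level
#' (sub-pixel contour), and its width is taken as the minimum Feret width of
#' the contour. The method diameter is the mean of the three per-plane
#' widths, the averaging the clinical protocol uses.
#'
#' The minimum Feret width is used because an oblique cut through a cylinder
#' is an ellipse (or strip) whose *minor* width equals the true diameter;
#' that minor width is what a clinician's ruler across the tunnel
#' approximates. `width = "max_chord"` switches to the maximum caliper width
#' for sensitivity analysis.
#'
#' @param tunnel_mask a [binary_mask()] of the tunnel cavity.
#' @param midpoint_mm world point (mm) inside the tunnel, typically the
#'   centerline point at station 0.5.
#' @param smooth_sigma_voxels in-plane Gaussian smoothing of the slice before
#'   contouring (voxels); 0 contours the raw binary slice. The default of
#'   one voxel suppresses the staircase crests of oblique section edges,
#'   which the minimum-Feret width (a maximum over boundary points per
#'   direction) would otherwise ride on; it matches the iso-surfacing
#'   default of [mask_to_mesh()].
#' @param width `"min_feret"` (default) or `"max_chord"`.
#' @return a one-row `data.frame` measurement record with columns
#'   `method`, `diameter_mm`, `axial_mm`, `coronal_mm`, `sagittal_mm`.
#' @export
ct2d_diameter <- function(tunnel_mask, midpoint_mm,
                          smooth_sigma_voxels = 1,
                          width = c("min_feret", "max_chord")) {
  width <- match.arg(width)
  stopifnot(inherits(tunnel_mask, "binary_mask"))
  idx <- world_to_voxel(tunnel_mask, midpoint_mm)
  vox <- tunnel_mask$voxels
  if (!vox[idx[1], idx[2], idx[3]]) {
    stop("midpoint lies outside the tunnel mask", call. = FALSE)
  }
  sp <- tunnel_mask$spacing_mm
  or <- tunnel_mask$origin_mm

  plane_width <- function(slice, coords1, coords2, seed12, sig12) {
    comp <- flood_fill2(slice, seed12)
    if (!any(comp)) stop("empty in-slice tunnel component", call. = FALSE)
    d2 <- dim(comp)
    if (any(comp[c(1, d2[1]), ]) || any(comp[, c(1, d2[2])])) {
      warning("in-slice tunnel component touches the slice edge", call. = FALSE)
    }
    field <- matrix(as.numeric(comp), d2[1], d2[2])
    if (smooth_sigma_voxels > 0) {
      field <- gaussian_blur2(field, smooth_sigma_voxels * sig12)
    }
    cl <- contourLines(coords1, coords2, field, levels = 0.5)
    if (!length(cl)) stop("no 0.5-level contour in slice", call. = FALSE)
    seed_mm <- c(coords1[seed12[1]], coords2[seed12[2]])
    containing <- which(vapply(cl, function(cc) {
      point_in_polygon(seed_mm, cbind(cc$x, cc$y))
    }, logical(1)))
    pick <- if (length(containing)) containing[1] else {
      # fall back to the contour closest to the seed
      which.min(vapply(cl, function(cc) {
        min((cc$x - seed_mm[1])^2 + (cc$y - seed_mm[2])^2)
      }, numeric(1)))
    }
    pts <- cbind(cl[[pick]]$x, cl[[pick]]$y)
    if (width == "min_feret") min_feret_width(pts) else max_caliper_width(pts)
  }

  xs <- or[1] + (seq_len(dim(vox)[1]) - 1) * sp[1]
  ys <- or[2] + (seq_len(dim(vox)[2]) - 1) * sp[2]
  zs <- or[3] + (seq_len(dim(vox)[3]) - 1) * sp[3]

  axial <- plane_width(vox[, , idx[3]], xs, ys, idx[c(1, 2)],
                       c(1, 1))
  coronal <- plane_width(vox[, idx[2], ], xs, zs, idx[c(1, 3)],
                         c(1, 1))
  sagittal <- plane_width(vox[idx[1], , ], ys, zs, idx[c(2, 3)],
                          c(1, 1))
  data.frame(
    method = "ct2d",
    diameter_mm = mean(c(axial, coronal, sagittal)),
    axial_mm = axial, coronal_mm = coronal, sagittal_mm = sagittal,
    stringsAsFactors = FALSE
  )
}

# 8-connected 2D flood fill from a seed pixel.
flood_fill2 <- function(slice, seed12) {
  d <- dim(slice)
  candidate <- as.vector(slice)
  visited <- logical(length(candidate))
  start <- (seed12[2] - 1L) * d[1] + seed12[1]
  if (!candidate[start]) return(array(FALSE, d))
  visited[start] <- TRUE
  frontier <- start
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  off_lin <- offs[, 2] * d[1] + offs[, 1]
  ii <- ((seq_along(candidate) - 1L) %% d[1]) + 1L
  jj <- ((seq_along(candidate) - 1L) %/% d[1]) + 1L
  while (length(frontier)) {
    src <- rep(frontier, each = nrow(offs))
    nb <- src + rep(off_lin, times = length(frontier))
    di <- rep(offs[, 1], times = length(frontier))
    dj <- rep(offs[, 2], times = length(frontier))
    ok <- ii[src] + di >= 1L & ii[src] + di <= d[1] &
      jj[src] + dj >= 1L & jj[src] + dj <= d[2]
    nb <- nb[ok]
    nb <- unique(nb[candidate[nb] & !visited[nb]])
    visited[nb] <- TRUE
    frontier <- nb
  }
  matrix(visited & candidate, d[1], d[2])
}

# Separable 2D Gaussian blur (sigma per axis, voxel units).
gaussian_blur2 <- function(mat, sigma) {
  sigma <- rep_len(sigma, 2L)
  arr <- array(mat, c(dim(mat), 1L))
  arr <- gaussian_blur3(arr, c(sigma, 0))
  arr[, , 1]
}

#' Minimum Feret width of a 2D point set
#'
#' Width of the narrowest pair of parallel supporting lines. Computed on the
#' convex hull: the minimum width is attained with one line flush with a
#' hull edge.
#'
#' @param pts n x 2 matrix.
#' @return width (same units as `pts`).
#' @export
min_feret_width <- function(pts) {
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  n <- nrow(hull)
  if (n < 3L) return(0)
  widths <- vapply(seq_len(n), function(i) {
    a <- hull[i, ]
    b <- hull[if (i == n) 1L else i + 1L, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len < 1e-12) return(Inf)
    nrm <- c(-e[2], e[1]) / len
    d <- (hull[, 1] - a[1]) * nrm[1] + (hull[, 2] - a[2]) * nrm[2]
    max(abs(d))
  }, numeric(1))
  min(widths)
}

# Largest pairwise distance over the convex hull (rotating-calipers-free
# brute force; hulls here are small).
max_caliper_width <- function(pts) {
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  max(stats::dist(hull))
}
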