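#' Threshold segmentation of a CT volume
#'
#' Labels voxels whose density lies in `[low, high]`, the density-range
#' segmentation used clinically to highlight bone on CT. No morphology is
#' applied here.
#'
#' @param volume a [ct_volume()].
#' @param low,high density bounds (inclusive); `high` may be `Inf`.
#' @return a [binary_mask()]; a warning (not an error) if it is empty.
#' @export
threshold_segment <- function(volume, low, high = Inf) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!(low < high)) stop("threshold range requires low < high", call. = FALSE)
  m <- volume$voxels >= low & volume$voxels <= high
  if (!any(m)) warning("threshold range selected no voxels", call. = FALSE)
  binary_mask(m, volume$spacing_mm, volume$origin_mm)
}

# Distance (mm) from every voxel to the nearest TRUE voxel.
mask_distance_mm <- function(mask) {
  d2 <- .edt3d_sq(as.vector(mask$voxels), dim(mask$voxels), mask$spacing_mm)
  array(sqrt(d2), dim(mask$voxels))
}

# Morphological dilation/erosion/closing with a Euclidean ball of radius mm,
# computed through the exact anisotropic distance transform so the element is
# truly spherical in world units regardless of voxel anisotropy.
dilate_ball <- function(mask, radius_mm) {
  if (radius_mm <= 0) return(mask)
  binary_mask(mask_distance_mm(mask) <= radius_mm,
              mask$spacing_mm, mask$origin_mm)
}

erode_ball <- function(mask, radius_mm) {
  if (radius_mm <= 0) return(mask)
  inv <- binary_mask(!mask$voxels, mask$spacing_mm, mask$origin_mm)
  binary_mask(!(mask_distance_mm(inv) <= radius_mm),
              mask$spacing_mm, mask$origin_mm)
}

close_ball <- function(mask, radius_mm) {
  erode_ball(dilate_ball(mask, radius_mm), radius_mm)
}

#' Extract the tunnel cavity from a bone mask
#'
#' The tunnel appears as empty space inside the segmented bone. Closing the
#' bone mask with a ball larger than the tunnel radius fills the tunnel;
#' subtracting the bone mask leaves candidate cavity voxels; the connected
#' component (26-neighbourhood) containing the seed point is the tunnel
#' cavity.
#'
#' @param bone_mask a [binary_mask()] of bone.
#' @param closing_radius_mm ball radius (mm); must exceed the expected tunnel
#'   radius or the closing cannot bridge the lumen.
#' @param seed_point_mm world point (mm) inside the cavity.
#' @return a [binary_mask()] of the tunnel cavity.
#' @export
extract_tunnel_cavity <- function(bone_mask, closing_radius_mm, seed_point_mm) {
  stopifnot(inherits(bone_mask, "binary_mask"), closing_radius_mm > 0)
  # On a discrete grid, dilation reaches up to half a voxel diagonal beyond
  # the r-offset surface (voxel centres within r), so eroding by exactly r
  # leaves a spurious one-voxel film of "cavity" over the whole bone
  # surface, 26-connected to the tunnel apertures. Eroding by r plus half
  # the voxel diagonal suppresses it; the tunnel interior, far deeper than
  # the closing radius, is unaffected.
  overshoot <- 0.5 * sqrt(sum(bone_mask$spacing_mm^2))
  # pad with background so the dilation never reaches the array edge:
  # otherwise the erosion loses its reference background and the closing
  # degenerates to the whole grid
  pad <- ceiling((closing_radius_mm + overshoot) / bone_mask$spacing_mm) + 1L
  padded <- pad_mask(bone_mask, pad)
  dil <- dilate_ball(padded, closing_radius_mm)
  closed_p <- erode_ball(dil, closing_radius_mm + overshoot)
  closed <- crop_mask(closed_p, pad, dim(bone_mask$voxels))
  cavity <- closed$voxels & !bone_mask$voxels
  seed_idx <- world_to_voxel(bone_mask, seed_point_mm)
  if (!cavity[seed_idx[1], seed_idx[2], seed_idx[3]]) {
    stop("no cavity at the seed point: it lies outside any enclosed empty space",
         call. = FALSE)
  }
  comp <- flood_fill3(cavity, seed_idx)
  binary_mask(comp, bone_mask$spacing_mm, bone_mask$origin_mm)
}

# Pad a mask with FALSE voxels on every side (per-axis widths).
pad_mask <- function(mask, pad) {
  d <- dim(mask$voxels)
  nd <- d + 2L * pad
  vox <- array(FALSE, nd)
  vox[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), pad[3] + seq_len(d[3])] <-
    mask$voxels
  binary_mask(vox, mask$spacing_mm,
              mask$origin_mm - pad * mask$spacing_mm)
}

# Crop a padded mask back to the original grid.
crop_mask <- function(mask, pad, orig_dim) {
  vox <- mask$voxels[pad[1] + seq_len(orig_dim[1]),
                     pad[2] + seq_len(orig_dim[2]),
                     pad[3] + seq_len(orig_dim[3]), drop = FALSE]
  binary_mask(array(vox, orig_dim), mask$spacing_mm,
              mask$origin_mm + pad * mask$spacing_mm)
}

# 26-connected flood fill from a seed voxel; returns the component mask.
flood_fill3 <- function(vox, seed_idx) {
  d <- dim(vox)
  lin <- function(i, j, k) (k - 1L) * d[1] * d[2] + (j - 1L) * d[1] + i
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  off_lin <- offs[, 3] * d[1] * d[2] + offs[, 2] * d[1] + offs[, 1]

  visited <- logical(length(vox))
  candidate <- as.vector(vox)
  start <- lin(seed_idx[1], seed_idx[2], seed_idx[3])
  visited[start] <- TRUE
  frontier <- start
  # index arithmetic needs explicit bounds checks to avoid wrap-around
  ii <- ((seq_along(candidate) - 1L) %% d[1]) + 1L
  jj <- (((seq_along(candidate) - 1L) %/% d[1]) %% d[2]) + 1L
  kk <- ((seq_along(candidate) - 1L) %/% (d[1] * d[2])) + 1L
  while (length(frontier)) {
    nb <- rep(frontier, each = nrow(offs)) +
      rep(off_lin, times = length(frontier))
    src <- rep(frontier, each = nrow(offs))
    m <- nrow(offs)
    di <- rep(offs[, 1], times = length(frontier))
    dj <- rep(offs[, 2], times = length(frontier))
    dk <- rep(offs[, 3], times = length(frontier))
    ok <- ii[src] + di >= 1L & ii[src] + di <= d[1] &
      jj[src] + dj >= 1L & jj[src] + dj <= d[2] &
      kk[src] + dk >= 1L & kk[src] + dk <= d[3]
    nb <- nb[ok]
    nb <- unique(nb[candidate[nb] & !visited[nb]])
    visited[nb] <- TRUE
    frontier <- nb
  }
  array(visited & candidate, d)
}

#' Extract an iso-surface mesh from a binary mask
#'
#' Surfaces the mask at level 0.5, by default on a Gaussian-smoothed copy of
#' the 0/1 field so vertices land at sub-voxel positions instead of on the
#' voxel lattice; `smooth_sigma_voxels = 0` surfaces the raw mask. Vertices
#' are in world mm; normals are oriented into the lumen (toward mask == TRUE),
#' the convention the measurement methods expect for cavity meshes.
#'
#' @param mask a [binary_mask()] (non-empty).
#' @param iso_level iso value on the smoothed 0/1 field (default 0.5).
#' @param smooth_sigma_voxels Gaussian sigma in voxels (default 1; 0 = raw).
#' @return a [tunnel_mesh()]; `has_aperture` is set when the mask touches the
#'   array boundary (the surface is then open there).
#' @export
mask_to_mesh <- function(mask, iso_level = 0.5, smooth_sigma_voxels = 1) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$voxels)) stop("cannot mesh an empty mask", call. = FALSE)
  field <- array(as.numeric(mask$voxels), dim(mask$voxels))
  if (smooth_sigma_voxels > 0) {
    field <- gaussian_blur3(field, smooth_sigma_voxels)
  }
  d <- dim(field)
  touches <- any(mask$voxels[c(1, d[1]), , ]) || any(mask$voxels[, c(1, d[2]), ]) ||
    any(mask$voxels[, , c(1, d[3])])
  res <- .march_tet(as.vector(field), d, iso_level, mask$spacing_mm,
                    mask$origin_mm)
  if (nrow(res$faces) == 0L) {
    stop("iso-surface is empty at this level; try a lower smoothing sigma",
         call. = FALSE)
  }
  tunnel_mesh(res$vertices, res$faces, orientation = "into_lumen",
              has_aperture = touches)
}
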