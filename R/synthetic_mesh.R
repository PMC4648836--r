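## Analytic ground-truth meshes: cylinders, frustums, parallel plates.
## These are the oracles against which the measurement methods are tested:
## every vertex lies exactly on the stated surface before any perturbation.

#' Analytic cylinder tunnel mesh
#'
#' Triangulated cylinder of the given radius: every vertex lies at exactly
#' `radius_mm` from the axis. By default the tube is open at both ends
#' (apertures), matching a drilled tunnel; `capped = TRUE` adds end fans.
#' Face winding is chosen so normals point into the lumen (toward the axis),
#' the convention [wall_thickness()] requires.
#'
#' @param radius_mm cylinder radius (mm), > 0.
#' @param length_mm cylinder length (mm), > 0.
#' @param axis_direction axis direction (any length, normalised internally).
#' @param axis_point point on the axis at the cylinder centre (mm).
#' @param n_circumferential number of vertices per ring (>= 8).
#' @param n_axial number of rings (>= 2).
#' @param capped close the ends with triangle fans.
#' @return a [tunnel_mesh()] with `orientation = "into_lumen"`.
#' @export
make_cylinder_mesh <- function(radius_mm, length_mm,
                               axis_direction = c(0, 0, 1),
                               axis_point = c(0, 0, 0),
                               n_circumferential = 64L, n_axial = 24L,
                               capped = FALSE) {
  stopifnot(radius_mm > 0, length_mm > 0,
            n_circumferential >= 8L, n_axial >= 2L)
  d <- normalize3(axis_direction)
  rings <- tube_rings(function(t) radius_mm, length_mm, d, axis_point,
                      n_circumferential, n_axial)
  build_tube_mesh(rings, n_circumferential, n_axial, capped, d, axis_point,
                  length_mm)
}

#' Analytic frustum (linearly tapered tube) mesh
#'
#' Radius varies linearly with the axial fraction `t` in `[0, 1]`:
#' `r(t) = r_entry + t * (r_exit - r_entry)`. Used to test the mid-length
#' semantics of the transverse-section method (at `t = 0.5` the radius is the
#' arithmetic mean of the end radii).
#'
#' @param r_entry_mm radius at `t = 0` (mm), > 0.
#' @param r_exit_mm radius at `t = 1` (mm), > 0.
#' @inheritParams make_cylinder_mesh
#' @return a [tunnel_mesh()].
#' @export
make_frustum_mesh <- function(r_entry_mm, r_exit_mm, length_mm,
                              axis_direction = c(0, 0, 1),
                              axis_point = c(0, 0, 0),
                              n_circumferential = 64L, n_axial = 24L,
                              capped = FALSE) {
  stopifnot(r_entry_mm > 0, r_exit_mm > 0, length_mm > 0,
            n_circumferential >= 8L, n_axial >= 2L)
  d <- normalize3(axis_direction)
  rings <- tube_rings(function(t) r_entry_mm + t * (r_exit_mm - r_entry_mm),
                      length_mm, d, axis_point, n_circumferential, n_axial)
  build_tube_mesh(rings, n_circumferential, n_axial, capped, d, axis_point,
                  length_mm)
}

# Ring vertices for a tube of profile radius_fun(t), t in [0,1] along axis.
# axis_point is the t = 0.5 midpoint.
tube_rings <- function(radius_fun, length_mm, d, axis_point,
                       n_circ, n_axial) {
  b <- plane_basis(d)
  theta <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  ct <- cos(theta); st <- sin(theta)
  tfrac <- seq(0, 1, length.out = n_axial)
  verts <- matrix(0, n_circ * n_axial, 3)
  for (i in seq_len(n_axial)) {
    r <- radius_fun(tfrac[i])
    centre <- axis_point + (tfrac[i] - 0.5) * length_mm * d
    ring <- centre[1] + r * (ct * b$e1[1] + st * b$e2[1])
    ring <- cbind(ring,
                  centre[2] + r * (ct * b$e1[2] + st * b$e2[2]),
                  centre[3] + r * (ct * b$e1[3] + st * b$e2[3]))
    verts[(i - 1L) * n_circ + seq_len(n_circ), ] <- ring
  }
  verts
}

# Quad strip triangulation between consecutive rings, normals into lumen.
build_tube_mesh <- function(verts, n_circ, n_axial, capped, d, axis_point,
                            length_mm) {
  faces <- vector("list", n_axial - 1L)
  idx <- function(ring, j) (ring - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L
  j <- seq_len(n_circ)
  for (i in seq_len(n_axial - 1L)) {
    a <- idx(i, j); b_ <- idx(i, j + 1L)
    c_ <- idx(i + 1L, j); dd <- idx(i + 1L, j + 1L)
    # winding (a, c, b) / (b, c, d): right-hand normals point toward the axis
    faces[[i]] <- rbind(cbind(a, c_, b_), cbind(b_, c_, dd))
  }
  faces <- do.call(rbind, faces)
  nv <- n_circ * n_axial
  if (capped) {
    c0 <- axis_point - 0.5 * length_mm * d
    c1 <- axis_point + 0.5 * length_mm * d
    verts <- rbind(verts, c0, c1)
    lo <- idx(1L, j); lo2 <- idx(1L, j + 1L)
    hi <- idx(n_axial, j); hi2 <- idx(n_axial, j + 1L)
    # cap normals also face the interior
    faces <- rbind(faces,
                   cbind(lo, lo2, rep(nv + 1L, n_circ)),
                   cbind(hi2, hi, rep(nv + 2L, n_circ)))
  }
  m <- tunnel_mesh(verts, faces, orientation = "into_lumen",
                   has_aperture = !capped)
  # verify the winding convention: mean normal . (axis - centroid) > 0
  ensure_into_lumen(m, axis_point)
}

# Flip winding if face normals do not, on average, point toward the
# given interior point.
ensure_into_lumen <- function(mesh, interior_point) {
  n <- face_normals(mesh)
  cen <- face_centroids(mesh)
  to_axis <- sweep(-cen, 2, interior_point, "+")
  if (mean(rowSums(n * to_axis)) < 0) {
    mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  }
  mesh
}

#' Two parallel plates facing each other across a gap
#'
#' Degenerate "tunnel" used to test the wall-thickness method: every ray from
#' one plate along its normal crosses exactly the gap to the other plate.
#'
#' @param gap_mm distance between the plates (mm).
#' @param size_mm side length of the square plates (mm).
#' @param n number of vertices per plate edge.
#' @return a [tunnel_mesh()] with normals facing the opposite plate.
#' @export
make_plates_mesh <- function(gap_mm, size_mm = 20, n = 12L) {
  stopifnot(gap_mm > 0, size_mm > 0, n >= 2L)
  g <- seq(-size_mm / 2, size_mm / 2, length.out = n)
  grid <- as.matrix(expand.grid(x = g, y = g))
  lower <- cbind(grid, -gap_mm / 2)
  upper <- cbind(grid, +gap_mm / 2)
  verts <- rbind(lower, upper)
  faces <- vector("list", 2L * (n - 1L)^2)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (jj in seq_len(n - 1L)) {
      a <- (jj - 1L) * n + i
      b <- a + 1L
      c_ <- a + n
      d_ <- c_ + 1L
      k <- k + 1L
      # lower plate: normals +z (toward upper plate)
      faces[[k]] <- rbind(c(a, b, d_), c(a, d_, c_))
      k <- k + 1L
      off <- n * n
      # upper plate: normals -z
      faces[[k]] <- rbind(c(a, d_, b) + off, c(a, c_, d_) + off)
    }
  }
  tunnel_mesh(verts, do.call(rbind, faces), orientation = "into_lumen",
              has_aperture = TRUE)
}

#' Perturb mesh vertices along their normals
#'
#' Displaces each vertex along its (angle/area-weighted) vertex normal by an
#' independent zero-mean Gaussian draw, emulating the surface roughness of a
#' real segmented tunnel model whose triangle orientations vary. Topology is
#' unchanged; the result is reproducible for a fixed seed.
#'
#' @param mesh a [tunnel_mesh()].
#' @param vertex_noise_sd_mm standard deviation of the displacement (mm), >= 0.
#' @param seed integer seed; randomness is local to this call.
#' @return perturbed `tunnel_mesh`.
#' @export
perturb_mesh <- function(mesh, vertex_noise_sd_mm, seed = 1L) {
  stopifnot(vertex_noise_sd_mm >= 0)
  if (vertex_noise_sd_mm == 0) return(mesh)
  vn <- vertex_normals(mesh)
  disp <- with_local_seed(seed, rnorm(nrow(mesh$vertices),
                                      sd = vertex_noise_sd_mm))
  tunnel_mesh(mesh$vertices + vn * disp, mesh$faces,
              orientation = mesh$orientation,
              has_aperture = mesh$has_aperture)
}
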