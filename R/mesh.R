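#' Triangle mesh of a tunnel wall
#'
#' Constructs a `tunnel_mesh`: a triangulated surface of the tunnel cavity
#' wall in world millimetre coordinates. Faces are triples of 1-based vertex
#' indices with consistent winding; the stored orientation records whether
#' face normals point into the lumen (the convention required by
#' [wall_thickness()]) or out of it.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param orientation `"into_lumen"` or `"out_of_lumen"`.
#' @param has_aperture logical; `TRUE` when the surface has open boundary
#'   loops (tunnel apertures at the bone surface).
#' @return An object of class `tunnel_mesh`.
#' @export
tunnel_mesh <- function(vertices, faces,
                        orientation = c("into_lumen", "out_of_lumen"),
                        has_aperture = FALSE) {
  orientation <- match.arg(orientation)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix", call. = FALSE)
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix", call. = FALSE)
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  structure(
    list(vertices = vertices, faces = faces, orientation = orientation,
         has_aperture = isTRUE(has_aperture)),
    class = "tunnel_mesh"
  )
}

#' @export
print.tunnel_mesh <- function(x, ...) {
  cat(sprintf("<tunnel_mesh> %d vertices, %d faces, normals %s%s\n",
              nrow(x$vertices), nrow(x$faces), x$orientation,
              if (x$has_aperture) ", open apertures" else ""))
  invisible(x)
}

#' Per-face centroids of a mesh
#' @param mesh a [tunnel_mesh()].
#' @return numeric m x 3 matrix of triangle centroids (mm).
#' @export
face_centroids <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' Per-face unit normals of a mesh
#'
#' Normals follow the winding order of the faces (right-hand rule), which by
#' package convention agrees with the mesh's stored `orientation`.
#'
#' @param mesh a [tunnel_mesh()].
#' @return numeric m x 3 matrix of unit normals.
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2))
  len[len < 1e-300] <- 1
  n / len
}

#' Per-face areas (mm^2)
#' @param mesh a [tunnel_mesh()].
#' @return numeric vector of triangle areas.
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  0.5 * sqrt(rowSums(n^2))
}

#' Angle-weighted per-vertex unit normals
#'
#' Used by [perturb_mesh()] to displace vertices along the surface normal.
#'
#' @param mesh a [tunnel_mesh()].
#' @return numeric n x 3 matrix of unit vertex normals.
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  ar <- face_areas(mesh)
  n <- matrix(0, nrow(mesh$vertices), 3)
  f <- mesh$faces
  for (k in 1:3) {
    idx <- f[, k]
    n[, 1] <- n[, 1] + tabulate_weighted(idx, fn[, 1] * ar, nrow(n))
    n[, 2] <- n[, 2] + tabulate_weighted(idx, fn[, 2] * ar, nrow(n))
    n[, 3] <- n[, 3] + tabulate_weighted(idx, fn[, 3] * ar, nrow(n))
  }
  len <- sqrt(rowSums(n^2))
  len[len < 1e-300] <- 1
  n / len
}

tabulate_weighted <- function(idx, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, group = idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Apply a rigid (or similarity) transform to a mesh
#'
#' @param mesh a [tunnel_mesh()].
#' @param rotation 3 x 3 matrix (applied first).
#' @param translation length-3 vector (applied second), mm.
#' @param scale scalar multiplier (applied with the rotation).
#' @return transformed `tunnel_mesh`.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                           scale = 1) {
  v <- scale * (mesh$vertices %*% t(rotation))
  v <- sweep(v, 2, translation, "+")
  flip <- det(rotation) < 0
  faces <- mesh$faces
  if (flip) faces <- faces[, c(1, 3, 2), drop = FALSE]
  tunnel_mesh(v, faces, orientation = mesh$orientation,
              has_aperture = mesh$has_aperture)
}

#' Remove faces near the axial ends of a tube-like mesh
#'
#' Drops the faces whose centroids fall in the outer `fraction` of the mesh's
#' extent along its dominant principal axis, then prunes unreferenced
#' vertices. Used to strip the closed/rounded end caps that cavity extraction
#' produces before fitting cylinders or casting rays, leaving an open tube
#' like the real tunnel wall between its apertures.
#'
#' @param mesh a [tunnel_mesh()].
#' @param fraction fraction (0-0.45) of the axial extent removed at each end.
#' @return trimmed `tunnel_mesh` with `has_aperture = TRUE`.
#' @export
trim_tunnel_ends <- function(mesh, fraction = 0.15) {
  stopifnot(fraction >= 0, fraction < 0.45)
  if (fraction == 0) return(mesh)
  pc <- prcomp(mesh$vertices, center = TRUE, scale. = FALSE)
  axis_dir <- pc$rotation[, 1]
  t_face <- face_centroids(mesh) %*% axis_dir
  rng <- range(mesh$vertices %*% axis_dir)
  lo <- rng[1] + fraction * diff(rng)
  hi <- rng[2] - fraction * diff(rng)
  keep <- t_face >= lo & t_face <= hi
  if (!any(keep)) stop("trimming removed every face", call. = FALSE)
  drop_unreferenced(tunnel_mesh(mesh$vertices,
                                mesh$faces[keep, , drop = FALSE],
                                orientation = mesh$orientation,
                                has_aperture = TRUE))
}

# Prune vertices not referenced by any face, remapping indices.
drop_unreferenced <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  map <- integer(nrow(mesh$vertices))
  map[used] <- seq_along(used)
  tunnel_mesh(mesh$vertices[used, , drop = FALSE],
              matrix(map[mesh$faces], ncol = 3L),
              orientation = mesh$orientation,
              has_aperture = mesh$has_aperture)
}

# Merge vertices closer than `tol` (exact duplicates after rounding).
merge_duplicate_vertices <- function(mesh, tol = 1e-9) {
  key <- paste(round(mesh$vertices[, 1] / tol), round(mesh$vertices[, 2] / tol),
               round(mesh$vertices[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])   # compacted index for every original vertex
  faces <- matrix(map[mesh$faces], ncol = 3L)
  degenerate <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  tunnel_mesh(mesh$vertices[first, , drop = FALSE],
              faces[!degenerate, , drop = FALSE],
              orientation = mesh$orientation,
              has_aperture = mesh$has_aperture)
}
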