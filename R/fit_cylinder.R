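#' Orthogonal-distance best-fit cylinder
#'
#' The best-fit-cylinder measurement: an analytic cylinder fitted to the
#' entire tunnel wall by minimising the sum of squared orthogonal distances
#' of the mesh vertices to the cylinder surface. The residual of a point `p`
#' for a cylinder (point `c`, unit direction `d`, radius `r`) is
#' `||(p - c) - ((p - c).d) d|| - r`.
#'
#' The axis direction is initialised from the first principal axis of the
#' vertices and optimised over a two-parameter tangent perturbation; for any
#' candidate direction the optimal centre and radius are recovered by the
#' inner [fit_circle()] on the projected points, so the search is a smooth
#' 2-parameter problem. Refinement stops at a gradient/relative tolerance of
#' 1e-10 (up to 200 outer iterations).
#'
#' @param mesh a [tunnel_mesh()] (or a plain n x 3 matrix of points) with at
#'   least 50 vertices spanning a dominant axis.
#' @param min_aspect minimum ratio of first to second principal extent; below
#'   this the cloud is near-spherical and the axis is not identifiable.
#' @return An object of class `tunnel_cylinder`: `axis_point`,
#'   `axis_direction`, `radius_mm`, `diameter_mm`, `extent_mm`
#'   (axial range of the data about `axis_point`), `rss`, `converged`.
#' @export
fit_cylinder <- function(mesh, min_aspect = 1.2) {
  pts <- if (inherits(mesh, "tunnel_mesh")) mesh$vertices else as.matrix(mesh)
  if (nrow(pts) < 50L) {
    stop("cylinder fit needs at least 50 vertices", call. = FALSE)
  }
  pc <- prcomp(pts, center = TRUE, scale. = FALSE)
  if (pc$sdev[1] < min_aspect * pc$sdev[2]) {
    stop("invalid geometry: point cloud has no dominant axis ",
         sprintf("(principal extent ratio %.2f < %.2f)",
                 pc$sdev[1] / pc$sdev[2], min_aspect), call. = FALSE)
  }
  d0 <- pc$rotation[, 1]
  centroid <- colMeans(pts)
  b <- plane_basis(d0)

  obj <- function(ab) {
    d <- normalize3(d0 + ab[1] * b$e1 + ab[2] * b$e2)
    bb <- plane_basis(d)
    u <- pts %*% bb$e1
    v <- pts %*% bb$e2
    fit_circle(cbind(u, v))$rss
  }
  opt <- optim(c(0, 0), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 200L))
  d <- normalize3(d0 + opt$par[1] * b$e1 + opt$par[2] * b$e2)
  bb <- plane_basis(d)
  u <- pts %*% bb$e1
  v <- pts %*% bb$e2
  circ <- fit_circle(cbind(u, v))
  if (!circ$converged && opt$convergence != 0) {
    stop("cylinder fit did not converge", call. = FALSE)
  }
  axis_point <- circ$centre[1] * bb$e1 + circ$centre[2] * bb$e2 +
    sum(centroid * d) * d
  t_axial <- as.vector(pts %*% d) - sum(axis_point * d)
  structure(list(
    axis_point = as.numeric(axis_point),
    axis_direction = as.numeric(d),
    radius_mm = circ$radius,
    diameter_mm = 2 * circ$radius,
    extent_mm = range(t_axial),
    rss = circ$rss,
    converged = circ$converged && opt$convergence == 0
  ), class = "tunnel_cylinder")
}

#' @export
print.tunnel_cylinder <- function(x, ...) {
  cat(sprintf("<tunnel_cylinder> diameter %.4f mm, axis (%.3f, %.3f, %.3f), length %.1f mm\n",
              x$diameter_mm, x$axis_direction[1], x$axis_direction[2],
              x$axis_direction[3], diff(x$extent_mm)))
  invisible(x)
}
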