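#' Centerline of a tunnel mesh
#'
#' Extracts an ordered polyline through the tunnel lumen by binning the mesh
#' vertices into `n_slabs` equal-width slabs along the initial principal axis
#' and taking each slab's centroid; slabs with fewer than `min_vertices`
#' vertices are dropped. Points are ordered by axial coordinate and carry a
#' cumulative arc-length parameterisation.
#'
#' Because the slabs are taken along the principal axis of the vertices, a
#' uniformly oblique tunnel poses no problem (the principal axis *is* the
#' tunnel axis). Straight slabs do cut the tube obliquely where it ends or
#' bends, so the outermost centroids and centroids at a bend carry a small
#' sideways bias (order r times the bend angle); the measurement pipeline
#' works at interior stations of trimmed, nearly straight tunnels, where
#' the recipe is unbiased.
#'
#' @param mesh a [tunnel_mesh()].
#' @param n_slabs number of slabs (>= 5, default 20).
#' @param min_vertices minimum vertices for a slab to contribute a point.
#' @return An object of class `tunnel_centerline`: `points` (k x 3 mm),
#'   `arc_length` (cumulative, starting at 0).
#' @export
fit_centerline <- function(mesh, n_slabs = 20L, min_vertices = 10L) {
  stopifnot(n_slabs >= 5L)
  pts <- mesh$vertices
  pc <- prcomp(pts, center = TRUE, scale. = FALSE)
  axis_dir <- pc$rotation[, 1]
  t_ax <- as.vector(pts %*% axis_dir)
  rng <- range(t_ax)
  breaks <- seq(rng[1], rng[2], length.out = n_slabs + 1L)
  bin <- findInterval(t_ax, breaks, rightmost.closed = TRUE)
  centres <- vector("list", n_slabs)
  for (s in seq_len(n_slabs)) {
    in_s <- bin == s
    if (sum(in_s) >= min_vertices) {
      centres[[s]] <- colMeans(pts[in_s, , drop = FALSE])
    }
  }
  centres <- do.call(rbind, centres)
  if (is.null(centres) || nrow(centres) < 2L) {
    stop("invalid geometry: fewer than 2 valid centerline slabs", call. = FALSE)
  }
  ord <- order(centres %*% axis_dir)
  centres <- centres[ord, , drop = FALSE]
  seg <- sqrt(rowSums(diff(centres)^2))
  if (any(seg <= 0)) {
    keep <- c(TRUE, seg > 0)
    centres <- centres[keep, , drop = FALSE]
    seg <- sqrt(rowSums(diff(centres)^2))
  }
  structure(list(points = centres, arc_length = c(0, cumsum(seg))),
            class = "tunnel_centerline")
}

#' @export
print.tunnel_centerline <- function(x, ...) {
  cat(sprintf("<tunnel_centerline> %d points, length %.2f mm\n",
              nrow(x$points), max(x$arc_length)))
  invisible(x)
}

# Point and unit tangent at an arc-length fraction of a centerline.
centerline_at <- function(centerline, station) {
  stopifnot(station > 0, station < 1)
  s <- station * max(centerline$arc_length)
  al <- centerline$arc_length
  i <- max(which(al <= s))
  i <- min(i, nrow(centerline$points) - 1L)
  f <- (s - al[i]) / (al[i + 1] - al[i])
  p <- centerline$points[i, ] + f * (centerline$points[i + 1, ] -
                                       centerline$points[i, ])
  # central-difference tangent where possible
  lo <- max(1L, i - 1L)
  hi <- min(nrow(centerline$points), i + 2L)
  tangent <- normalize3(centerline$points[hi, ] - centerline$points[lo, ])
  list(point = as.numeric(p), tangent = tangent)
}
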