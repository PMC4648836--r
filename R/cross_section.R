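#' Transverse-section diameter of a tunnel
#'
#' The transverse-section measurement: a plane is placed through the
#' centerline point at the requested arc-length fraction (default 0.5,
#' "mid-length"), perpendicular to the local centerline tangent; the
#' mesh-plane intersection is chained into boundary loops; the loop
#' containing the centerline point is retained (innermost if nested, with a
#' warning); and a circle is fitted to its points by [fit_circle()]
#' (Kasa initialisation + geometric refinement). Diameter = 2 x fitted
#' radius.
#'
#' @param mesh a [tunnel_mesh()].
#' @param centerline a [tunnel_centerline()]; computed from the mesh if
#'   missing.
#' @param station arc-length fraction in (0, 1); default 0.5.
#' @return An object of class `tunnel_cross_section`: `plane_point`,
#'   `plane_normal`, `boundary_mm` (k x 3 points on the loop), `centre_mm`,
#'   `radius_mm`, `diameter_mm`, `fit` (the circle-fit detail).
#' @export
transverse_section_diameter <- function(mesh, centerline = NULL,
                                        station = 0.5) {
  if (is.null(centerline)) centerline <- fit_centerline(mesh)
  if (!(station > 0 && station < 1)) {
    stop("station must lie strictly inside (0, 1)", call. = FALSE)
  }
  at <- centerline_at(centerline, station)
  sec <- mesh_plane_section(mesh, at$point, at$tangent)
  if (!length(sec$loops)) {
    if (length(sec$open_chains)) {
      stop("open mesh-plane intersection (the plane passes through an aperture); ",
           "try a different station", call. = FALSE)
    }
    stop("the section plane does not intersect the mesh", call. = FALSE)
  }
  b <- plane_basis(at$tangent)
  origin2 <- c(sum(at$point * b$e1), sum(at$point * b$e2))
  loop_2d <- lapply(sec$loops, function(L) {
    cbind(L %*% b$e1, L %*% b$e2)
  })
  containing <- which(vapply(loop_2d, function(P) {
    point_in_polygon(origin2, P)
  }, logical(1)))
  if (!length(containing)) {
    stop("no intersection loop encloses the centerline point; ",
         "try a different station", call. = FALSE)
  }
  if (length(containing) > 1L) {
    warning("nested section loops: keeping the innermost", call. = FALSE)
    areas <- vapply(containing, function(i) polygon_area(loop_2d[[i]]),
                    numeric(1))
    containing <- containing[which.min(areas)]
  }
  loop <- sec$loops[[containing]]
  fit <- fit_circle(loop_2d[[containing]])
  centre3 <- fit$centre[1] * b$e1 + fit$centre[2] * b$e2 +
    sum(at$point * at$tangent) * at$tangent
  structure(list(
    plane_point = at$point,
    plane_normal = at$tangent,
    boundary_mm = loop,
    centre_mm = as.numeric(centre3),
    radius_mm = fit$radius,
    diameter_mm = 2 * fit$radius,
    fit = fit
  ), class = "tunnel_cross_section")
}

#' @export
print.tunnel_cross_section <- function(x, ...) {
  cat(sprintf("<tunnel_cross_section> diameter %.4f mm (%d boundary points)\n",
              x$diameter_mm, nrow(x$boundary_mm)))
  invisible(x)
}

# Intersect a triangle mesh with a plane (point p, unit normal n).
# Returns closed loops (list of k x 3 matrices of ordered points) and any
# open chains (plane crossing an aperture).
mesh_plane_section <- function(mesh, p, n) {
  v <- mesh$vertices
  s <- as.vector(v %*% n) - sum(p * n)
  s[s == 0] <- 1e-12            # nudge on-plane vertices off the plane
  f <- mesh$faces
  s1 <- s[f[, 1]]; s2 <- s[f[, 2]]; s3 <- s[f[, 3]]
  crossed <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(crossed)) return(list(loops = list(), open_chains = list()))
  fc <- f[crossed, , drop = FALSE]

  edge_key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
  seg_edges <- vector("list", nrow(fc))
  for (i in seq_len(nrow(fc))) {
    tri <- fc[i, ]
    sv <- s[tri]
    cross_e <- which(c(sv[1] * sv[2] < 0, sv[2] * sv[3] < 0, sv[3] * sv[1] < 0))
    pairs <- rbind(tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)])[cross_e, ,
                                                             drop = FALSE]
    seg_edges[[i]] <- pairs
  }
  nseg <- vapply(seg_edges, nrow, integer(1))
  keep <- nseg == 2L     # a triangle crossing the plane yields 2 cut edges
  seg_edges <- seg_edges[keep]
  if (!length(seg_edges)) return(list(loops = list(), open_chains = list()))

  e1k <- vapply(seg_edges, function(e) edge_key(e[1, 1], e[1, 2]), character(1))
  e2k <- vapply(seg_edges, function(e) edge_key(e[2, 1], e[2, 2]), character(1))
  all_keys <- unique(c(e1k, e2k))
  # intersection point per cut edge
  key_pairs <- do.call(rbind, lapply(seg_edges, function(e) e))
  key_of_pairs <- edge_key(key_pairs[, 1], key_pairs[, 2])
  first_idx <- match(all_keys, key_of_pairs)
  ea <- key_pairs[first_idx, 1]; eb <- key_pairs[first_idx, 2]
  t <- s[ea] / (s[ea] - s[eb])
  pts <- v[ea, , drop = FALSE] + t * (v[eb, , drop = FALSE] -
                                        v[ea, , drop = FALSE])
  rownames(pts) <- all_keys

  # adjacency: each face connects its two cut edges
  adj <- new.env(parent = emptyenv())
  add_link <- function(a, b) {
    assign(a, c(get0(a, envir = adj, ifnotfound = character(0)), b),
           envir = adj)
  }
  for (i in seq_along(e1k)) {
    add_link(e1k[i], e2k[i])
    add_link(e2k[i], e1k[i])
  }

  visited <- new.env(parent = emptyenv())
  nbrs_of <- function(k) get0(k, envir = adj, ifnotfound = character(0))
  # walk from `start` toward `nxt`, marking nodes visited; returns the chain
  # (excluding start) and whether it closed back onto start
  walk <- function(start, nxt) {
    chain <- character(0)
    prev <- start
    cur <- nxt
    while (!is.null(cur) && is.null(get0(cur, envir = visited))) {
      chain <- c(chain, cur)
      assign(cur, TRUE, envir = visited)
      cand <- setdiff(nbrs_of(cur), prev)
      if (!length(cand)) return(list(chain = chain, closed = FALSE))
      if (cand[1] == start) return(list(chain = chain, closed = TRUE))
      prev <- cur
      cur <- cand[1]
    }
    list(chain = chain, closed = FALSE)
  }
  loops <- list()
  open_chains <- list()
  for (start in all_keys) {
    if (!is.null(get0(start, envir = visited))) next
    assign(start, TRUE, envir = visited)
    nb <- nbrs_of(start)
    if (!length(nb)) next
    fwd <- walk(start, nb[1])
    if (fwd$closed) {
      loops <- c(loops, list(pts[c(start, fwd$chain), , drop = FALSE]))
    } else {
      back <- if (length(nb) > 1L) walk(start, nb[2])
              else list(chain = character(0))
      chain <- c(rev(back$chain), start, fwd$chain)
      if (length(chain) > 1L) {
        open_chains <- c(open_chains, list(pts[chain, , drop = FALSE]))
      }
    }
  }
  list(loops = loops, open_chains = open_chains)
}

# Even-odd point-in-polygon test.
point_in_polygon <- function(pt, poly) {
  x <- pt[1]; y <- pt[2]
  px <- poly[, 1]; py <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  crosses <- ((py > y) != (py[j] > y)) &
    (x < (px[j] - px) * (y - py) / (py[j] - py) + px)
  sum(crosses) %% 2L == 1L
}

# Shoelace area (absolute).
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}
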