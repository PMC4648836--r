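#' Circle fit: algebraic initialisation + geometric refinement
#'
#' Fits a circle to 2D points by the Kasa algebraic fit (a linear least
#' squares problem) followed by Gauss-Newton refinement of the geometric
#' objective `sum_i (||p_i - centre|| - r)^2` to a gradient tolerance of
#' 1e-10 (at most 100 iterations).
#'
#' @param xy numeric n x 2 matrix of points (n >= 3).
#' @return list with `centre` (length 2), `radius`, `rss`, `iterations`,
#'   `converged`.
#' @export
fit_circle <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3L) stop("circle fit needs at least 3 points", call. = FALSE)
  x <- xy[, 1]; y <- xy[, 2]
  # Kasa: x^2 + y^2 = 2 a x + 2 b y + c
  A <- cbind(2 * x, 2 * y, 1)
  rhs <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, rhs), error = function(e) NULL)
  if (is.null(sol)) stop("degenerate point set: circle fit is singular",
                         call. = FALSE)
  centre <- sol[1:2]
  r <- sqrt(max(sol[3] + sum(centre^2), .Machine$double.eps))

  # geometric refinement: parameters (a, b, r)
  par <- c(centre, r)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    dx <- x - par[1]; dy <- y - par[2]
    di <- sqrt(dx^2 + dy^2)
    di[di < 1e-12] <- 1e-12
    res <- di - par[3]
    J <- cbind(-dx / di, -dy / di, -1)
    g <- crossprod(J, res)
    if (max(abs(g)) < 1e-10 || iter > 100L) {
      converged <- max(abs(g)) < 1e-10
      break
    }
    step <- tryCatch(solve(crossprod(J), g), error = function(e) NULL)
    if (is.null(step)) break
    par <- par - as.vector(step)
  }
  dx <- x - par[1]; dy <- y - par[2]
  res <- sqrt(dx^2 + dy^2) - par[3]
  list(centre = par[1:2], radius = par[3], rss = sum(res^2),
       iterations = iter, converged = converged)
}
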