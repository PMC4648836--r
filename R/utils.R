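## Internal helpers shared across modules.

# Run code with a locally seeded RNG, restoring global state afterwards.
# All package randomness goes through this so no call touches global state.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate direction vector (zero length)", call. = FALSE)
  v / n
}

assert_unit3 <- function(v, name = "axis", tol = 1e-9) {
  if (length(v) != 3L || !is.numeric(v)) {
    stop(sprintf("%s must be a numeric 3-vector", name), call. = FALSE)
  }
  if (abs(sqrt(sum(v^2)) - 1) > tol) {
    stop(sprintf("%s must be a unit vector (|v| = 1 within %g)", name, tol),
         call. = FALSE)
  }
  invisible(v)
}

# Orthonormal basis (e1, e2) spanning the plane perpendicular to unit d.
plane_basis <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- normalize3(pracma_cross(ref, d))
  e2 <- pracma_cross(d, e1)
  list(e1 = e1, e2 = e2)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation matrix mapping unit vector `from` onto unit vector `to`.
rotation_between <- function(from, to) {
  from <- normalize3(from); to <- normalize3(to)
  v <- pracma_cross(from, to)
  c_ <- sum(from * to)
  if (c_ < -1 + 1e-12) {
    # antiparallel: rotate pi about any axis perpendicular to `from`
    b <- plane_basis(from)
    a <- b$e1
    return(2 * outer(a, a) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# Uniform random rotation matrix (QR of Gaussian matrix, sign-fixed).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

`%||%` <- function(a, b) if (is.null(a)) b else a
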