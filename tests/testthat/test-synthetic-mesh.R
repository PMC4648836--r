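test_that("cylinder mesh vertices lie exactly on the stated surface", {
  m <- make_cylinder_mesh(4.0, 30, axis_direction = c(0, 0, 1),
                          n_circumferential = 64, n_axial = 12)
  r <- radial_distances(m$vertices, c(0, 0, 1))
  expect_lt(max(abs(r - 4.0)), 1e-9)

  # arbitrary orientation: radial distances about the rotated axis unchanged
  R <- fixed_rotation(5)
  ax <- as.vector(R %*% c(0, 0, 1))
  m2 <- make_cylinder_mesh(4.0, 30, axis_direction = ax,
                           axis_point = c(3, -2, 1),
                           n_circumferential = 64, n_axial = 12)
  r2 <- radial_distances(m2$vertices, ax, c(3, -2, 1))
  expect_lt(max(abs(r2 - 4.0)), 1e-9)

  # rigid transform of a mesh preserves radial distances about the moved axis
  m3 <- transform_mesh(m, rotation = R, translation = c(1, 2, 3))
  r3 <- radial_distances(m3$vertices, as.vector(R %*% c(0, 0, 1)), c(1, 2, 3))
  expect_lt(max(abs(r3 - 4.0)), 1e-9)
})

test_that("cross-section ring area matches the shoelace oracle", {
  n <- 64
  m <- make_cylinder_mesh(2.5, 10, n_circumferential = n, n_axial = 2)
  ring <- m$vertices[seq_len(n), 1:2]
  # shoelace area of the inscribed polygon
  jx <- c(2:n, 1)
  area <- abs(sum(ring[, 1] * ring[jx, 2] - ring[jx, 1] * ring[, 2])) / 2
  expect_lt(abs(area - pi * 2.5^2) / (pi * 2.5^2), 0.005)
})

test_that("degenerate axis is rejected", {
  expect_error(make_cylinder_mesh(4, 30, axis_direction = c(0, 0, 0)),
               "degenerate")
})

test_that("frustum radius follows the linear taper", {
  n_circ <- 48; n_axial <- 21
  m <- make_frustum_mesh(2.5, 3.5, 30, n_circumferential = n_circ,
                         n_axial = n_axial)
  ring_radius <- function(i) {
    ring <- m$vertices[(i - 1) * n_circ + seq_len(n_circ), ]
    mean(radial_distances(ring, c(0, 0, 1)))
  }
  # t = 0.5 is the middle ring (n_axial odd)
  expect_lt(abs(ring_radius(11) - 3.0), 1e-9)
  # t = 0.25
  expect_lt(abs(ring_radius(6) - 2.75), 1e-9)

  m2 <- make_frustum_mesh(2.0, 4.0, 30, n_circumferential = n_circ,
                          n_axial = 5)
  ring2 <- m2$vertices[n_circ + seq_len(n_circ), ]   # t = 0.25
  expect_lt(max(abs(radial_distances(ring2, c(0, 0, 1)) - 2.5)), 1e-9)

  # degenerate frustum = cylinder
  fc <- make_frustum_mesh(3, 3, 20, n_circumferential = 32, n_axial = 7)
  cc <- make_cylinder_mesh(3, 20, n_circumferential = 32, n_axial = 7)
  expect_equal(radial_distances(fc$vertices, c(0, 0, 1)),
               radial_distances(cc$vertices, c(0, 0, 1)), tolerance = 1e-12)
})

test_that("vertex perturbation is zero-mean, seeded and topology-preserving", {
  m <- make_cylinder_mesh(4, 40, n_circumferential = 100, n_axial = 100)

  expect_identical(perturb_mesh(m, 0, seed = 3)$vertices, m$vertices)

  p1 <- perturb_mesh(m, 0.1, seed = 42)
  p2 <- perturb_mesh(m, 0.1, seed = 42)
  expect_identical(p1$vertices, p2$vertices)
  expect_identical(p1$faces, m$faces)

  p3 <- perturb_mesh(m, 0.1, seed = 43)
  expect_false(identical(p1$vertices, p3$vertices))

  # CLT: mean radial distance within 3 standard errors of the true radius
  r <- radial_distances(p1$vertices, c(0, 0, 1))
  se <- 0.1 / sqrt(nrow(p1$vertices))
  expect_lt(abs(mean(r) - 4.0), 3 * se + 0.1^2 / 4)  # + curvature term
})

test_that("perturbation does not touch global RNG state", {
  set.seed(999)
  before <- .Random.seed
  invisible(perturb_mesh(make_cylinder_mesh(3, 10), 0.05, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("parallel plates have the stated gap and facing normals", {
  m <- make_plates_mesh(5, size_mm = 10, n = 6)
  z <- m$vertices[, 3]
  expect_setequal(round(unique(z), 9), c(-2.5, 2.5))
  n <- face_normals(m)
  cen <- face_centroids(m)
  # normals point from each plate toward the other
  expect_true(all(sign(n[, 3]) == -sign(cen[, 3])))
})
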