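test_that("centerline of a straight tube lies on the true axis", {
  R <- fixed_rotation(3)
  ax <- as.vector(R %*% c(0, 0, 1))
  m <- make_cylinder_mesh(3, 30, axis_direction = ax, axis_point = c(1, 2, 3),
                          n_circumferential = 64, n_axial = 40)
  cl <- fit_centerline(m)
  dev <- radial_distances(cl$points, ax, c(1, 2, 3))
  expect_lt(max(dev), 1e-6)
  expect_true(all(diff(cl$arc_length) > 0))

  fr <- make_frustum_mesh(2.5, 3.5, 30, axis_direction = ax,
                          axis_point = c(1, 2, 3),
                          n_circumferential = 64, n_axial = 40)
  devf <- radial_distances(fit_centerline(fr)$points, ax, c(1, 2, 3))
  expect_lt(max(devf), 1e-6)
})

test_that("centerline follows a bent tube's medial axis", {
  # miter-jointed tube: two segments meeting at the origin, 10 degrees apart
  half_angle <- 5 * pi / 180
  d1 <- c(sin(half_angle), 0, cos(half_angle))
  d2 <- c(-sin(half_angle), 0, cos(half_angle))
  r <- 3
  mesh <- bent_tube_mesh(r = r, seg_len = 20, half_angle = half_angle,
                         n_per_seg = 100)
  cl <- fit_centerline(mesh, n_slabs = 20)
  # analytic medial axis: the two segments {t*d1} and {-t*d2}, t in [0,20]
  seg_dist <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (a + t * ab))^2))
  }
  dev <- apply(cl$points, 1, function(p) {
    min(seg_dist(p, c(0, 0, 0), 20 * d1), seg_dist(p, c(0, 0, 0), -20 * d2))
  })
  # straight interior slabs recover the axis to well under 5% of the radius;
  # the slabs cutting the tube ends and the elbow itself carry the known
  # oblique-cut bias of the slab recipe (order r times the bend angle),
  # bounded here at 10% of the radius
  z <- cl$points[, 3]
  interior <- abs(z) > 2.5 & abs(z) < 17
  expect_true(any(interior))
  expect_lt(max(dev[interior]), 0.05 * r)
  expect_lt(max(dev), 0.10 * r)
})

test_that("mid-length transverse section of a cylinder returns its diameter", {
  R <- fixed_rotation(9)
  ax <- as.vector(R %*% c(0, 0, 1))
  # fine tessellation: the chord sagitta r*(pi/n)^2/2 is below the 1e-6
  # tolerance, and an even ring count keeps every vertex off the mid plane
  m <- make_cylinder_mesh(3, 30, axis_direction = ax,
                          n_circumferential = 4096, n_axial = 24)
  cs <- transverse_section_diameter(m, fit_centerline(m, n_slabs = 24), 0.5)
  expect_lt(abs(cs$diameter_mm - 6.0), 1e-6)
})

test_that("frustum sections recover the linear taper", {
  fr <- make_frustum_mesh(2.5, 3.5, 30, n_circumferential = 256, n_axial = 48)
  cl <- fit_centerline(fr, n_slabs = 20)
  d_at <- vapply(c(0.25, 0.5, 0.75), function(s) {
    transverse_section_diameter(fr, cl, s)$diameter_mm
  }, numeric(1))
  expect_lt(abs(d_at[2] - 6.0), 1e-3)
  # three stations collinear in (station, radius): the mid radius is the
  # mean of the quarter radii
  expect_lt(abs(d_at[2] - (d_at[1] + d_at[3]) / 2) / 2, 1e-3)
})

test_that("square prism section matches a direct circle-fit oracle", {
  a <- 6   # side length
  side <- seq(-a / 2, a / 2, length.out = 15)[-15]
  profile <- rbind(cbind(side, -a / 2), cbind(a / 2, side),
                   cbind(rev(side), a / 2), cbind(-a / 2, rev(side)))
  prism <- profile_tube_mesh(profile, 20)
  cs <- transverse_section_diameter(prism, fit_centerline(prism, n_slabs = 10),
                                    0.5)
  # oracle: direct Nelder-Mead minimisation of the geometric objective on
  # the section boundary points
  pts2 <- cs$boundary_mm[, 1:2]
  obj <- function(p) {
    di <- sqrt((pts2[, 1] - p[1])^2 + (pts2[, 2] - p[2])^2)
    sum((di - p[3])^2)
  }
  o <- optim(c(0, 0, a / 2), obj, control = list(reltol = 1e-14,
                                                 maxit = 5000))
  expect_lt(abs(cs$radius_mm - o$par[3]), 1e-4)
})

test_that("sections through an aperture or outside the mesh fail loudly", {
  m <- make_cylinder_mesh(3, 30, n_circumferential = 48, n_axial = 25)
  # open a hole in the side wall near mid-length
  cen <- face_centroids(m)
  hole <- abs(cen[, 3]) < 2 & cen[, 1] > 2.5
  holey <- tunnel_mesh(m$vertices, m$faces[!hole, , drop = FALSE],
                       orientation = "into_lumen", has_aperture = TRUE)
  cl <- fit_centerline(m, n_slabs = 25)
  expect_error(transverse_section_diameter(holey, cl, 0.5), "aperture")
  expect_error(transverse_section_diameter(m, cl, 1.5), "station")
})

test_that("all mesh methods are rigidly invariant together", {
  m <- make_cylinder_mesh(3.25, 28, n_circumferential = 64, n_axial = 24)
  R <- fixed_rotation(21)
  m2 <- transform_mesh(m, rotation = R, translation = c(5, -3, 8))
  for (mesh_pair in list(list(m, m2))) {
    d1 <- c(
      fit_cylinder(mesh_pair[[1]])$diameter_mm,
      transverse_section_diameter(mesh_pair[[1]])$diameter_mm,
      wall_thickness(mesh_pair[[1]])$diameter_mm
    )
    d2 <- c(
      fit_cylinder(mesh_pair[[2]])$diameter_mm,
      transverse_section_diameter(mesh_pair[[2]])$diameter_mm,
      wall_thickness(mesh_pair[[2]])$diameter_mm
    )
    expect_lt(max(abs(d1 - d2)), 1e-6)
  }
})
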