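# Shared fixtures, built in code. Heavy objects are memoised so several
# test files can reuse them without regenerating.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- builder()
  }
  .fixture_cache[[name]]
}

# deterministic rotation matrix from a seed
fixed_rotation <- function(seed) {
  tunnelmetry:::with_local_seed(seed, tunnelmetry:::random_rotation())
}

# radial distances of points about an axis through `point` along unit `d`
radial_distances <- function(pts, d, point = c(0, 0, 0)) {
  rel <- sweep(pts, 2, point)
  t_ax <- as.vector(rel %*% d)
  perp <- rel - t_ax %*% t(d)
  sqrt(rowSums(perp^2))
}

# tube mesh over an arbitrary closed 2D profile (rows of profile_xy), used
# for the square-prism cross-section oracle
profile_tube_mesh <- function(profile_xy, length_mm, n_axial = 11L) {
  n_circ <- nrow(profile_xy)
  zs <- seq(-length_mm / 2, length_mm / 2, length.out = n_axial)
  verts <- do.call(rbind, lapply(zs, function(z) cbind(profile_xy, z)))
  idx <- function(ring, j) (ring - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L
  j <- seq_len(n_circ)
  faces <- do.call(rbind, lapply(seq_len(n_axial - 1L), function(i) {
    a <- idx(i, j); b <- idx(i, j + 1L)
    c_ <- idx(i + 1L, j); d_ <- idx(i + 1L, j + 1L)
    rbind(cbind(a, c_, b), cbind(b, c_, d_))
  }))
  tunnel_mesh(verts, faces, orientation = "into_lumen", has_aperture = TRUE)
}

# Miter-jointed bent tube: two straight cylindrical segments meeting at the
# origin with a miter-ellipse ring in the bisector plane, i.e. a proper
# bent pipe without overlapping walls. half_angle is half the bend angle.
bent_tube_mesh <- function(r = 3, seg_len = 20, half_angle = 5 * pi / 180,
                           n_circ = 48L, n_per_seg = 30L) {
  d1 <- c(sin(half_angle), 0, cos(half_angle))
  d2 <- c(-sin(half_angle), 0, cos(half_angle))
  theta <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  ring_at <- function(centre, d) {
    ref <- c(0, 1, 0)                     # keeps rings azimuthally aligned
    e1 <- c(ref[2] * d[3] - ref[3] * d[2],
            ref[3] * d[1] - ref[1] * d[3],
            ref[1] * d[2] - ref[2] * d[1])
    e1 <- e1 / sqrt(sum(e1^2))
    e2_ <- c(d[2] * e1[3] - d[3] * e1[2],
             d[3] * e1[1] - d[1] * e1[3],
             d[1] * e1[2] - d[2] * e1[1])
    t(centre + r * (outer(e1, cos(theta)) + outer(e2_, sin(theta))))
  }
  # miter ring: intersection of either cylinder with the bisector plane z=0
  miter <- cbind((r / cos(half_angle)) * cos(theta), r * sin(theta), 0)
  s_lo <- seq(-seg_len, 0, length.out = n_per_seg + 1L)[-(n_per_seg + 1L)]
  s_hi <- seq(0, seg_len, length.out = n_per_seg + 1L)[-1L]
  rings <- c(lapply(s_lo, function(s) ring_at(-s * -d2, d2)),
             list(miter),
             lapply(s_hi, function(s) ring_at(s * d1, d1)))
  verts <- do.call(rbind, rings)
  n_rings <- length(rings)
  idx <- function(ring, j) (ring - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L
  j <- seq_len(n_circ)
  faces <- do.call(rbind, lapply(seq_len(n_rings - 1L), function(i) {
    a <- idx(i, j); b <- idx(i, j + 1L)
    c_ <- idx(i + 1L, j); d_ <- idx(i + 1L, j + 1L)
    rbind(cbind(a, c_, b), cbind(b, c_, d_))
  }))
  tunnel_mesh(verts, faces, orientation = "into_lumen", has_aperture = TRUE)
}

# small tilted noisy phantom measured end to end (reused by several files)
measured_phantom_7mm <- function() {
  fixture("measured_phantom_7mm", function() {
    spec <- phantom_spec(drill_diameter_mm = 7,
                         tunnel_axis = c(sin(pi / 6), 0, cos(pi / 6)),
                         seed = 11L)
    ph <- make_phantom_volume(spec)
    res <- measure_volume_tunnel(ph$volume, c(0, 0, 0), run_config(),
                                 truth = ph$truth, id = "fixture7")
    list(phantom = ph, result = res)
  })
}

# definitional two-way ANOVA ICC oracle: mean squares from raw sums of
# squares, computed with explicit loops (independent of the package path)
icc_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (mean(x[i, ]) - grand)^2
  ss_cols <- 0
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (mean(x[, j]) - grand)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    ss_tot <- ss_tot + (x[i, j] - grand)^2
  }
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
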