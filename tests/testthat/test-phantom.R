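test_that("carved tunnel volume matches the analytic cylinder volume", {
  # noiseless, unblurred, axis-aligned, tunnel fully interior to the block
  spec <- phantom_spec(drill_diameter_mm = 6, tunnel_axis = c(0, 0, 1),
                       tunnel_length_mm = 20, bone_extent_mm = c(30, 30, 30),
                       voxel_spacing_mm = c(0.5, 0.5, 0.5),
                       blur_sigma_voxels = 0, noise_sd = 0, margin_mm = 2)
  ph <- make_phantom_volume(spec)
  v <- ph$volume
  # tunnel voxels: inside the block but at background density
  xs <- v$origin_mm[1] + (seq_len(dim(v$voxels)[1]) - 1) * v$spacing_mm[1]
  ys <- v$origin_mm[2] + (seq_len(dim(v$voxels)[2]) - 1) * v$spacing_mm[2]
  zs <- v$origin_mm[3] + (seq_len(dim(v$voxels)[3]) - 1) * v$spacing_mm[3]
  in_block <- outer(outer(abs(xs) <= 15, abs(ys) <= 15, "&"), abs(zs) <= 15, "&")
  n_tunnel <- sum(in_block & v$voxels < 150)
  analytic <- pi * 3^2 * 20 / prod(v$spacing_mm)
  expect_lt(abs(n_tunnel - analytic) / analytic, 0.05)
})

test_that("tunnel voxelization converges to the analytic volume", {
  count_err <- function(sp) {
    spec <- phantom_spec(drill_diameter_mm = 6, tunnel_axis = c(0, 0, 1),
                         tunnel_length_mm = 20, bone_extent_mm = c(30, 30, 30),
                         voxel_spacing_mm = rep(sp, 3),
                         blur_sigma_voxels = 0, noise_sd = 0, margin_mm = 2)
    ph <- make_phantom_volume(spec)
    v <- ph$volume
    xs <- v$origin_mm[1] + (seq_len(dim(v$voxels)[1]) - 1) * v$spacing_mm[1]
    ys <- v$origin_mm[2] + (seq_len(dim(v$voxels)[2]) - 1) * v$spacing_mm[2]
    zs <- v$origin_mm[3] + (seq_len(dim(v$voxels)[3]) - 1) * v$spacing_mm[3]
    in_block <- outer(outer(abs(xs) <= 15, abs(ys) <= 15, "&"),
                      abs(zs) <= 15, "&")
    n <- sum(in_block & v$voxels < 150) * prod(v$spacing_mm)
    abs(n - pi * 9 * 20)
  }
  expect_lte(count_err(0.5), count_err(1.0))
})

test_that("phantom generation is deterministic for a fixed seed", {
  spec <- phantom_spec(seed = 123L)
  a <- make_phantom_volume(spec)
  b <- make_phantom_volume(spec)
  expect_identical(a$volume$voxels, b$volume$voxels)
  spec2 <- phantom_spec(seed = 124L)
  expect_false(identical(make_phantom_volume(spec2)$volume$voxels,
                         a$volume$voxels))
})

test_that("a tunnel that does not fit is rejected", {
  spec <- phantom_spec(drill_diameter_mm = 50)
  expect_error(make_phantom_volume(spec), "does not fit")
})

test_that("phantom spec validates its inputs", {
  expect_error(phantom_spec(drill_diameter_mm = -1))
  expect_error(phantom_spec(noise_sd = -5))
  expect_error(phantom_spec(tunnel_axis = c(0, 0, 0)), "degenerate")
})

test_that("cohort generation samples the 0.5 mm drill grid reproducibly", {
  grid <- seq(5, 9, by = 0.5)
  # manifest only: use tiny volumes to keep this quick
  tpl <- phantom_spec(tunnel_length_mm = 18, bone_extent_mm = c(34, 34, 12),
                      voxel_spacing_mm = c(2, 2, 2), blur_sigma_voxels = 0,
                      noise_sd = 0)
  co <- make_cohort(24, grid, spec_template = tpl, seed = 9)
  expect_equal(nrow(co$manifest), 24)
  expect_true(all(co$manifest$true_diameter_mm %in% grid))
  # obliquity in the stated band
  tilt <- acos(pmin(1, co$manifest$axis_z)) * 180 / pi
  expect_true(all(tilt >= 20 - 1e-9 & tilt <= 40 + 1e-9))

  co2 <- make_cohort(24, grid, spec_template = tpl, seed = 9)
  expect_identical(co$manifest, co2$manifest)

  co3 <- make_cohort(2, 6.0, spec_template = tpl, seed = 1)
  expect_equal(co3$manifest$true_diameter_mm, c(6, 6))

  expect_error(make_cohort(1, grid, spec_template = tpl), ">= 2")
  expect_error(make_cohort(5, numeric(0), spec_template = tpl), "non-empty")
})

test_that("phantom round-trips through NIfTI with its ground truth", {
  spec <- phantom_spec(tunnel_length_mm = 18, bone_extent_mm = c(34, 34, 12),
                       voxel_spacing_mm = c(1.5, 1.5, 1.5), seed = 5)
  ph <- make_phantom_volume(spec)
  stem <- file.path(tempdir(), "phantom_rt")
  paths <- write_phantom(ph, stem)
  vol <- read_volume(paths[["volume"]])
  expect_equal(vol$spacing_mm, ph$volume$spacing_mm, tolerance = 1e-6)
  expect_equal(vol$origin_mm, ph$volume$origin_mm, tolerance = 1e-4)
  expect_equal(vol$voxels, ph$volume$voxels, tolerance = 1e-6,
               ignore_attr = TRUE)
  tr <- read_ground_truth(paths[["truth"]])
  expect_equal(tr$true_diameter_mm, ph$truth$true_diameter_mm)
  expect_equal(tr$axis_direction, ph$truth$axis_direction, tolerance = 1e-12)
  unlink(paths)
})
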