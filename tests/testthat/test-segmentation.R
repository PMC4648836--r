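make_sharp_phantom <- function(d = 6, axis = c(0, 0, 1), sp = c(1, 1, 1)) {
  make_phantom_volume(phantom_spec(
    drill_diameter_mm = d, tunnel_axis = axis, tunnel_length_mm = 20,
    bone_extent_mm = c(30, 30, 30), voxel_spacing_mm = sp,
    blur_sigma_voxels = 0, noise_sd = 0, margin_mm = 2))
}

test_that("threshold segmentation reproduces the separable phantom levels", {
  ph <- make_sharp_phantom()
  v <- ph$volume
  mask <- threshold_segment(v, 200, Inf)
  expect_identical(mask$voxels, v$voxels >= 200)
  # independent geometric oracle: block minus tunnel
  xs <- v$origin_mm[1] + (seq_len(dim(v$voxels)[1]) - 1) * v$spacing_mm[1]
  ys <- v$origin_mm[2] + (seq_len(dim(v$voxels)[2]) - 1) * v$spacing_mm[2]
  zs <- v$origin_mm[3] + (seq_len(dim(v$voxels)[3]) - 1) * v$spacing_mm[3]
  in_block <- outer(outer(abs(xs) <= 15, abs(ys) <= 15, "&"), abs(zs) <= 15, "&")
  gx <- array(rep(xs, times = length(ys) * length(zs)), dim(v$voxels))
  gy <- array(rep(rep(ys, each = length(xs)), times = length(zs)), dim(v$voxels))
  in_tunnel <- (gx^2 + gy^2) <= 9  # axis +z through origin, |t| <= 10 covers block z? no: length 20
  gz <- array(rep(zs, each = length(xs) * length(ys)), dim(v$voxels))
  in_tunnel <- in_tunnel & abs(gz) <= 10
  expect_identical(mask$voxels, in_block & !in_tunnel)
})

test_that("threshold range above the maximum yields an empty mask with warning", {
  ph <- make_sharp_phantom()
  expect_warning(m <- threshold_segment(ph$volume, 1e6, Inf), "no voxels")
  expect_false(any(m$voxels))
  expect_error(threshold_segment(ph$volume, 10, 5), "low < high")
})

test_that("threshold segmentation is monotone in the density range", {
  ph <- make_phantom_volume(phantom_spec(seed = 2))   # blurred + noisy
  narrow <- threshold_segment(ph$volume, 200, 900)
  wide <- threshold_segment(ph$volume, 150, 1500)
  expect_true(all(wide$voxels[narrow$voxels]))
})

test_that("mid-level threshold on a blurred phantom recovers the tunnel volume", {
  ph <- make_phantom_volume(phantom_spec(
    drill_diameter_mm = 6, tunnel_axis = c(0, 0, 1), tunnel_length_mm = 20,
    bone_extent_mm = c(30, 30, 30), voxel_spacing_mm = c(0.5, 0.5, 0.5),
    blur_sigma_voxels = 0.6, noise_sd = 0, margin_mm = 2))
  v <- ph$volume
  bone <- threshold_segment(v, 150, Inf)   # midway background/cancellous
  xs <- v$origin_mm[1] + (seq_len(dim(v$voxels)[1]) - 1) * v$spacing_mm[1]
  ys <- v$origin_mm[2] + (seq_len(dim(v$voxels)[2]) - 1) * v$spacing_mm[2]
  zs <- v$origin_mm[3] + (seq_len(dim(v$voxels)[3]) - 1) * v$spacing_mm[3]
  in_core <- outer(outer(abs(xs) <= 12, abs(ys) <= 12, "&"), abs(zs) <= 8, "&")
  n_tunnel <- sum(in_core & !bone$voxels)
  analytic <- pi * 9 * 16 / prod(v$spacing_mm)
  expect_lt(abs(n_tunnel - analytic) / analytic, 0.10)
})

test_that("cavity extraction recovers the tunnel and only the tunnel", {
  ph <- make_sharp_phantom(d = 6)
  bone <- threshold_segment(ph$volume, 150, Inf)
  cavity <- extract_tunnel_cavity(bone, 6, c(0, 0, 0))
  # ground-truth tunnel voxels
  v <- ph$volume
  xs <- v$origin_mm[1] + (seq_len(dim(v$voxels)[1]) - 1) * v$spacing_mm[1]
  ys <- v$origin_mm[2] + (seq_len(dim(v$voxels)[2]) - 1) * v$spacing_mm[2]
  zs <- v$origin_mm[3] + (seq_len(dim(v$voxels)[3]) - 1) * v$spacing_mm[3]
  gx <- array(rep(xs, times = length(ys) * length(zs)), dim(v$voxels))
  gy <- array(rep(rep(ys, each = length(xs)), times = length(zs)), dim(v$voxels))
  gz <- array(rep(zs, each = length(xs) * length(ys)), dim(v$voxels))
  truth <- (gx^2 + gy^2 <= 9) & abs(gz) <= 10
  overlap <- sum(cavity$voxels & truth)
  expect_gte(overlap / sum(truth), 0.90)
  expect_lte(sum(cavity$voxels) / sum(truth), 1.10)
  # cavity is disjoint from bone
  expect_false(any(cavity$voxels & bone$voxels))
})

test_that("a solid block has no cavity", {
  vox <- array(FALSE, c(20, 20, 20))
  vox[5:16, 5:16, 5:16] <- TRUE
  solid <- binary_mask(vox, c(1, 1, 1), c(0, 0, 0))
  expect_error(extract_tunnel_cavity(solid, 5, c(10, 10, 10)), "no cavity")
})

test_that("cavity extraction is component-local for disjoint tunnels", {
  # block with two parallel square shafts
  vox <- array(FALSE, c(40, 40, 24))
  vox[4:37, 4:37, 4:21] <- TRUE
  vox[10:13, 10:13, ] <- FALSE    # tunnel A (open through z)
  vox[28:31, 28:31, ] <- FALSE    # tunnel B
  bone <- binary_mask(vox, c(1, 1, 1), c(0, 0, 0))
  cavA <- extract_tunnel_cavity(bone, 5, c(10.5, 10.5, 12))
  idxB <- which(cavA$voxels[28:31, 28:31, ])
  expect_length(idxB, 0)
  expect_true(cavA$voxels[11, 11, 12])
})

test_that("iso-surfacing a cylindrical cavity recovers its diameter", {
  ph <- make_phantom_volume(phantom_spec(
    drill_diameter_mm = 6, tunnel_axis = c(0, 0, 1), tunnel_length_mm = 40,
    bone_extent_mm = c(30, 30, 24), voxel_spacing_mm = c(0.5, 0.5, 0.5),
    blur_sigma_voxels = 0, noise_sd = 0, margin_mm = 2))
  bone <- threshold_segment(ph$volume, 150, Inf)
  cavity <- extract_tunnel_cavity(bone, 6, c(0, 0, 0))
  mesh <- mask_to_mesh(cavity)
  trimmed <- trim_tunnel_ends(mesh, 0.15)
  fit <- fit_cylinder(trimmed)
  expect_lt(abs(fit$diameter_mm - 6), 0.5 * min(ph$volume$spacing_mm))

  # structural sanity for any non-empty mask
  expect_gt(nrow(mesh$vertices), 0)
  expect_true(all(mesh$faces >= 1 & mesh$faces <= nrow(mesh$vertices)))
})

test_that("mesh diameter error shrinks with finer voxels", {
  err_at <- function(sp) {
    ph <- make_phantom_volume(phantom_spec(
      drill_diameter_mm = 6, tunnel_axis = c(0, 0, 1), tunnel_length_mm = 40,
      bone_extent_mm = c(30, 30, 24), voxel_spacing_mm = rep(sp, 3),
      blur_sigma_voxels = 0, noise_sd = 0, margin_mm = 2))
    bone <- threshold_segment(ph$volume, 150, Inf)
    cavity <- extract_tunnel_cavity(bone, 6, c(0, 0, 0))
    mesh <- trim_tunnel_ends(mask_to_mesh(cavity), 0.15)
    abs(fit_cylinder(mesh)$diameter_mm - 6)
  }
  expect_lte(err_at(0.5), err_at(1.0))
})

test_that("meshing an empty mask errors", {
  empty <- binary_mask(array(FALSE, c(10, 10, 10)), c(1, 1, 1), c(0, 0, 0))
  expect_error(mask_to_mesh(empty), "empty")
})
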