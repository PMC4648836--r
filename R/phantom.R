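#' Specification of a synthetic CT tunnel phantom
#'
#' Describes a two-density rectangular bone block (cancellous interior with a
#' cortical shell) pierced by a cylindrical tunnel of known drill diameter,
#' voxelized at CT-like spacing with partial-volume blur and additive noise.
#' Defaults emulate a clinical knee protocol: in-plane spacing 500 mm field of
#' view / 512 = 0.977 mm, slice increment 0.75 mm, and drill diameters on the
#' 0.5 mm graft-ruler grid from 5.0 to 9.0 mm.
#'
#' The tunnel axis segment must lie laterally inside the volume (an error
#' otherwise); its ends may pierce the axial faces of the block, producing
#' the open apertures a drilled tunnel has at the bone surface.
#'
#' @param drill_diameter_mm tunnel diameter (mm), > 0.
#' @param tunnel_axis unit 3-vector, tunnel direction.
#' @param tunnel_length_mm axis segment length (mm).
#' @param bone_extent_mm length-3 extent of the bone block (mm).
#' @param cortical_density,cancellous_density,background_density HU-like
#'   density levels of shell, interior and surroundings.
#' @param cortical_thickness_mm thickness of the cortical shell (mm).
#' @param voxel_spacing_mm length-3 voxel spacing (mm).
#' @param blur_sigma_voxels isotropic Gaussian blur (voxel units) applied to
#'   the density field, modelling partial volume.
#' @param noise_sd additive Gaussian noise SD (density units).
#' @param margin_mm background margin around the block (mm).
#' @param seed integer seed for the noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(drill_diameter_mm = 7,
                         tunnel_axis = c(0, 0, 1),
                         tunnel_length_mm = 30,
                         bone_extent_mm = c(46, 46, 22),
                         cortical_density = 1200,
                         cancellous_density = 300,
                         background_density = 0,
                         cortical_thickness_mm = 1.5,
                         voxel_spacing_mm = c(500 / 512, 500 / 512, 0.75),
                         blur_sigma_voxels = 0.6,
                         noise_sd = 20,
                         margin_mm = 3,
                         seed = 1L) {
  stopifnot(drill_diameter_mm > 0, tunnel_length_mm > 0,
            all(bone_extent_mm > 0), all(voxel_spacing_mm > 0),
            blur_sigma_voxels >= 0, noise_sd >= 0, margin_mm >= 0)
  assert_unit3(normalize3(tunnel_axis), "tunnel_axis")
  structure(list(
    drill_diameter_mm = drill_diameter_mm,
    tunnel_axis = normalize3(tunnel_axis),
    tunnel_length_mm = tunnel_length_mm,
    bone_extent_mm = as.numeric(bone_extent_mm),
    cortical_density = cortical_density,
    cancellous_density = cancellous_density,
    background_density = background_density,
    cortical_thickness_mm = cortical_thickness_mm,
    voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    blur_sigma_voxels = blur_sigma_voxels,
    noise_sd = noise_sd,
    margin_mm = margin_mm,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Ground truth of a generated phantom
#'
#' The drill diameter plays the role the surgical drill record plays for real
#' scans: the control measure every method is compared against.
#'
#' @param id tunnel identifier (character).
#' @param true_diameter_mm drilled diameter (mm).
#' @param axis_point point on the tunnel axis (mm, world coordinates).
#' @param axis_direction unit 3-vector.
#' @param length_mm axis segment length (mm).
#' @param profile `"cylinder"`, `"frustum"` or `"plates"`.
#' @param profile_params optional list (e.g. `r_entry`, `r_exit`, `gap`).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(id, true_diameter_mm, axis_point, axis_direction,
                         length_mm, profile = "cylinder",
                         profile_params = list()) {
  stopifnot(true_diameter_mm > 0, length_mm > 0)
  assert_unit3(axis_direction, "axis_direction")
  if (profile == "frustum") {
    stopifnot(profile_params$r_entry > 0, profile_params$r_exit > 0)
  }
  structure(list(id = as.character(id), true_diameter_mm = true_diameter_mm,
                 axis_point = as.numeric(axis_point),
                 axis_direction = as.numeric(axis_direction),
                 length_mm = length_mm, profile = profile,
                 profile_params = profile_params),
            class = "ground_truth")
}

#' Voxelize a tunnel phantom
#'
#' Builds the density volume of a [phantom_spec()]: background everywhere,
#' cancellous density inside the bone block, cortical density in a shell at
#' the block faces, background again inside the tunnel cylinder; then
#' isotropic Gaussian blur (partial volume) and additive Gaussian noise.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` (a [ct_volume()]) and `truth`
#'   (a [ground_truth()]).
#' @export
make_phantom_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$voxel_spacing_mm
  ext <- spec$bone_extent_mm + 2 * spec$margin_mm
  dims <- pmax(ceiling(ext / sp) + 1L, 8L)
  origin <- -(dims - 1) / 2 * sp       # grid centred on the block centre
  # voxel centre coordinates
  xs <- origin[1] + (seq_len(dims[1]) - 1) * sp[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * sp[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * sp[3]

  half <- spec$bone_extent_mm / 2
  inx <- abs(xs) <= half[1]; iny <- abs(ys) <= half[2]; inz <- abs(zs) <= half[3]
  corex <- abs(xs) <= half[1] - spec$cortical_thickness_mm
  corey <- abs(ys) <= half[2] - spec$cortical_thickness_mm
  corez <- abs(zs) <= half[3] - spec$cortical_thickness_mm

  in_block <- outer(outer(inx, iny, "&"), inz, "&")
  in_core <- outer(outer(corex, corey, "&"), corez, "&")

  vox <- array(spec$background_density, dims)
  vox[in_block] <- spec$cortical_density
  vox[in_core] <- spec$cancellous_density

  # carve the tunnel: voxels within radius of the axis segment
  d <- spec$tunnel_axis
  r <- spec$drill_diameter_mm / 2
  gx <- array(rep(xs, times = dims[2] * dims[3]), dims)
  gy <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dims)
  gz <- array(rep(zs, each = dims[1] * dims[2]), dims)
  t_ax <- gx * d[1] + gy * d[2] + gz * d[3]   # axis through the origin
  px <- gx - t_ax * d[1]; py <- gy - t_ax * d[2]; pz <- gz - t_ax * d[3]
  rad2 <- px^2 + py^2 + pz^2
  hl <- spec$tunnel_length_mm / 2
  in_tunnel <- rad2 <= r^2 & abs(t_ax) <= hl

  # the tunnel must stay laterally inside the volume over the block's
  # axial span (apertures through the block faces are allowed)
  check_tunnel_fits(spec, dims, origin)
  vox[in_tunnel] <- spec$background_density

  if (spec$blur_sigma_voxels > 0) {
    vox <- gaussian_blur3(vox, spec$blur_sigma_voxels)
  }
  if (spec$noise_sd > 0) {
    noise <- with_local_seed(spec$seed,
                             rnorm(prod(dims), sd = spec$noise_sd))
    vox <- vox + array(noise, dims)
  }
  truth <- ground_truth(id = "phantom", true_diameter_mm = 2 * r,
                        axis_point = c(0, 0, 0), axis_direction = d,
                        length_mm = spec$tunnel_length_mm)
  list(volume = ct_volume(vox, sp, origin), truth = truth)
}

check_tunnel_fits <- function(spec, dims, origin) {
  d <- spec$tunnel_axis
  r <- spec$drill_diameter_mm / 2
  hl <- spec$tunnel_length_mm / 2
  half <- spec$bone_extent_mm / 2
  tt <- seq(-hl, hl, length.out = 64)
  for (t in tt) {
    p <- t * d
    # laterally the tunnel must stay inside the bone block over the block's
    # axial span; beyond it the ends may pierce the faces (apertures)
    if (abs(p[3]) <= half[3] &&
        (any(abs(p[1:2]) + r > half[1:2]))) {
      stop("tunnel does not fit inside the bone block ",
           "(reduce tilt, length or diameter, or enlarge bone_extent_mm)",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write a phantom and its ground truth to disk
#'
#' The volume goes to NIfTI; the ground truth to a JSON sidecar with the same
#' stem.
#'
#' @param phantom result of [make_phantom_volume()].
#' @param stem output path without extension.
#' @return paths of the written files, invisibly.
#' @export
write_phantom <- function(phantom, stem) {
  vol_path <- paste0(stem, ".nii.gz")
  json_path <- paste0(stem, ".json")
  write_nifti_volume(phantom$volume, vol_path)
  tr <- phantom$truth
  jsonlite::write_json(list(
    id = tr$id, true_diameter_mm = tr$true_diameter_mm,
    axis_point = tr$axis_point, axis_direction = tr$axis_direction,
    length_mm = tr$length_mm, profile = tr$profile
  ), json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(volume = vol_path, truth = json_path))
}

#' Read a ground-truth JSON sidecar
#'
#' @param path JSON file written by [write_phantom()].
#' @return a [ground_truth()].
#' @export
read_ground_truth <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  ground_truth(g$id, g$true_diameter_mm, g$axis_point, g$axis_direction,
               g$length_mm, g$profile %||% "cylinder")
}

#' Generate a cohort of tunnel phantoms
#'
#' Draws `n_tunnels` drill diameters (with replacement) from the 0.5 mm
#' graft-ruler grid and a random oblique tunnel orientation per phantom: the
#' axis is tilted uniformly 20-40 degrees away from the scan (z) axis with a
#' uniform azimuth, emulating the oblique femoral tunnels of anatomic ACL
#' reconstruction. Each phantom gets its own derived seed so the cohort is
#' reproducible from the single `seed` argument.
#'
#' @param n_tunnels number of phantoms (>= 2); the validation cohort default
#'   is 24 subjects.
#' @param diameter_grid candidate drill diameters (mm).
#' @param spec_template [phantom_spec()] supplying all other parameters.
#' @param seed integer master seed.
#' @param tilt_range_deg range of the axis tilt from the z axis (degrees).
#' @return list with `phantoms` (list of `list(volume, truth)`) and
#'   `manifest` (data.frame: id, true_diameter_mm, axis, length_mm, seed).
#' @export
make_cohort <- function(n_tunnels = 24L,
                        diameter_grid = seq(5, 9, by = 0.5),
                        spec_template = phantom_spec(),
                        seed = 1L,
                        tilt_range_deg = c(20, 40)) {
  if (n_tunnels < 2L) stop("n_tunnels must be >= 2", call. = FALSE)
  if (!length(diameter_grid)) stop("diameter_grid must be non-empty", call. = FALSE)
  draws <- with_local_seed(seed, {
    list(
      # index-based draw: sample(x, ...) on a length-1 numeric x would
      # sample from 1:x instead of from the grid
      diam = diameter_grid[sample.int(length(diameter_grid), n_tunnels,
                                      replace = TRUE)],
      tilt = runif(n_tunnels, tilt_range_deg[1], tilt_range_deg[2]) * pi / 180,
      azim = runif(n_tunnels, 0, 2 * pi)
    )
  })
  phantoms <- vector("list", n_tunnels)
  rows <- vector("list", n_tunnels)
  for (i in seq_len(n_tunnels)) {
    axis <- c(sin(draws$tilt[i]) * cos(draws$azim[i]),
              sin(draws$tilt[i]) * sin(draws$azim[i]),
              cos(draws$tilt[i]))
    sp_i <- spec_template
    sp_i$drill_diameter_mm <- draws$diam[i]
    sp_i$tunnel_axis <- axis
    sp_i$seed <- as.integer((seed + 7919 * i) %% .Machine$integer.max)
    ph <- make_phantom_volume(sp_i)
    ph$truth$id <- sprintf("tunnel_%02d", i)
    phantoms[[i]] <- ph
    rows[[i]] <- data.frame(
      id = ph$truth$id,
      true_diameter_mm = draws$diam[i],
      axis_x = axis[1], axis_y = axis[2], axis_z = axis[3],
      length_mm = sp_i$tunnel_length_mm,
      seed = sp_i$seed,
      stringsAsFactors = FALSE
    )
  }
  list(phantoms = phantoms, manifest = do.call(rbind, rows))
}
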