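#' CT volume container
#'
#' A voxel grid of density values with physical spacing and origin. The axis
#' order is fixed as (x, y, z) with 1-based array indices in R; world
#' coordinates are `origin + (index - 1) * spacing` so that voxel `[1, 1, 1]`
#' is centred at `origin`.
#'
#' @param voxels 3D numeric array of density values.
#' @param spacing_mm length-3 vector of positive voxel spacings (mm).
#' @param origin_mm length-3 vector, world position of the first voxel centre.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  stopifnot(length(dim(voxels)) == 3L, all(spacing_mm > 0),
            length(spacing_mm) == 3L, length(origin_mm) == 3L)
  if (any(dim(voxels) < 8L)) {
    stop("ct_volume requires at least 8 voxels per axis", call. = FALSE)
  }
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "ct_volume")
}

#' Binary mask on a CT grid
#'
#' Same geometry as [ct_volume()] but with logical voxels.
#'
#' @param voxels 3D logical array.
#' @inheritParams ct_volume
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  stopifnot(length(dim(voxels)) == 3L, is.logical(voxels))
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "binary_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, origin %s mm\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              paste(signif(x$origin_mm, 4), collapse = ", ")))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels (%d set), spacing %s mm\n",
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels),
              paste(signif(x$spacing_mm, 4), collapse = "x")))
  invisible(x)
}

# world coordinates (mm) of a voxel index triple (1-based, possibly fractional)
voxel_to_world <- function(vol, idx) {
  vol$origin_mm + (as.numeric(idx) - 1) * vol$spacing_mm
}

# nearest voxel index (1-based) of a world point; clamped into the grid
world_to_voxel <- function(vol, point_mm) {
  idx <- round((as.numeric(point_mm) - vol$origin_mm) / vol$spacing_mm) + 1
  pmin(pmax(idx, 1), dim(vol$voxels))
}

#' Write a volume or mask to NIfTI
#'
#' Spacing is stored in `pixdim` and the origin in the sform/qform
#' translation. Masks are written as 8-bit integers.
#'
#' @param vol a [ct_volume()] or [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(vol, path) {
  dat <- vol$voxels
  if (is.logical(dat)) dat <- array(as.integer(dat), dim(dat))
  img <- RNifti::asNifti(dat)
  # pixdim must be set before the xform: the qform replacement keeps the
  # rotation/translation but takes the scale from pixdim
  RNifti::pixdim(img) <- vol$spacing_mm
  xfm <- diag(4)
  diag(xfm)[1:3] <- vol$spacing_mm
  xfm[1:3, 4] <- vol$origin_mm
  img <- RNifti::`qform<-`(img, structure(xfm, code = 2L))
  img <- RNifti::`sform<-`(img, structure(xfm, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file.
#' @param as_mask return a [binary_mask()] (voxels != 0) instead of a
#'   [ct_volume()].
#' @return a [ct_volume()] or [binary_mask()].
#' @export
read_nifti_volume <- function(path, as_mask = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read NIfTI volume: '%s' does not exist", path),
         call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  xfm <- RNifti::xform(img)
  spacing <- abs(c(RNifti::pixdim(img)))[1:3]
  origin <- xfm[1:3, 4]
  # undo RNifti's RAS sign flips so our (x,y,z) convention round-trips
  signs <- sign(diag(xfm[1:3, 1:3, drop = FALSE]))
  signs[signs == 0] <- 1
  dims <- dim(img)[1:3]
  origin <- ifelse(signs < 0, origin - spacing * (dims - 1), origin)
  arr <- array(as.numeric(img), dim = dims)
  for (ax in which(signs < 0)) {
    idx <- rev(seq_len(dims[ax]))
    arr <- switch(ax,
                  arr[idx, , , drop = FALSE],
                  arr[, idx, , drop = FALSE],
                  arr[, , idx, drop = FALSE])
  }
  if (as_mask) binary_mask(arr != 0, spacing, origin)
  else ct_volume(arr, spacing, origin)
}

#' Write a volume to NRRD
#'
#' Minimal NRRD0004 writer: raw little-endian doubles, attached header,
#' spacing via `space directions`, origin via `space origin`.
#'
#' @inheritParams write_nifti_volume
#' @param encoding `"raw"` or `"gzip"`.
#' @return `path`, invisibly.
#' @export
write_nrrd_volume <- function(vol, path, encoding = c("gzip", "raw")) {
  encoding <- match.arg(encoding)
  dat <- vol$voxels
  if (is.logical(dat)) dat <- array(as.numeric(dat), dim(dat))
  s <- vol$spacing_mm
  header <- c(
    "NRRD0004",
    "# tunnelmetry volume",
    "type: double",
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %d %d %d", dim(dat)[1], dim(dat)[2], dim(dat)[3]),
    sprintf("space directions: (%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
            s[1], s[2], s[3]),
    "endian: little",
    sprintf("encoding: %s", encoding),
    sprintf("space origin: (%.9g,%.9g,%.9g)",
            vol$origin_mm[1], vol$origin_mm[2], vol$origin_mm[3]),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  payload <- writeBin(as.numeric(dat), raw(), size = 8, endian = "little")
  if (encoding == "gzip") payload <- memCompress(payload, "gzip")
  writeBin(payload, con)
  invisible(path)
}

#' Read an NRRD volume
#'
#' Supports 3D attached-header NRRD with raw or gzip encoding and the scalar
#' types this package writes plus common integer types.
#'
#' @inheritParams read_nifti_volume
#' @return a [ct_volume()] or [binary_mask()].
#' @export
read_nrrd_volume <- function(path, as_mask = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read NRRD volume: '%s' does not exist", path),
         call. = FALSE)
  }
  raw_all <- readBin(path, "raw", file.info(path)$size)
  # header ends at the first blank line
  nl <- which(raw_all == as.raw(10L))
  hdr_end <- NA_integer_
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L) { hdr_end <- p; break }
    prev <- p
  }
  if (is.na(hdr_end)) stop("malformed NRRD: no blank line after header",
                           call. = FALSE)
  hdr <- strsplit(rawToChar(raw_all[1:(hdr_end - 1L)]), "\n")[[1]]
  field <- function(name) {
    ln <- grep(sprintf("^%s:", name), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub(sprintf("^%s:\\s*", name), "", ln[1]))
  }
  type <- field("type") %||% "double"
  sizes <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
  enc <- field("encoding") %||% "raw"
  sd_ <- field("space directions")
  spacing <- c(1, 1, 1)
  if (!is.null(sd_)) {
    vecs <- regmatches(sd_, gregexpr("\\(([^)]*)\\)", sd_))[[1]]
    spacing <- vapply(seq_along(vecs), function(i) {
      v <- as.numeric(strsplit(gsub("[()]", "", vecs[i]), ",")[[1]])
      sqrt(sum(v^2))
    }, numeric(1))[1:3]
  }
  so <- field("space origin")
  origin <- c(0, 0, 0)
  if (!is.null(so)) {
    origin <- as.numeric(strsplit(gsub("[()]", "", so), ",")[[1]])[1:3]
  }
  payload <- raw_all[(hdr_end + 1L):length(raw_all)]
  if (enc == "gzip") payload <- memDecompress(payload, "gzip")
  n <- prod(sizes)
  vals <- switch(type,
    "double" = readBin(payload, "numeric", n, size = 8, endian = "little"),
    "float" = readBin(payload, "numeric", n, size = 4, endian = "little"),
    "short" = , "int16" = readBin(payload, "integer", n, size = 2,
                                  signed = TRUE, endian = "little"),
    "uchar" = , "uint8" = as.integer(payload[1:n]),
    "int" = , "int32" = readBin(payload, "integer", n, size = 4,
                                endian = "little"),
    stop(sprintf("unsupported NRRD type '%s'", type), call. = FALSE))
  arr <- array(as.numeric(vals), dim = sizes)
  if (as_mask) binary_mask(arr != 0, spacing, origin)
  else ct_volume(arr, spacing, origin)
}

#' Read a CT volume by file extension
#'
#' Dispatches to the NIfTI or NRRD reader based on the file name.
#'
#' @inheritParams read_nifti_volume
#' @return a [ct_volume()] or [binary_mask()].
#' @export
read_volume <- function(path, as_mask = FALSE) {
  if (grepl("\\.nii(\\.gz)?$", path)) read_nifti_volume(path, as_mask)
  else if (grepl("\\.nrrd$", path)) read_nrrd_volume(path, as_mask)
  else stop(sprintf("unrecognised volume format: '%s' (expected .nii, .nii.gz or .nrrd)",
                    path), call. = FALSE)
}

# Separable Gaussian blur in voxel units (sigma per axis, truncated at 4 sigma).
# Edge handling: renormalised kernel (equivalent to replicate-average).
gaussian_blur3 <- function(arr, sigma_voxels) {
  sigma_voxels <- rep_len(sigma_voxels, 3L)
  for (ax in 1:3) {
    s <- sigma_voxels[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(4 * s))
    off <- -half:half
    w <- exp(-off^2 / (2 * s^2))
    w <- w / sum(w)
    arr <- convolve_axis(arr, w, off, ax)
  }
  arr
}

convolve_axis <- function(arr, w, off, ax) {
  d <- dim(arr)
  out <- array(0, d)
  norm <- array(0, d)
  n <- d[ax]
  for (m in seq_along(off)) {
    k <- off[m]
    src <- seq_len(n) + k
    ok <- src >= 1L & src <= n
    dst <- which(ok)
    src <- src[ok]
    sl <- function(a, idx) switch(ax,
                                  a[idx, , , drop = FALSE],
                                  a[, idx, , drop = FALSE],
                                  a[, , idx, drop = FALSE])
    add <- sl(arr, src) * w[m]
    # drop = FALSE keeps conformable 3D shapes when an extent is 1
    if (ax == 1L) {
      out[dst, , ] <- out[dst, , , drop = FALSE] + add
      norm[dst, , ] <- norm[dst, , , drop = FALSE] + w[m]
    } else if (ax == 2L) {
      out[, dst, ] <- out[, dst, , drop = FALSE] + add
      norm[, dst, ] <- norm[, dst, , drop = FALSE] + w[m]
    } else {
      out[, , dst] <- out[, , dst, drop = FALSE] + add
      norm[, , dst] <- norm[, , dst, drop = FALSE] + w[m]
    }
  }
  out / norm
}
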