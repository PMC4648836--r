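## STL / PLY mesh readers and writers.
## Both formats are simple enough that they are implemented directly here;
## the package supports binary and ASCII STL and ASCII PLY.

#' Write a mesh to STL
#'
#' @param mesh a [tunnel_mesh()].
#' @param path output file path.
#' @param binary write binary STL (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  n <- face_normals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- raw(80)
    txt <- charToRaw("tunnelmetry binary STL")
    header[seq_along(txt)] <- txt
    writeBin(header, con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    # 50-byte records: 12 little-endian float32 + 2 attribute bytes
    tri <- cbind(n, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                 v[f[, 3], , drop = FALSE])
    floats <- writeBin(as.numeric(t(tri)), raw(), size = 4, endian = "little")
    rec <- matrix(raw(50 * nrow(f)), nrow = 50)
    rec[1:48, ] <- matrix(floats, nrow = 48)
    writeBin(as.vector(rec), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid tunnelmetry", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         n[i, 1], n[i, 2], n[i, 3]), con)
      writeLines("    outer loop", con)
      for (k in 1:3) {
        p <- v[f[i, k], ]
        writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
      }
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid tunnelmetry", con)
  }
  invisible(path)
}

#' Read a mesh from STL (binary or ASCII)
#'
#' STL stores independent triangles; vertices shared between triangles are
#' merged on read so downstream topology (ray casting, sections) works.
#'
#' @param path STL file.
#' @param orientation normal convention to record on the result.
#' @return a [tunnel_mesh()].
#' @export
read_stl <- function(path, orientation = "into_lumen") {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  is_binary <- !is.na(ntri) && sz == 84 + 50 * ntri
  close(con)
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 84)
    body <- readBin(con, "raw", 50 * ntri)
    # 50-byte records: 12 little-endian float32 + 2 attribute bytes
    rec <- matrix(body, nrow = 50)
    floats <- readBin(as.vector(rec[1:48, ]), "numeric", n = 12 * ntri,
                      size = 4, endian = "little")
    m <- matrix(floats, ncol = 12, byrow = TRUE)
    verts <- rbind(m[, 4:6, drop = FALSE], m[, 7:9, drop = FALSE],
                   m[, 10:12, drop = FALSE])
    ord <- as.vector(t(matrix(seq_len(3 * ntri), ncol = 3)))
    verts <- verts[ord, , drop = FALSE]
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    parts <- strsplit(trimws(vl), "\\s+")
    verts <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    ntri <- nrow(verts) / 3
  }
  faces <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
  merge_duplicate_vertices(
    tunnel_mesh(verts, faces, orientation = orientation),
    tol = 1e-7
  )
}

#' Write a mesh to ASCII PLY
#'
#' @inheritParams write_stl
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply",
    "format ascii 1.0",
    "comment tunnelmetry mesh",
    sprintf("element vertex %d", nrow(v)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  ), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY mesh
#'
#' @param path PLY file.
#' @param orientation normal convention to record on the result.
#' @return a [tunnel_mesh()].
#' @export
read_ply <- function(path, orientation = "into_lumen") {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply") {
    stop(sprintf("'%s' is not a PLY file", path), call. = FALSE)
  }
  if (!grepl("ascii", lines[2])) {
    stop("only ASCII PLY is supported", call. = FALSE)
  }
  end <- match("end_header", trimws(lines))
  nv <- as.integer(sub("element vertex\\s+", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face\\s+", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vl <- lines[(end + 1):(end + nv)]
  fl <- lines[(end + nv + 1):(end + nv + nf)]
  vparts <- strsplit(trimws(vl), "\\s+")
  verts <- t(vapply(vparts, function(p) as.numeric(p[1:3]), numeric(3)))
  fparts <- strsplit(trimws(fl), "\\s+")
  faces <- t(vapply(fparts, function(p) as.integer(p[2:4]) + 1L, integer(3)))
  tunnel_mesh(verts, faces, orientation = orientation)
}
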