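# STL and PLY mesh I/O. STL (binary and ASCII) carries geometry only; PLY
# (ASCII) additionally persists the per-vertex signed-distance scalar and an
# optional 8-bit colour channel.

PLY_SCALAR_NAME <- "signed_distance_mm"

#' Read a surface mesh
#'
#' Reads binary/ASCII STL or ASCII PLY. STL vertices are welded on load so
#' triangles share vertices; PLY vertices are used as stored. A PLY property
#' named `signed_distance_mm` is loaded into the mesh's scalar channel.
#'
#' @param path an `.stl` or `.ply` file.
#' @param weld weld duplicate vertices after reading STL (default TRUE).
#' @return A [surface_mesh()].
#' @seealso [write_mesh()]
#' @export
read_mesh <- function(path, weld = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") return(read_ply(path))
  if (ext == "stl") {
    mesh <- read_stl(path)
    return(if (weld) weld_vertices(mesh) else mesh)
  }
  stop("unsupported mesh format: ", ext, call. = FALSE)
}

#' Write a surface mesh
#'
#' @param mesh a [surface_mesh()].
#' @param path output file.
#' @param format `"stl"` (binary) or `"ply"` (ASCII). STL cannot store the
#'   scalar channel; writing a mesh with scalars to STL warns that they are
#'   dropped.
#' @param colors optional n x 3 integer matrix (0-255) written as PLY
#'   `red/green/blue` vertex properties.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("stl", "ply"), colors = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  format <- match.arg(format)
  if (format == "stl") {
    if (!is.null(mesh$scalars))
      warning("STL cannot store per-vertex scalars; channel dropped")
    write_stl_binary(mesh, path)
  } else {
    write_ply(mesh, path, colors = colors)
  }
  invisible(path)
}

# ---- STL -------------------------------------------------------------------

read_stl <- function(path) {
  head_raw <- readBin(path, raw(), n = 512)
  is_ascii <- length(head_raw) >= 6 &&
    identical(rawToChar(head_raw[1:5]), "solid") &&
    # binary files may also start with "solid": check for "facet" in header
    grepl("facet", rawToChar(head_raw[head_raw != as.raw(0)]), fixed = TRUE)
  if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
}

read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, raw(), 80)
  n <- readBin(con, "integer", size = 4, endian = "little")
  if (is.na(n) || n < 0 || 84 + n * 50 != sz)
    stop("malformed binary STL: ", path, call. = FALSE)
  rec <- readBin(con, raw(), n * 50)
  dim(rec) <- c(50, n)
  tri <- apply(rec[13:48, , drop = FALSE], 2, function(b)
    readBin(b, "numeric", n = 9, size = 4, endian = "little"))
  verts <- matrix(as.vector(tri), ncol = 3, byrow = TRUE)
  faces <- matrix(seq_len(3 * n), ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces, clean = FALSE)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("malformed ASCII STL: ", path, call. = FALSE)
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(x) as.numeric(x[2:4]), numeric(3)))
  if (any(!is.finite(nums)))
    stop("malformed ASCII STL vertex line in ", path, call. = FALSE)
  faces <- matrix(seq_len(nrow(nums)), ncol = 3, byrow = TRUE)
  surface_mesh(nums, faces, clean = FALSE)
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("condylometry STL"), raw(80 - 16)), con)
  f <- mesh$faces
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  nrm <- face_normals(mesh)
  v <- mesh$vertices
  # 50-byte records: normal, 3 vertices (float32), attribute count (uint16)
  block <- matrix(0, 12, nrow(f))
  block[1:3, ] <- t(nrm)
  block[4:6, ] <- t(v[f[, 1], , drop = FALSE])
  block[7:9, ] <- t(v[f[, 2], , drop = FALSE])
  block[10:12, ] <- t(v[f[, 3], , drop = FALSE])
  payload <- writeBin(as.vector(block), raw(), size = 4, endian = "little")
  dim(payload) <- c(48, nrow(f))
  rec <- rbind(payload, matrix(as.raw(0), 2, nrow(f)))
  writeBin(as.vector(rec), con)
  invisible(path)
}

# ---- PLY (ASCII) -----------------------------------------------------------

write_ply <- function(mesh, path, colors = NULL) {
  v <- mesh$vertices
  n <- nrow(v)
  props <- c("property float x", "property float y", "property float z")
  cols <- NULL
  if (!is.null(mesh$scalars))
    props <- c(props, paste("property float", PLY_SCALAR_NAME))
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    stopifnot(nrow(colors) == n, ncol(colors) == 3)
    props <- c(props, "property uchar red", "property uchar green",
               "property uchar blue")
  }
  header <- c("ply", "format ascii 1.0",
              "comment condylometry signed-distance mesh",
              paste("element vertex", n), props,
              paste("element face", nrow(mesh$faces)),
              "property list uchar int vertex_indices", "end_header")
  vtab <- format(v, trim = TRUE, digits = 9)
  cols_txt <- do.call(paste, c(lapply(1:3, function(j) vtab[, j])))
  if (!is.null(mesh$scalars))
    cols_txt <- paste(cols_txt,
                      format(mesh$scalars, trim = TRUE, digits = 9))
  if (!is.null(colors))
    cols_txt <- paste(cols_txt, colors[, 1], colors[, 2], colors[, 3])
  ftab <- paste(3, mesh$faces[, 1] - 1, mesh$faces[, 2] - 1,
                mesh$faces[, 3] - 1)
  writeLines(c(header, cols_txt, ftab), path)
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path, call. = FALSE)
  if (!grepl("ascii", lines[2]))
    stop("only ASCII PLY is supported: ", path, call. = FALSE)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("malformed PLY header: ", path, call. = FALSE)
  header <- trimws(lines[seq_len(endh)])
  n_vert <- n_face <- 0
  vprops <- character(0)
  cur <- ""
  for (h in header) {
    if (grepl("^element vertex ", h)) {
      n_vert <- as.integer(sub("element vertex ", "", h)); cur <- "vertex"
    } else if (grepl("^element face ", h)) {
      n_face <- as.integer(sub("element face ", "", h)); cur <- "face"
    } else if (grepl("^property ", h) && cur == "vertex") {
      vprops <- c(vprops, sub("^property \\S+ ", "", h))
    }
  }
  vlines <- lines[(endh + 1):(endh + n_vert)]
  vdat <- matrix(as.numeric(unlist(strsplit(trimws(vlines), "\\s+"))),
                 nrow = n_vert, byrow = TRUE)
  colnames(vdat) <- vprops[seq_len(ncol(vdat))]
  verts <- vdat[, c("x", "y", "z"), drop = FALSE]
  scalars <- if (PLY_SCALAR_NAME %in% colnames(vdat))
    vdat[, PLY_SCALAR_NAME] else NULL
  flines <- lines[(endh + n_vert + 1):(endh + n_vert + n_face)]
  fdat <- matrix(as.integer(unlist(strsplit(trimws(flines), "\\s+"))),
                 nrow = n_face, byrow = TRUE)
  if (any(fdat[, 1] != 3))
    stop("only triangle PLY faces are supported: ", path, call. = FALSE)
  mesh <- surface_mesh(verts, fdat[, 2:4] + 1L, scalars = scalars,
                       clean = FALSE)
  attr(mesh, "ply_colors") <- if (all(c("red", "green", "blue")
                                      %in% colnames(vdat)))
    vdat[, c("red", "green", "blue"), drop = FALSE] else NULL
  mesh
}
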