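# Triangle surface meshes: constructor, mask-boundary extraction, normals,
# welding, watertightness, and a subdivided icosphere used by tests and
# examples.

#' Triangle surface mesh
#'
#' Vertices are mm coordinates in the patient frame; faces are 1-based vertex
#' index triples, oriented counter-clockwise seen from outside. An optional
#' per-vertex scalar channel carries signed distances (mm) for colour-map
#' export.
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param scalars optional numeric vector of length n (e.g. signed distance
#'   in mm).
#' @param clean drop zero-area (degenerate) triangles (default TRUE).
#' @return An object of class `surface_mesh` with a computed (not assumed)
#'   `watertight` flag.
#' @export
surface_mesh <- function(vertices, faces, scalars = NULL, clean = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3) stop("vertices must be n x 3", call. = FALSE)
  if (ncol(faces) != 3) stop("faces must be m x 3", call. = FALSE)
  if (any(!is.finite(vertices))) stop("vertex coordinates must be finite",
                                      call. = FALSE)
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  if (!is.null(scalars)) {
    scalars <- as.numeric(scalars)
    if (length(scalars) != nrow(vertices))
      stop("scalars must have one value per vertex", call. = FALSE)
  }
  if (clean && nrow(faces) > 0) {
    a <- face_areas(vertices, faces)
    keep <- a > 1e-12
    faces <- faces[keep, , drop = FALSE]
  }
  structure(list(vertices = vertices, faces = faces, scalars = scalars,
                 watertight = is_watertight(faces)),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, %swatertight%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (x$watertight) "" else "not ",
              if (is.null(x$scalars)) "" else ", with scalar channel"))
  invisible(x)
}

face_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  cr / pmax(sqrt(rowSums(cr^2)), 1e-30)
}

#' Outward per-vertex normals
#'
#' Area-weighted average of incident face normals. Orientation follows the
#' face winding, which is outward for meshes produced by [mesh_from_mask()]
#' and [mesh_icosphere()].
#'
#' @param mesh a [surface_mesh()].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])   # 2*area-weighted
  n <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    for (c_ in 1:3)
      n[, c_] <- n[, c_] + unname(tapply_add(cr[, c_], f[, j], nrow(v)))
  }
  len <- sqrt(rowSums(n^2))
  bad <- len < 1e-12
  len[bad] <- 1
  n <- n / len
  n[bad, ] <- 0
  n
}

# fast grouped sum into a fixed-length vector
tapply_add <- function(values, index, n) {
  out <- numeric(n)
  agg <- rowsum(values, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

is_watertight <- function(faces) {
  if (nrow(faces) == 0) return(FALSE)
  edges <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  all(table(key) == 2)
}

#' Total surface area and enclosed volume of a mesh
#'
#' Volume uses the signed divergence theorem and is only meaningful for
#' watertight, consistently oriented meshes.
#'
#' @param mesh a [surface_mesh()].
#' @return A list with `area` (mm^2) and `volume` (mm^3, signed).
#' @export
mesh_measures <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  list(area = sum(face_areas(v, f)),
       volume = sum(rowSums(a * cr)) / 6)
}

#' Weld duplicate vertices
#'
#' Merges vertices closer than `tol` (exact coordinate match after rounding
#' to `tol`), re-indexing faces. STL files store one vertex per corner, so
#' welding restores connectivity after [read_mesh()].
#'
#' @param mesh a [surface_mesh()].
#' @param tol welding tolerance in mm.
#' @return A [surface_mesh()] with unique vertices.
#' @export
weld_vertices <- function(mesh, tol = 1e-6) {
  key <- apply(round(mesh$vertices / tol), 1, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  new_v <- mesh$vertices[first, , drop = FALSE]
  new_f <- matrix(map[mesh$faces], ncol = 3)
  sc <- if (is.null(mesh$scalars)) NULL else mesh$scalars[first]
  surface_mesh(new_v, new_f, scalars = sc)
}

#' Extract the boundary surface of a binary mask
#'
#' Builds the voxel-boundary triangle mesh of a segmentation: every face
#' between a foreground and a background voxel contributes two triangles with
#' outward orientation, with vertices on the voxel corners (mm, volume
#' frame). The result is watertight by construction and shares provenance
#' with the voxel volume, as when a segmentation package exports an STL.
#'
#' @param mask a [ct_mask()].
#' @return A [surface_mesh()].
#' @export
mesh_from_mask <- function(mask) {
  m <- mask$data
  d <- dim(m)
  if (!any(m)) stop("mask is empty", call. = FALSE)
  # pad with background so border voxels generate faces
  p <- array(FALSE, d + 2)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  sp <- mask$spacing
  # corner (i,j,k) [0-based in corner grid] sits at origin + (idx-1.5)*spacing
  corner_key <- function(ci, cj, ck) {
    (ci + (d[1] + 2) * (cj + (d[2] + 2) * ck))
  }
  quads_i <- list(); quads_n <- 0
  add_faces <- function(fg_idx, axis, positive) {
    # fg_idx: arrayInd rows (padded grid) of foreground voxels whose
    # neighbour along +/- axis is background
    if (nrow(fg_idx) == 0) return(invisible())
    i <- fg_idx[, 1]; j <- fg_idx[, 2]; k <- fg_idx[, 3]
    # voxel (i,j,k) in padded grid has corners ci in {i-1, i} etc. (0-based
    # corner grid = padded index - 1)
    lo_i <- i - 1; lo_j <- j - 1; lo_k <- k - 1
    if (axis == 1) {
      ci <- if (positive) i else lo_i
      c1 <- cbind(ci, lo_j, lo_k); c2 <- cbind(ci, j, lo_k)
      c3 <- cbind(ci, j, k);       c4 <- cbind(ci, lo_j, k)
      if (!positive) { tmp <- c2; c2 <- c4; c4 <- tmp }
    } else if (axis == 2) {
      cj <- if (positive) j else lo_j
      c1 <- cbind(lo_i, cj, lo_k); c2 <- cbind(lo_i, cj, k)
      c3 <- cbind(i, cj, k);       c4 <- cbind(i, cj, lo_k)
      if (!positive) { tmp <- c2; c2 <- c4; c4 <- tmp }
    } else {
      ck <- if (positive) k else lo_k
      c1 <- cbind(lo_i, lo_j, ck); c2 <- cbind(lo_i, j, ck)
      c3 <- cbind(i, j, ck);       c4 <- cbind(i, lo_j, ck)
      if (positive) { tmp <- c2; c2 <- c4; c4 <- tmp }
    }
    quads_n <<- quads_n + 1
    quads_i[[quads_n]] <<- cbind(corner_key(c1[, 1], c1[, 2], c1[, 3]),
                                 corner_key(c2[, 1], c2[, 2], c2[, 3]),
                                 corner_key(c3[, 1], c3[, 2], c3[, 3]),
                                 corner_key(c4[, 1], c4[, 2], c4[, 3]))
    invisible()
  }
  shift <- function(arr, axis, by) {
    idx <- lapply(dim(arr), seq_len)
    n <- dim(arr)[axis]
    idx[[axis]] <- pmin(pmax(seq_len(n) + by, 1), n)
    out <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
    out
  }
  for (axis in 1:3) {
    nb_pos <- shift(p, axis, 1L)
    nb_neg <- shift(p, axis, -1L)
    sel_pos <- which(p & !nb_pos)
    sel_neg <- which(p & !nb_neg)
    add_faces(arrayInd(sel_pos, dim(p)), axis, TRUE)
    add_faces(arrayInd(sel_neg, dim(p)), axis, FALSE)
  }
  quads <- do.call(rbind, quads_i)
  keys <- unique(as.vector(quads))
  vidx <- match(as.vector(quads), keys)
  qf <- matrix(vidx, ncol = 4)
  # corner key -> 0-based corner coordinates -> mm
  ck <- keys
  ci <- ck %% (d[1] + 2); r <- ck %/% (d[1] + 2)
  cj <- r %% (d[2] + 2); ckk <- r %/% (d[2] + 2)
  verts <- cbind(mask$origin[1] + (ci - 1.5) * sp[1],
                 mask$origin[2] + (cj - 1.5) * sp[2],
                 mask$origin[3] + (ckk - 1.5) * sp[3])
  faces <- rbind(qf[, c(1, 2, 3)], qf[, c(1, 3, 4)])
  surface_mesh(verts, faces)
}

#' Subdivided icosphere
#'
#' A triangulated sphere used as analytic ground truth in tests and examples
#' (e.g. concentric-sphere signed-distance checks).
#'
#' @param radius sphere radius, mm.
#' @param center length-3 numeric, mm.
#' @param subdivisions number of 4-to-1 triangle subdivisions (0 gives the
#'   icosahedron; each level quadruples the face count).
#' @return A watertight [surface_mesh()] with outward-oriented faces.
#' @export
mesh_icosphere <- function(radius = 1, center = c(0, 0, 0), subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE)
    verts <- v
    nf <- matrix(0L, 0, 3)
    mid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      m <- edge_mid[[key]]
      if (!is.null(m)) return(m)
      p <- (verts[i, ] + verts[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      verts <<- rbind(verts, p)
      m <- nrow(verts)
      edge_mid[[key]] <- m
      m
    }
    new_f <- vector("list", nrow(f))
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c_ <- f[t, 3]
      ab <- mid(a, b); bc <- mid(b, c_); ca <- mid(c_, a)
      new_f[[t]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc),
                          c(ab, bc, ca))
    }
    v <- verts
    f <- do.call(rbind, new_f)
  }
  verts <- sweep(v * radius, 2, center, "+")
  surface_mesh(verts, f)
}

#' Taubin mesh smoothing
#'
#' Two-pass Laplacian smoothing (positive `lambda` shrink step followed by a
#' negative `mu` inflate step) that removes voxel staircase artefacts with
#' minimal shrinkage — the standard post-processing applied to segmentation
#' surfaces before morphometric comparison.
#'
#' @param mesh a [surface_mesh()].
#' @param iterations number of lambda/mu passes (default 20).
#' @param lambda,mu Taubin coefficients; `|mu| > lambda` with `mu < 0`.
#' @return The smoothed [surface_mesh()] (same connectivity).
#' @export
mesh_smooth <- function(mesh, iterations = 20, lambda = 0.5, mu = -0.53) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0 || iterations < 1) return(mesh)
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  edges <- rbind(edges, edges[, 2:1])
  deg <- tabulate(edges[, 1], nbins = nrow(v))
  step <- function(v, w) {
    nb <- rowsum(v[edges[, 2], , drop = FALSE], edges[, 1])
    nb <- nb / deg[as.integer(rownames(nb))]
    target <- v
    target[as.integer(rownames(nb)), ] <- nb
    v + w * (target - v)
  }
  for (i in seq_len(iterations)) {
    v <- step(v, lambda)
    v <- step(v, mu)
  }
  surface_mesh(v, f, scalars = mesh$scalars, clean = FALSE)
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh a [surface_mesh()].
#' @param transform a [rigid_transform()].
#' @return The transformed [surface_mesh()] (scalars preserved).
#' @export
transform_mesh <- function(mesh, transform) {
  surface_mesh(transform_points(transform, mesh$vertices), mesh$faces,
               scalars = mesh$scalars, clean = FALSE)
}
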