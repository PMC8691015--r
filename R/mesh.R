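#' Triangle mesh in patient coordinates
#'
#' A closed, consistently outward-oriented triangle surface mesh. Coordinates
#' are millimetres in the patient frame: +x patient-left, +y anterior,
#' +z cranial.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle,
#'   consistently oriented so that face normals point outward.
#' @param validate check watertightness, orientation and face degeneracy.
#'   A globally inverted mesh (negative enclosed volume) is repaired by
#'   flipping all faces, with a warning.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must have 3 columns")
  if (nrow(faces) < 4L) stop("a closed surface needs at least 4 faces")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  m <- structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
  if (validate) m <- validate_mesh(m)
  m
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces", nrow(x$vertices),
              nrow(x$faces)))
  if (isTRUE(attr(x, "watertight")))
    cat(sprintf(", watertight, volume %.3f cm^3", mesh_volume(x)))
  cat("\n")
  invisible(x)
}

# directed edge keys as doubles (exact up to 2^53)
edge_keys <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices) + 1
  a <- as.double(c(f[, 1], f[, 2], f[, 3]))
  b <- as.double(c(f[, 2], f[, 3], f[, 1]))
  list(fwd = a * nv + b, rev = b * nv + a, a = a, b = b)
}

#' Boundary (non-manifold) edges of a mesh
#'
#' Returns the directed edges that are not matched by an opposite-direction
#' twin; a watertight, consistently oriented mesh has none.
#' @param mesh a [tri_mesh()].
#' @return Two-column matrix of vertex index pairs (possibly 0 rows).
#' @export
mesh_boundary_edges <- function(mesh) {
  k <- edge_keys(mesh)
  if (anyDuplicated(k$fwd))
    return(cbind(k$a[duplicated(k$fwd)], k$b[duplicated(k$fwd)]))
  unmatched <- !(k$fwd %in% k$rev)
  cbind(k$a[unmatched], k$b[unmatched])
}

validate_mesh <- function(mesh) {
  # degenerate faces
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(cr^2))
  if (any(area2 <= 1e-12))
    stop("mesh has ", sum(area2 <= 1e-12), " degenerate (zero-area) face(s)")
  be <- mesh_boundary_edges(mesh)
  if (nrow(be) > 0) {
    show <- head(be, 10)
    stop("mesh is not watertight/consistently oriented; ", nrow(be),
         " boundary edge(s), e.g. ",
         paste(sprintf("(%d,%d)", show[, 1], show[, 2]), collapse = " "))
  }
  sv <- signed_volume_mm3(mesh)
  if (sv < 0) {
    warning("mesh orientation was inward (negative signed volume); ",
            "flipping all faces")
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  }
  attr(mesh, "watertight") <- TRUE
  mesh
}

ensure_watertight <- function(mesh) {
  if (!inherits(mesh, "tri_mesh")) stop("not a tri_mesh")
  if (!isTRUE(attr(mesh, "watertight"))) mesh <- validate_mesh(mesh)
  mesh
}

# signed enclosed volume in mm^3 (divergence theorem over origin tetrahedra)
signed_volume_mm3 <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
      a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Enclosed volume of a watertight mesh
#'
#' Volume by the divergence theorem (sum of signed origin tetrahedra).
#' @param mesh a watertight [tri_mesh()].
#' @return Volume in cm^3.
#' @export
mesh_volume <- function(mesh) {
  mesh <- ensure_watertight(mesh)
  abs(signed_volume_mm3(mesh)) / 1000
}

#' Solid centre of mass of a watertight mesh
#'
#' Uniform-density solid centroid (not the vertex average), via the signed
#' tetrahedron decomposition.
#' @param mesh a watertight [tri_mesh()].
#' @return Numeric length-3 point in mm.
#' @export
center_of_mass <- function(mesh) {
  mesh <- ensure_watertight(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  w <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
       a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
       a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  ctr <- (a + b + c) / 4  # tetra centroid with 4th vertex at the origin
  unname(colSums(ctr * w) / sum(w))
}

#' Rigid and affine mesh transforms
#'
#' @param mesh a [tri_mesh()].
#' @param offset numeric length-3 translation in mm.
#' @return The transformed mesh.
#' @export
mesh_translate <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2, offset, "+")
  mesh
}

#' @rdname mesh_translate
#' @param rotation 3 x 3 rotation matrix.
#' @param center point about which to rotate (default origin).
#' @export
mesh_rotate <- function(mesh, rotation, center = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be a proper rotation matrix (det = 1)")
  p <- sweep(mesh$vertices, 2, center)
  mesh$vertices <- sweep(p %*% t(rotation), 2, center, "+")
  mesh
}

#' Axis-aligned bounding box of a mesh
#' @param mesh a [tri_mesh()].
#' @return List with `lo` and `hi`, length-3 points in mm.
#' @export
mesh_bbox <- function(mesh) {
  list(lo = apply(mesh$vertices, 2, min), hi = apply(mesh$vertices, 2, max))
}

# parity test: is a point inside a closed mesh? (+z ray crossing count;
# the tiny offset avoids grazing lattice-aligned edges)
point_in_mesh <- function(p, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  rx <- p[1] + 7.1e-7
  ry <- p[2] + 11.3e-7
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  d <- (b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
       (b[, 2] - a[, 2]) * (c[, 1] - a[, 1])
  ok <- d != 0
  u <- ((rx - a[, 1]) * (c[, 2] - a[, 2]) -
          (ry - a[, 2]) * (c[, 1] - a[, 1])) / d
  w <- ((b[, 1] - a[, 1]) * (ry - a[, 2]) -
          (b[, 2] - a[, 2]) * (rx - a[, 1])) / d
  hit <- ok & u >= 0 & w >= 0 & u + w <= 1
  z <- a[, 3] + u * (b[, 3] - a[, 3]) + w * (c[, 3] - a[, 3])
  sum(hit & z > p[3]) %% 2 == 1
}

# rotation matrix about a coordinate axis (radians)
rot3 <- function(axis = c("z", "x", "y"), angle) {
  axis <- match.arg(axis)
  ca <- cos(angle); sa <- sin(angle)
  switch(axis,
    z = matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3),
    x = matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3),
    y = matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3))
}
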