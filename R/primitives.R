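#' Watertight geometric primitives
#'
#' Builds closed, outward-oriented triangle meshes for simple solids used as
#' atlas building blocks and test fixtures. All primitives are inscribed
#' (vertices lie on the ideal surface), so tessellated volumes approach the
#' analytic volume from below as the tessellation is refined.
#'
#' @param kind one of `"sphere"`, `"ellipsoid"`, `"cone"`, `"box"`.
#' @param ... parameters of the chosen primitive:
#' * sphere: `radius` (mm), `center`, `subdivisions` (icosphere level,
#'   default 3 giving 642 vertices).
#' * ellipsoid: `semiaxes` (length 3, mm), `center`, `subdivisions`.
#' * cone: `base_radius` (mm), `height` (mm), `base_center`,
#'   `axis` (unit direction from base towards apex, default `c(0, 0, -1)`),
#'   `segments` (default 96).
#' * box: `lengths` (length 3, mm), `center`.
#' @return A [tri_mesh()].
#' @export
make_primitive <- function(kind = c("sphere", "ellipsoid", "cone", "box"),
                           ...) {
  kind <- match.arg(kind)
  switch(kind,
         sphere = prim_sphere(...),
         ellipsoid = prim_ellipsoid(...),
         cone = prim_cone(...),
         box = prim_box(...))
}

# icosphere by repeated edge-midpoint subdivision of an icosahedron,
# vertices projected onto the unit sphere
unit_icosphere <- function(subdivisions = 3) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    # midpoint cache keyed by undirected vertex pair
    key <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
    e1 <- key(f[, 1], f[, 2]); e2 <- key(f[, 2], f[, 3])
    e3 <- key(f[, 3], f[, 1])
    allk <- c(e1, e2, e3)
    uk <- unique(allk)
    ia <- (uk %/% (nv + 1)); ib <- (uk %% (nv + 1))
    mid <- (v[ia, , drop = FALSE] + v[ib, , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    midx <- nv + match(allk, uk)
    m1 <- midx[seq_len(nrow(f))]
    m2 <- midx[nrow(f) + seq_len(nrow(f))]
    m3 <- midx[2 * nrow(f) + seq_len(nrow(f))]
    v <- rbind(v, mid)
    f <- rbind(cbind(f[, 1], m1, m3), cbind(f[, 2], m2, m1),
               cbind(f[, 3], m3, m2), cbind(m1, m2, m3))
  }
  list(vertices = v, faces = f)
}

prim_sphere <- function(radius, center = c(0, 0, 0), subdivisions = 3) {
  if (radius <= 0) stop("radius must be positive")
  s <- unit_icosphere(subdivisions)
  tri_mesh(sweep(s$vertices * radius, 2, center, "+"), s$faces)
}

prim_ellipsoid <- function(semiaxes, center = c(0, 0, 0), subdivisions = 3) {
  if (length(semiaxes) != 3 || any(semiaxes <= 0))
    stop("semiaxes must be 3 positive lengths")
  s <- unit_icosphere(subdivisions)
  v <- sweep(s$vertices, 2, semiaxes, "*")
  tri_mesh(sweep(v, 2, center, "+"), s$faces)
}

prim_cone <- function(base_radius, height, base_center = c(0, 0, 0),
                      axis = c(0, 0, -1), segments = 96) {
  if (base_radius <= 0 || height <= 0)
    stop("base_radius and height must be positive")
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal frame around the axis
  up <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- up - sum(up * axis) * axis
  u <- u / sqrt(sum(u^2))
  w <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  ang <- 2 * pi * (seq_len(segments) - 1) / segments
  ring <- sweep(base_radius * (outer(cos(ang), u) + outer(sin(ang), w)),
                2, base_center, "+")
  apex <- base_center + height * axis
  v <- rbind(ring, base_center, apex)
  ib <- segments + 1L
  ia <- segments + 2L
  nxt <- c(seq_len(segments)[-1], 1L)
  # winding below assumes the +z-up frame with axis pointing away from base;
  # base fan oriented opposite to side fan so normals are outward
  side <- cbind(seq_len(segments), nxt, rep(ia, segments))
  base <- cbind(nxt, seq_len(segments), rep(ib, segments))
  tri_mesh(v, rbind(side, base))
}

prim_box <- function(lengths, center = NULL, corner = NULL) {
  if (length(lengths) != 3 || any(lengths <= 0))
    stop("lengths must be 3 positive values")
  if (is.null(corner)) {
    if (is.null(center)) center <- c(0, 0, 0)
    corner <- center - lengths / 2
  }
  g <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  v <- sweep(g * rep(lengths, each = 8), 2, corner, "+")
  # vertex order from expand.grid: x fastest; explicit triangles, outward
  f <- rbind(
    c(1, 7, 3), c(1, 5, 7),   # x = 0 face
    c(2, 4, 8), c(2, 8, 6),   # x = 1 face
    c(1, 2, 6), c(1, 6, 5),   # y = 0 face
    c(3, 8, 4), c(3, 7, 8),   # y = 1 face
    c(1, 3, 4), c(1, 4, 2),   # z = 0 face
    c(5, 6, 8), c(5, 8, 7))   # z = 1 face
  tri_mesh(v, f)
}
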