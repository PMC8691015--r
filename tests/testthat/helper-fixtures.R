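# shared fixtures and independent oracles for the test suite

unit_cube <- function(corner = c(0, 0, 0), side = 10) {
  make_primitive("box", lengths = rep(side, 3), corner = corner)
}

# brute-force symmetric vertex-to-vertex distances (independent oracle,
# quadratic; only for small meshes)
brute_force_distances <- function(va, vb) {
  d2 <- outer(rowSums(va^2), rowSums(vb^2), "+") - 2 * va %*% t(vb)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  ab <- apply(d, 1, min)
  ba <- apply(d, 2, min)
  list(asd = (mean(ab) + mean(ba)) / 2, hd = max(max(ab), max(ba)))
}

# voxel-counting centroid oracle at given spacing
voxel_centroid_oracle <- function(mesh, spacing = 0.5) {
  g <- grid_for_bbox(mesh_bbox(mesh), spacing = spacing, pad = 2)
  mask_centroid(voxelize(mesh, g))
}

# a random watertight blob: ellipsoid with random size/pose
random_blob <- function(seed, center_range = 15) {
  set.seed(seed)
  m <- make_primitive("ellipsoid", semiaxes = runif(3, 8, 20),
                      subdivisions = 2)
  m <- mesh_rotate(m, rot3("z", runif(1, 0, pi)))
  mesh_translate(m, runif(3, -center_range, center_range))
}

random_rotation <- function(seed) {
  set.seed(seed)
  rot3("z", runif(1, 0, 2 * pi)) %*% rot3("x", runif(1, 0, 2 * pi)) %*%
    rot3("y", runif(1, 0, 2 * pi))
}

# two-way ANOVA mean squares computed from scratch (sums, no lm)
anova_ms_oracle <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  gm <- mean(mat)
  rm <- rowMeans(mat); cm <- colMeans(mat)
  ssr <- k * sum((rm - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sse <- sum((mat - outer(rm, rep(1, k)) -
                outer(rep(1, n), cm) + gm)^2)
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

icc2_oracle <- function(mat) {
  ms <- anova_ms_oracle(mat)
  n <- nrow(mat); k <- ncol(mat)
  (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
}

# long-format cell values from a patients x observers matrix
cells_from_matrix <- function(mat, structure = "s1") {
  data.frame(structure = structure,
             patient = rep(sprintf("p%02d", seq_len(nrow(mat))), ncol(mat)),
             observer = rep(sprintf("o%d", seq_len(ncol(mat))),
                            each = nrow(mat)),
             value = as.vector(mat), stringsAsFactors = FALSE)
}
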