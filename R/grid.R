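#' Regular 3D grid specification
#'
#' Defines a regular voxel grid by the minimum corner of its extent, the
#' voxel spacing, and the voxel counts. Voxel `(i, j, k)` (1-based) has its
#' centre at `origin + (c(i, j, k) - 0.5) * spacing` and the grid extent is
#' `[origin, origin + spacing * shape]`.
#'
#' @param origin length-3 minimum corner, mm.
#' @param spacing length-3 (or scalar) positive voxel spacing, mm.
#' @param shape length-3 positive integer voxel counts.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin, spacing, shape) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(origin) != 3 || length(spacing) != 3 || length(shape) != 3)
    stop("origin, spacing, shape must have length 3")
  if (any(spacing <= 0)) stop("spacing must be positive")
  shape <- as.integer(shape)
  if (any(shape < 1)) stop("shape must be >= 1 in each axis")
  structure(list(origin = as.double(origin), spacing = as.double(spacing),
                 shape = shape),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Grid covering a bounding box
#'
#' Convenience constructor: a grid at the requested spacing whose extent
#' covers `bbox` expanded by `pad` on every side. The origin is snapped to a
#' multiple of the spacing so regridding the same region is reproducible.
#'
#' @param bbox list with `lo`, `hi` (length-3, mm), e.g. from [mesh_bbox()].
#' @param spacing voxel spacing in mm (scalar or length 3).
#' @param pad margin added around the box, mm.
#' @return A [grid_spec()].
#' @export
grid_for_bbox <- function(bbox, spacing = 1, pad = 0) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  lo <- floor((bbox$lo - pad) / spacing) * spacing
  hi <- ceiling((bbox$hi + pad) / spacing) * spacing
  grid_spec(lo, spacing, pmax(1, round((hi - lo) / spacing)))
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-9)) &&
    all(a$shape == b$shape)
}

#' Binary voxel mask
#'
#' @param grid a [grid_spec()].
#' @param values logical array matching `grid$shape`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(grid, values) {
  if (!inherits(grid, "grid_spec")) stop("grid must be a grid_spec")
  if (!is.logical(values)) storage.mode(values) <- "logical"
  if (is.null(dim(values)) || !all(dim(values) == grid$shape))
    stop("values shape does not match grid shape")
  structure(list(grid = grid, values = values), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %d of %d voxels set, volume %.3f cm^3\n",
              sum(x$values), length(x$values), mask_volume(x)))
  invisible(x)
}

#' Volume of a binary mask
#' @param mask a [binary_mask()].
#' @return Volume in cm^3 (voxel count times voxel volume).
#' @export
mask_volume <- function(mask) {
  sum(mask$values) * prod(mask$grid$spacing) / 1000
}

#' Centroid of a binary mask
#' @param mask a nonempty [binary_mask()].
#' @return Length-3 centroid of the set voxel centres, mm.
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask$values, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask has no centroid")
  g <- mask$grid
  unname(colMeans(sweep(sweep(idx - 0.5, 2, g$spacing, "*"),
                        2, g$origin, "+")))
}

#' Voxelize a watertight mesh onto a grid
#'
#' A voxel is inside iff its centre is inside the closed surface (parity of
#' ray crossings along z). Deterministic: rays carry a fixed sub-micrometre
#' offset so they cannot graze lattice-aligned mesh edges.
#'
#' @param mesh a watertight [tri_mesh()].
#' @param grid a [grid_spec()] whose extent contains the mesh.
#' @param clip if `TRUE`, the part of the mesh outside the grid is silently
#'   cut off instead of raising an error (used to bound valve volumes).
#' @return A [binary_mask()].
#' @export
voxelize <- function(mesh, grid, clip = FALSE) {
  mesh <- ensure_watertight(mesh)
  if (!clip) {
    bb <- mesh_bbox(mesh)
    hi <- grid$origin + grid$spacing * grid$shape
    for (d in 1:3) {
      if (bb$lo[d] < grid$origin[d] - 1e-9 || bb$hi[d] > hi[d] + 1e-9)
        stop(sprintf("mesh exceeds grid extent along %s axis",
                     c("x", "y", "z")[d]))
    }
  }
  vals <- cpp_voxelize(mesh$vertices, mesh$faces - 1L, grid$origin,
                       grid$spacing, grid$shape)
  binary_mask(grid, vals)
}

#' Volumes of two masks and their boolean combinations
#'
#' @param maskA,maskB [binary_mask()] objects on the identical grid.
#' @return Named list `volA`, `volB`, `volIntersection`, `volUnion` in cm^3;
#'   inclusion-exclusion (`volUnion = volA + volB - volIntersection`) holds
#'   exactly.
#' @export
boolean_volumes <- function(maskA, maskB) {
  if (!same_grid(maskA$grid, maskB$grid))
    stop("masks are on different grids; no silent resampling is performed")
  cnt <- cpp_pair_counts(maskA$values, maskB$values)
  vv <- prod(maskA$grid$spacing) / 1000
  volA <- cnt[1] * vv
  volB <- cnt[2] * vv
  volI <- cnt[3] * vv
  # computed from the rounded volumes so inclusion-exclusion is bitwise exact
  list(volA = volA, volB = volB, volIntersection = volI,
       volUnion = volA + volB - volI)
}

# squared Euclidean distance of every foreground voxel centre to the nearest
# background voxel centre (outside-of-grid counts as background)
mask_depth_sq <- function(mask) {
  cpp_edt_sq(mask$values, mask$grid$shape, mask$grid$spacing)
}

#' Morphological inner margin (erosion) by Euclidean distance
#'
#' Keeps the voxels whose Euclidean distance to the outside of the structure
#' exceeds `margin`.
#'
#' @param mask a [binary_mask()].
#' @param margin non-negative margin, mm.
#' @return A [binary_mask()]; empty (with a warning) when the margin exceeds
#'   the structure's inradius.
#' @export
inner_margin <- function(mask, margin) {
  if (margin < 0) stop("margin must be >= 0")
  if (margin == 0) return(mask)
  d2 <- mask_depth_sq(mask)
  out <- binary_mask(mask$grid, array(d2 > margin^2, dim = mask$grid$shape))
  if (sum(out$values) == 0 && sum(mask$values) > 0)
    warning(sprintf("inner margin of %g mm erased the structure", margin))
  out
}

#' Outer shell of a structure
#'
#' The set difference between a mask and its inner margin: `shell` and the
#' eroded core partition the input voxelwise.
#'
#' @param mask a [binary_mask()].
#' @param thickness positive shell thickness, mm.
#' @return A [binary_mask()].
#' @export
outer_shell <- function(mask, thickness) {
  if (thickness <= 0) stop("thickness must be > 0")
  core <- suppressWarnings(inner_margin(mask, thickness))
  binary_mask(mask$grid,
              array(mask$values & !core$values, dim = mask$grid$shape))
}

#' Voxel boundary surface of a mask as a triangle mesh
#'
#' Extracts the boundary faces between inside and outside voxels (cuberille
#' surface). The result is watertight, outward-oriented, and encloses exactly
#' the mask volume.
#'
#' @param mask a nonempty [binary_mask()].
#' @return A [tri_mesh()].
#' @export
mask_to_mesh <- function(mask) {
  if (sum(mask$values) == 0) stop("cannot mesh an empty mask")
  g <- mask$grid
  res <- cpp_mask_to_mesh(mask$values, g$shape, g$origin, g$spacing)
  m <- tri_mesh(res$vertices, res$faces, validate = FALSE)
  attr(m, "watertight") <- TRUE  # watertight by construction
  m
}

#' Surface sample points of a structure
#'
#' Centres of the boundary voxels of a mask, optionally thinned to roughly
#' one point per `thin` mm cell; used for surface-distance computations.
#'
#' @param mask a [binary_mask()].
#' @param thin target sample spacing in mm (`NULL` to keep all points).
#' @return Matrix of points (n x 3), mm.
#' @export
boundary_points <- function(mask, thin = NULL) {
  g <- mask$grid
  p <- cpp_boundary_points(mask$values, g$shape, g$origin, g$spacing)
  if (!is.null(thin)) p <- thin_points(p, thin)
  p
}

# deterministic spatial thinning: keep the first point in each cubic bin
thin_points <- function(points, spacing) {
  if (nrow(points) == 0) return(points)
  cell <- floor(sweep(points, 2, spacing, "/"))
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  points[!duplicated(key), , drop = FALSE]
}
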