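#' All unordered observer pairs
#'
#' @param observers vector of at least two distinct observer identifiers.
#' @return Data frame with columns `observer_a`, `observer_b`, one row per
#'   unordered pair, lexicographically ordered; `n * (n - 1) / 2` rows.
#' @export
observer_pairs <- function(observers) {
  observers <- sort(unique(as.character(observers)))
  if (length(observers) < 2)
    stop("need at least 2 distinct observers")
  idx <- utils::combn(length(observers), 2)
  data.frame(observer_a = observers[idx[1, ]],
             observer_b = observers[idx[2, ]],
             stringsAsFactors = FALSE)
}

#' Volume-overlap agreement between two contours
#'
#' Dice (twice the intersection volume over the sum of both volumes) and
#' Jaccard (intersection over union) coefficients, computed from voxel-based
#' boolean volumes on a common grid covering both meshes.
#'
#' @param meshA,meshB watertight [tri_mesh()] contours of the same structure.
#' @param spacing voxel spacing for the common grid, mm.
#' @return List with `dsc` and `jsc`, both in `[0, 1]`.
#' @export
overlap_metrics <- function(meshA, meshB, spacing = 1) {
  bbA <- mesh_bbox(meshA)
  bbB <- mesh_bbox(meshB)
  bb <- list(lo = pmin(bbA$lo, bbB$lo), hi = pmax(bbA$hi, bbB$hi))
  grid <- grid_for_bbox(bb, spacing = spacing, pad = 2 * max(spacing))
  v <- boolean_volumes(voxelize(meshA, grid), voxelize(meshB, grid))
  overlap_from_volumes(v)
}

overlap_from_volumes <- function(v) {
  if (v$volUnion == 0)
    stop("overlap metrics undefined: both structures are empty")
  list(dsc = 2 * v$volIntersection / (v$volA + v$volB),
       jsc = v$volIntersection / v$volUnion)
}

#' Distance-based agreement between two contours
#'
#' Centre-of-mass distance (DCOM, between the solid centroids), average
#' surface distance (ASD) and Hausdorff distance (HD). ASD and HD are based
#' on vertex-by-vertex Euclidean distances between the two meshes: with
#' `d(a -> B)` the distance from a vertex of A to the nearest vertex of B,
#' `asd = (mean_a d(a -> B) + mean_b d(b -> A)) / 2` and
#' `hd = max(max_a d(a -> B), max_b d(b -> A))`.
#'
#' Vertex-to-vertex distances are tessellation dependent, so by default both
#' vertex sets are thinned to roughly one point per `resample` mm before the
#' computation. `method = "surface"` measures to the closest point on the
#' other surface instead of the closest vertex.
#'
#' @param meshA,meshB watertight [tri_mesh()] contours.
#' @param resample spatial thinning pitch in mm (`NULL` to use all vertices).
#' @param method `"vertex"` (default, vertex-to-vertex) or `"surface"`
#'   (vertex-to-surface).
#' @param verbose also return the two directed means and maxima.
#' @return List with `dcom`, `asd`, `hd` (mm); in verbose mode additionally
#'   `asd_ab`, `asd_ba`, `hd_ab`, `hd_ba`.
#' @export
distance_metrics <- function(meshA, meshB, resample = 2,
                             method = c("vertex", "surface"),
                             verbose = FALSE) {
  method <- match.arg(method)
  if (nrow(meshA$vertices) == 0 || nrow(meshB$vertices) == 0)
    stop("empty vertex set")
  dcom <- sqrt(sum((center_of_mass(meshA) - center_of_mass(meshB))^2))
  pa <- meshA$vertices
  pb <- meshB$vertices
  if (!is.null(resample)) {
    pa <- thin_points(pa, resample)
    pb <- thin_points(pb, resample)
  }
  if (method == "vertex") {
    dists <- point_set_distances(pa, pb)
  } else {
    dists <- list(ab = cpp_point_mesh_dist(pa, meshB$vertices,
                                           meshB$faces - 1L),
                  ba = cpp_point_mesh_dist(pb, meshA$vertices,
                                           meshA$faces - 1L))
  }
  out <- list(dcom = dcom,
              asd = (mean(dists$ab) + mean(dists$ba)) / 2,
              hd = max(max(dists$ab), max(dists$ba)))
  if (verbose) {
    out$asd_ab <- mean(dists$ab)
    out$asd_ba <- mean(dists$ba)
    out$hd_ab <- max(dists$ab)
    out$hd_ba <- max(dists$ba)
  }
  out
}

# symmetric nearest-neighbour distances between two point sets
point_set_distances <- function(pa, pb) {
  cell <- max(2, stats::median(c(
    diff(range(pa[, 1])), diff(range(pb[, 1])))) / 20)
  list(ab = cpp_nn_dist(pa, pb, cell), ba = cpp_nn_dist(pb, pa, cell))
}

# all five pairwise metrics from two structure-set entries on a shared grid
pair_structure_metrics <- function(sa, sb, resample = 2) {
  if (is.null(sa) || is.null(sb))
    return(list(dsc = NA_real_, jsc = NA_real_, dcom = NA_real_,
                asd = NA_real_, hd = NA_real_))
  na <- sum(sa$mask$values)
  nb <- sum(sb$mask$values)
  if (na == 0 && nb == 0)
    return(list(dsc = NA_real_, jsc = NA_real_, dcom = NA_real_,
                asd = NA_real_, hd = NA_real_))
  v <- boolean_volumes(sa$mask, sb$mask)
  ov <- overlap_from_volumes(v)
  if (na == 0 || nb == 0)
    return(list(dsc = ov$dsc, jsc = ov$jsc, dcom = NA_real_,
                asd = NA_real_, hd = NA_real_))
  pa <- if (!is.null(sa$mesh)) thin_points(sa$mesh$vertices, resample)
        else boundary_points(sa$mask, thin = resample)
  pb <- if (!is.null(sb$mesh)) thin_points(sb$mesh$vertices, resample)
        else boundary_points(sb$mask, thin = resample)
  d <- point_set_distances(pa, pb)
  list(dsc = ov$dsc, jsc = ov$jsc,
       dcom = sqrt(sum((sa$centroid - sb$centroid)^2)),
       asd = (mean(d$ab) + mean(d$ba)) / 2,
       hd = max(max(d$ab), max(d$ba)))
}

#' Pairwise agreement records for one patient's structure sets
#'
#' Computes DSC, JSC, DCOM, ASD and HD for every structure and every
#' unordered observer pair of one patient. All structure sets must share one
#' grid. Structures that are empty for both observers of a pair yield
#' missing metrics (recorded, not imputed).
#'
#' @param sets list of [build_structure_set()] results for one patient (one
#'   per observer).
#' @param resample surface thinning pitch for distance metrics, mm.
#' @return Data frame with one row per (structure, observer pair).
#' @export
pairwise_agreement <- function(sets, resample = 2) {
  if (length(sets) < 2) stop("need at least 2 observers")
  obs <- vapply(sets, function(s) as.character(s$observer_id), character(1))
  names(sets) <- obs
  for (s in sets[-1])
    if (!same_grid(s$grid, sets[[1]]$grid))
      stop("structure sets are on different grids")
  pairs <- observer_pairs(obs)
  pid <- sets[[1]]$patient_id
  rows <- list()
  nms <- unique(unlist(lapply(sets, function(s) names(s$structures))))
  for (structure in nms) {
    for (r in seq_len(nrow(pairs))) {
      a <- pairs$observer_a[r]
      b <- pairs$observer_b[r]
      m <- pair_structure_metrics(sets[[a]]$structures[[structure]],
                                  sets[[b]]$structures[[structure]],
                                  resample = resample)
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = pid, structure = structure,
        observer_a = a, observer_b = b,
        dsc = m$dsc, jsc = m$jsc, dcom = m$dcom, asd = m$asd, hd = m$hd,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Aggregate pairwise agreement over observer pairs and patients
#'
#' Unweighted arithmetic mean of each metric per structure; missing values
#' (empty structures) are excluded and counted.
#'
#' @param records data frame as produced by [pairwise_agreement()].
#' @return Data frame with one row per structure: metric means, the number of
#'   records, and the number of records with missing metrics.
#' @export
aggregate_agreement <- function(records) {
  if (nrow(records) == 0) stop("no agreement records")
  metrics <- c("dsc", "jsc", "dcom", "asd", "hd")
  split_idx <- split(seq_len(nrow(records)), records$structure)
  # keep the canonical structure order where applicable
  ord <- c(intersect(atlas_structures(), names(split_idx)),
           setdiff(names(split_idx), atlas_structures()))
  out <- lapply(ord, function(s) {
    r <- records[split_idx[[s]], ]
    means <- vapply(metrics, function(m) mean(r[[m]], na.rm = TRUE),
                    numeric(1))
    cbind(data.frame(structure = s, stringsAsFactors = FALSE),
          as.data.frame(as.list(means)),
          data.frame(n_records = nrow(r),
                     n_missing = sum(!complete.cases(r[metrics]))))
  })
  do.call(rbind, out)
}
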