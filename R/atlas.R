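#' Heart landmarks
#'
#' The landmark points from which the valve surrogates are constructed: the
#' centre of the aortic root, a point within the truncus pulmonalis at the
#' level of the aortic root, and the left-right heart axis used to split the
#' anterior wall.
#'
#' @param aortic_root_center length-3 point, mm.
#' @param truncus_point length-3 point, mm; must differ from the root centre.
#' @param heart_axis_lr unit vector separating left from right anterior wall
#'   (default +x = patient-left).
#' @return An object of class `heart_landmarks`.
#' @export
heart_landmarks <- function(aortic_root_center, truncus_point,
                            heart_axis_lr = c(1, 0, 0)) {
  aortic_root_center <- as.double(aortic_root_center)
  truncus_point <- as.double(truncus_point)
  heart_axis_lr <- as.double(heart_axis_lr)
  if (length(aortic_root_center) != 3 || length(truncus_point) != 3 ||
      length(heart_axis_lr) != 3)
    stop("landmarks must be length-3 points")
  if (sqrt(sum((truncus_point - aortic_root_center)^2)) < 1e-9)
    stop("truncus_point must differ from aortic_root_center")
  n <- sqrt(sum(heart_axis_lr^2))
  if (n < 1e-12) stop("heart_axis_lr must be a nonzero vector")
  structure(list(aortic_root_center = aortic_root_center,
                 truncus_point = truncus_point,
                 heart_axis_lr = heart_axis_lr / n),
            class = "heart_landmarks")
}

#' Atlas construction parameters
#'
#' Tunable parameters of the surrogate-volume constructions. The cone
#' orientation and the base radius are only defined pictorially in the
#' underlying contouring protocol, so they are exposed as parameters.
#'
#' @param cone_base_radius aortic-valve cone base radius, mm.
#' @param cone_height aortic-valve cone axial extent, mm (caudal).
#' @param cone_orientation `"apex_down"` (base at the aortic root, apex
#'   caudal; default) or `"apex_up"`.
#' @param valve_gap clearance between the pulmonary-valve sphere and the
#'   aortic-valve surface ("almost touches"), mm.
#' @param myocardium_thickness outer-shell thickness, mm.
#' @param deep_margin symmetric inner margin for the deep structures, mm.
#' @param split_angle rotation (radians, about z) applied to the left-right
#'   axis before splitting the anterior wall; for sensitivity analyses.
#' @return A named list of class `atlas_params`.
#' @export
atlas_params <- function(cone_base_radius = 12, cone_height = 30,
                         cone_orientation = c("apex_down", "apex_up"),
                         valve_gap = 2, myocardium_thickness = 10,
                         deep_margin = 20, split_angle = 0) {
  cone_orientation <- match.arg(cone_orientation)
  stopifnot(cone_base_radius > 0, cone_height > 0, valve_gap >= 0,
            myocardium_thickness > 0, deep_margin >= 0)
  structure(list(cone_base_radius = cone_base_radius,
                 cone_height = cone_height,
                 cone_orientation = cone_orientation,
                 valve_gap = valve_gap,
                 myocardium_thickness = myocardium_thickness,
                 deep_margin = deep_margin,
                 split_angle = split_angle),
            class = "atlas_params")
}

#' Aortic valve surrogate: cone at the aortic root
#'
#' A conical volume starting at the aortic root and extending 3 cm in the
#' caudal (-z) direction. By default the base sits at the root and the apex
#' points caudally.
#'
#' @param landmarks a [heart_landmarks()].
#' @param base_radius cone base radius, mm.
#' @param height axial extent, mm.
#' @param orientation `"apex_down"` or `"apex_up"`.
#' @return A [tri_mesh()] whose z extent is
#'   `[root_z - height, root_z]`.
#' @export
build_aortic_valve <- function(landmarks, base_radius = 12, height = 30,
                               orientation = c("apex_down", "apex_up")) {
  orientation <- match.arg(orientation)
  if (base_radius <= 0) stop("base_radius must be positive")
  root <- landmarks$aortic_root_center
  if (orientation == "apex_down") {
    make_primitive("cone", base_radius = base_radius, height = height,
                   base_center = root, axis = c(0, 0, -1))
  } else {
    make_primitive("cone", base_radius = base_radius, height = height,
                   base_center = root - c(0, 0, height), axis = c(0, 0, 1))
  }
}

#' Pulmonary valve surrogate: sphere grown towards the aortic valve
#'
#' A spherical volume centred at the truncus pulmonalis landmark, expanded
#' uniformly until it almost touches the aortic-valve volume: its radius is
#' the distance from the centre to the aortic-valve surface minus `gap`.
#'
#' @param landmarks a [heart_landmarks()].
#' @param aortic_valve the aortic-valve [tri_mesh()].
#' @param gap clearance in mm ("almost touches").
#' @param subdivisions icosphere tessellation level.
#' @return A [tri_mesh()] sphere.
#' @export
build_pulmonary_valve <- function(landmarks, aortic_valve, gap = 2,
                                  subdivisions = 3) {
  ctr <- landmarks$truncus_point
  d <- cpp_point_mesh_dist(matrix(ctr, 1, 3), aortic_valve$vertices,
                           aortic_valve$faces - 1L)[1]
  radius <- d - gap
  if (radius <= 0 || point_in_mesh(ctr, aortic_valve))
    stop("truncus landmark inside/too close to the aortic valve ",
         sprintf("(surface distance %.2f mm, gap %.2f mm)", d, gap))
  make_primitive("sphere", radius = radius, center = ctr,
                 subdivisions = subdivisions)
}

#' Myocardium surrogate: 1 cm outer shell below the aortic valve
#'
#' The outer layer of the complete heart with the given thickness, restricted
#' to z below the aortic root plane (the caudal boundary of the valve's
#' cranial cap). The ventricular septum is excluded by construction since the
#' shell contains no interior voxels.
#'
#' @param heart complete-heart [binary_mask()].
#' @param landmarks a [heart_landmarks()] providing the root plane.
#' @param thickness shell thickness, mm.
#' @return A [binary_mask()].
#' @export
build_myocardium <- function(heart, landmarks, thickness = 10) {
  if (sum(heart$values) == 0) stop("heart mask is empty")
  shell <- outer_shell(heart, thickness)
  g <- heart$grid
  zc <- g$origin[3] + (seq_len(g$shape[3]) - 0.5) * g$spacing[3]
  below <- zc < landmarks$aortic_root_center[3]
  keep <- shell$values
  keep[, , !below] <- FALSE
  if (!any(keep)) stop("myocardium construction produced an empty structure")
  binary_mask(g, keep)
}

#' Split the anterior myocardium into left and right walls
#'
#' The anterior half-space (+y of the heart centroid) of the myocardium is
#' split by the sagittal plane through the centroid whose normal is the
#' left-right heart axis; the `left` output lies on the +axis (patient-left)
#' side.
#'
#' @param myocardium myocardium [binary_mask()].
#' @param landmarks a [heart_landmarks()].
#' @param center split point, mm; defaults to the centroid of `myocardium`
#'   (callers normally pass the heart centroid).
#' @param split_angle optional rotation of the axis about z, radians.
#' @return List with `left_anterior` and `right_anterior` masks; together
#'   they partition the anterior myocardium.
#' @export
split_anterior_walls <- function(myocardium, landmarks, center = NULL,
                                 split_angle = 0) {
  if (sum(myocardium$values) == 0) stop("myocardium mask is empty")
  if (is.null(center)) center <- mask_centroid(myocardium)
  axis <- landmarks$heart_axis_lr
  if (split_angle != 0) axis <- as.vector(rot3("z", split_angle) %*% axis)
  g <- myocardium$grid
  xc <- g$origin[1] + (seq_len(g$shape[1]) - 0.5) * g$spacing[1]
  yc <- g$origin[2] + (seq_len(g$shape[2]) - 0.5) * g$spacing[2]
  zc <- g$origin[3] + (seq_len(g$shape[3]) - 0.5) * g$spacing[3]
  # signed distance to the sagittal split plane, per voxel
  sx <- outer(outer((xc - center[1]) * axis[1], (yc - center[2]) * axis[2],
                    "+"), (zc - center[3]) * axis[3], "+")
  anterior <- array(rep(yc > center[2], each = g$shape[1]),
                    dim = g$shape) & myocardium$values
  if (!any(anterior)) stop("anterior myocardium region is empty")
  list(left_anterior = binary_mask(g, anterior & sx > 0),
       right_anterior = binary_mask(g, anterior & sx <= 0))
}

#' Deep structures surrogate: 2 cm inner margin
#'
#' A symmetric inner (negative) margin applied to the complete heart,
#' capturing the deep structures (atrioventricular node, bundle of His,
#' septum, mitral valve).
#'
#' @param heart complete-heart [binary_mask()].
#' @param margin inner margin, mm.
#' @return A [binary_mask()]; empty with a warning for very small hearts.
#' @export
build_deep_structures <- function(heart, margin = 20) {
  if (sum(heart$values) == 0) stop("heart mask is empty")
  inner_margin(heart, margin)
}

#' Build the full structure set for one (patient, observer) contour
#'
#' Voxelizes the complete-heart contour and constructs the six surrogate
#' substructures on a common analysis grid. Valve meshes may extend beyond
#' the heart (never clipped by it) but are bounded by the analysis grid.
#'
#' @param heart_mesh watertight complete-heart [tri_mesh()].
#' @param landmarks a [heart_landmarks()].
#' @param grid optional [grid_spec()]; defaults to the heart bounding box
#'   padded by `pad` at spacing `spacing`.
#' @param spacing analysis voxel spacing, mm (used when `grid` is `NULL`).
#' @param pad grid padding around the heart bounding box, mm.
#' @param params an [atlas_params()].
#' @param clip clip the heart contour to the grid instead of erroring when a
#'   perturbed contour grazes the grid boundary.
#' @param patient_id,observer_id identifiers carried into the result.
#' @return An object of class `structure_set`: fields `patient_id`,
#'   `observer_id`, `grid`, and `structures`, a named list over
#'   [atlas_structures()] with elements `mask`, `mesh` (`NULL` for
#'   mask-derived structures until requested), `volume` (cm^3) and
#'   `centroid` (mm); empty structures carry `NULL` centroids.
#' @export
build_structure_set <- function(heart_mesh, landmarks, grid = NULL,
                                spacing = 1, pad = 20,
                                params = atlas_params(), clip = FALSE,
                                patient_id = NA, observer_id = NA) {
  heart_mesh <- ensure_watertight(heart_mesh)
  if (is.null(grid))
    grid <- grid_for_bbox(mesh_bbox(heart_mesh), spacing = spacing, pad = pad)

  heart_mask <- voxelize(heart_mesh, grid, clip = clip)
  valve_a <- build_aortic_valve(landmarks, params$cone_base_radius,
                                params$cone_height, params$cone_orientation)
  valve_p <- build_pulmonary_valve(landmarks, valve_a, params$valve_gap)
  mask_a <- voxelize(valve_a, grid, clip = TRUE)
  mask_p <- voxelize(valve_p, grid, clip = TRUE)

  # one distance transform serves both the shell and the deep margin
  d2 <- mask_depth_sq(heart_mask)
  core10 <- binary_mask(grid, array(d2 > params$myocardium_thickness^2,
                                    dim = grid$shape))
  deep <- binary_mask(grid, array(d2 > params$deep_margin^2,
                                  dim = grid$shape))
  if (sum(deep$values) == 0)
    warning("deep structures empty (inner margin exceeds heart inradius)")
  shell <- binary_mask(grid, array(heart_mask$values & !core10$values,
                                   dim = grid$shape))
  g <- grid
  zc <- g$origin[3] + (seq_len(g$shape[3]) - 0.5) * g$spacing[3]
  myo_vals <- shell$values
  myo_vals[, , zc >= landmarks$aortic_root_center[3]] <- FALSE
  myo <- binary_mask(grid, myo_vals)
  if (sum(myo$values) == 0)
    stop("myocardium construction produced an empty structure")
  heart_ctr <- mask_centroid(heart_mask)
  walls <- split_anterior_walls(myo, landmarks, center = heart_ctr,
                                split_angle = params$split_angle)

  entry <- function(mask, mesh = NULL) {
    n <- sum(mask$values)
    list(mask = mask, mesh = mesh,
         volume = mask_volume(mask),
         centroid = if (n > 0) {
           if (!is.null(mesh)) center_of_mass(mesh) else mask_centroid(mask)
         } else NULL)
  }
  structures <- list(
    heart = entry(heart_mask, heart_mesh),
    aortic_valve = entry(mask_a, valve_a),
    pulmonary_valve = entry(mask_p, valve_p),
    myocardium = entry(myo),
    left_anterior_myocardium = entry(walls$left_anterior),
    right_anterior_myocardium = entry(walls$right_anterior),
    deep_structures = entry(deep))
  structure(list(patient_id = patient_id, observer_id = observer_id,
                 grid = grid, landmarks = landmarks, params = params,
                 structures = structures),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("structure_set (patient %s, observer %s)\n",
              x$patient_id, x$observer_id))
  for (nm in names(x$structures))
    cat(sprintf("  %-26s %8.2f cm^3\n", nm, x$structures[[nm]]$volume))
  invisible(x)
}

#' Extract a structure's surface mesh from a structure set
#'
#' Mesh-backed structures (heart, valves) return their original contour mesh;
#' mask-derived structures return the voxel boundary surface.
#'
#' @param set a [build_structure_set()] result.
#' @param name one of [atlas_structures()].
#' @return A [tri_mesh()].
#' @export
structure_mesh <- function(set, name) {
  s <- set$structures[[name]]
  if (is.null(s)) stop("unknown structure: ", name)
  if (!is.null(s$mesh)) return(s$mesh)
  mask_to_mesh(s$mask)
}
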