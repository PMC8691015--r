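#' Synthetic cohort configuration
#'
#' Study-design parameters of the synthetic multi-observer cohort. Defaults
#' mirror the validation study design: 16 patients contoured by 6 observers,
#' CT slice thickness 10 mm (3 patients), 7.5 mm (4), 5 mm (1) and 3 mm (8),
#' heart volumes around 700 cm^3, and one pair of tangential fields with a
#' 50 Gy prescription whose border crosses the anterior-left heart.
#'
#' @param n_patients,n_observers design size.
#' @param slice_thickness_mix slice thickness per patient, mm; recycled to
#'   `n_patients` when the lengths differ.
#' @param heart_volume_range uniform range of true heart volumes, cm^3.
#' @param observer_sd scale of the smooth random radial contour displacement
#'   applied per observer, mm.
#' @param landmark_sd per-axis SD of the valve landmark jitter, mm.
#' @param landmark_rho fraction of the landmark jitter variance shared
#'   between the aortic-root and truncus landmarks (both are read off the
#'   same image region, so their errors are correlated); marginal jitter per
#'   landmark stays N(0, landmark_sd^2) per axis.
#' @param valve_scale_sd log-scale SD of the per-observer aortic-valve cone
#'   radius (the valve's extent is judged from poorly visible anatomy, so
#'   observers disagree about its size as well as its position).
#' @param patient_shape_sd scale of the patient-level shape perturbation, mm.
#' @param analysis_spacing isotropic voxel spacing of the agreement analysis
#'   grid, mm.
#' @param resample surface thinning pitch for distance metrics, mm.
#' @param dose a [dose_config()].
#' @param atlas an [atlas_params()]; the generator default widens the
#'   aortic-valve cone to a 20 mm base radius so the mean valve volumes
#'   (~13 cm^3 aortic, ~7 cm^3 pulmonary) match clinical magnitudes, the
#'   aortic valve being the larger of the two.
#' @param master_seed master seed; every random substream is derived from it
#'   by (patient, observer, purpose) counters.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 16, n_observers = 6,
                          slice_thickness_mix = c(rep(10, 3), rep(7.5, 4),
                                                  5, rep(3, 8)),
                          heart_volume_range = c(550, 850),
                          observer_sd = 2.5, landmark_sd = 6,
                          landmark_rho = 0.7, valve_scale_sd = 0.1,
                          patient_shape_sd = 3, analysis_spacing = 1,
                          resample = 2, dose = dose_config(),
                          atlas = atlas_params(cone_base_radius = 20),
                          master_seed = 20210) {
  stopifnot(n_patients >= 1, n_observers >= 1,
            all(slice_thickness_mix > 0),
            length(heart_volume_range) == 2,
            all(heart_volume_range > 0),
            observer_sd > 0, landmark_sd >= 0,
            landmark_rho >= 0, landmark_rho <= 1, valve_scale_sd >= 0,
            patient_shape_sd >= 0,
            analysis_spacing > 0, master_seed == floor(master_seed))
  structure(list(
    n_patients = as.integer(n_patients),
    n_observers = as.integer(n_observers),
    slice_thickness_mix = rep_len(slice_thickness_mix, n_patients),
    heart_volume_range = heart_volume_range,
    observer_sd = observer_sd, landmark_sd = landmark_sd,
    landmark_rho = landmark_rho, valve_scale_sd = valve_scale_sd,
    patient_shape_sd = patient_shape_sd,
    analysis_spacing = analysis_spacing, resample = resample,
    dose = dose, atlas = atlas,
    master_seed = as.double(master_seed)), class = "cohort_config")
}

#' Synthetic dose model configuration
#'
#' Parameters of the tangential-field dose surrogate: a sigmoid penumbra
#' across a field-edge plane clipping the anterior-left heart, plus a
#' decaying near-field scatter term over a small out-of-field dose floor.
#'
#' @param prescription_gy dose on the in-field plateau, Gy.
#' @param penumbra_mm sigmoid penumbra scale, mm.
#' @param base_gy out-of-field dose floor, Gy.
#' @param scatter_gy near-field scatter amplitude at the field edge, Gy.
#' @param scatter_decay_mm exponential decay length of the scatter tail, mm.
#' @param field_angle_deg in-plane angle of the field-edge plane normal,
#'   degrees from the anterior (+y) axis towards patient-left (+x).
#' @param target_v5gy fraction of the true heart volume receiving at least
#'   5 Gy; the plane offset is placed by bisection to hit this value. A
#'   length-2 range draws one target per patient (plans differ in how close
#'   the tangential border runs to the heart); a scalar fixes it.
#' @param grid_spacing dose grid spacing, mm.
#' @param grid_pad dose grid margin around the heart, mm.
#' @return A list of class `dose_config`.
#' @export
dose_config <- function(prescription_gy = 50, penumbra_mm = 4,
                        base_gy = 0.3, scatter_gy = 2,
                        scatter_decay_mm = 25, field_angle_deg = 35,
                        target_v5gy = c(0.04, 0.22), grid_spacing = 2.5,
                        grid_pad = 30) {
  stopifnot(prescription_gy > 0, penumbra_mm > 0, base_gy >= 0,
            scatter_gy >= 0, scatter_decay_mm > 0,
            length(target_v5gy) %in% 1:2,
            all(target_v5gy > 0), all(target_v5gy < 1), grid_spacing > 0)
  structure(list(prescription_gy = prescription_gy,
                 penumbra_mm = penumbra_mm, base_gy = base_gy,
                 scatter_gy = scatter_gy,
                 scatter_decay_mm = scatter_decay_mm,
                 field_angle_deg = field_angle_deg,
                 target_v5gy = target_v5gy, grid_spacing = grid_spacing,
                 grid_pad = grid_pad), class = "dose_config")
}

#' Deterministic substream seed
#'
#' Derives the seed of an entity's random substream from the master seed and
#' (patient, observer, purpose) counters, so cohorts are reproducible under
#' partial regeneration. Arithmetic is exact in doubles and the result stays
#' below 2^31.
#'
#' @param master master seed (integer-valued).
#' @param patient,observer,purpose non-negative counters.
#' @return An integer-valued seed.
#' @export
substream_seed <- function(master, patient = 0, observer = 0, purpose = 0) {
  (master * 1000003 + patient * 10007 + observer * 101 + purpose * 7919) %%
    2147483629 + 1
}

# orthonormal real spherical harmonics up to degree L at unit directions;
# the squared basis values sum to (L + 1)^2 / (4 pi) at every point, so
# i.i.d. N(0, sd^2 * 4 pi / (L + 1)^2) coefficients give a smooth random
# field with pointwise standard deviation exactly sd
sh_basis <- function(dirs, L = 4) {
  ct <- pmin(pmax(dirs[, 3], -1), 1)
  phi <- atan2(dirs[, 2], dirs[, 1])
  n <- nrow(dirs)
  out <- matrix(0, n, (L + 1)^2)
  col <- 1
  for (l in 0:L) {
    P <- if (l == 0) matrix(1, 1, n) else pracma::legendre(l, ct)
    for (m in 0:l) {
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      if (m == 0) {
        out[, col] <- nrm * P[1, ]
        col <- col + 1
      } else {
        out[, col] <- sqrt(2) * nrm * P[m + 1, ] * cos(m * phi)
        out[, col + 1] <- sqrt(2) * nrm * P[m + 1, ] * sin(m * phi)
        col <- col + 2
      }
    }
  }
  out
}

# smooth zero-mean random radial displacement with pointwise SD = sd (mm)
random_radial_field <- function(dirs, sd, L = 4) {
  basis <- sh_basis(dirs, L)
  coef <- rnorm((L + 1)^2, 0, sd * sqrt(4 * pi) / (L + 1))
  as.vector(basis %*% coef)
}

#' Generate one synthetic true heart
#'
#' A smooth closed mesh: an ellipsoid (longest axis cranio-caudal) with a
#' mild low-order spherical-harmonic shape perturbation, rescaled so the
#' enclosed volume equals a draw from the configured volume range. Landmarks
#' are placed near the cranial pole (aortic root) and offset anterior-left at
#' the root level (truncus pulmonalis).
#'
#' @param patient_seed integer substream seed.
#' @param config a [cohort_config()].
#' @return List with `mesh` (a [tri_mesh()]), `landmarks`
#'   (a [heart_landmarks()]) and `volume` (cm^3).
#' @export
generate_heart <- function(patient_seed, config = cohort_config()) {
  set.seed(patient_seed)
  target <- runif(1, config$heart_volume_range[1],
                  config$heart_volume_range[2])
  ratios <- c(0.95, 1.0, 1.15) * exp(rnorm(3, 0, 0.06))
  r0 <- (target * 1000 * 3 / (4 * pi * prod(ratios)))^(1 / 3)
  s <- unit_icosphere(3)
  v <- sweep(s$vertices, 2, r0 * ratios, "*")
  if (config$patient_shape_sd > 0) {
    f <- random_radial_field(s$vertices, config$patient_shape_sd, L = 3)
    r <- sqrt(rowSums(v^2))
    v <- v * (r + f) / r
  }
  mesh <- tri_mesh(v, s$faces)
  mesh$vertices <- mesh$vertices * (target / mesh_volume(mesh))^(1 / 3)
  ctr <- center_of_mass(mesh)
  z_top <- max(mesh$vertices[, 3])
  root <- ctr + c(-5, -5, 0.72 * (z_top - ctr[3]))
  truncus <- root + c(24, 24, 0)  # 34 mm anterior-left, at the root level
  list(mesh = mesh,
       landmarks = heart_landmarks(root, truncus, c(1, 0, 0)),
       volume = mesh_volume(mesh))
}

# one observer's perturbed contour + jittered landmarks.
# (i)  smooth random radial displacement (spherical harmonics up to L = 4);
# (ii) cranio-caudal extent shifted ~ N(0, (slice/2)^2) and snapped to slice
#      planes, emulating the slice-thickness quantization of manual contours;
# (iii) landmark jitter ~ N(0, landmark_sd^2) per axis.
perturb_contour <- function(truth, observer_seed, slice_thickness,
                            config = cohort_config()) {
  for (attempt in 1:5) {
    set.seed(substream_seed(observer_seed, purpose = attempt - 1))
    mesh <- truth$mesh
    ctr <- center_of_mass(mesh)
    rel <- sweep(mesh$vertices, 2, ctr)
    r <- sqrt(rowSums(rel^2))
    dirs <- rel / r
    f <- random_radial_field(dirs, config$observer_sd, L = 4)
    newr <- r + f
    if (any(newr < 0.3 * stats::median(r))) {
      message("contour perturbation collapsed; resampling (attempt ",
              attempt, ")")
      next
    }
    v <- sweep(dirs * newr, 2, ctr, "+")
    # cranio-caudal extent shift + quantization to slice planes
    t <- slice_thickness
    z0 <- min(v[, 3]); z1 <- max(v[, 3])
    z1q <- round((z1 + rnorm(1, 0, t / 2)) / t) * t
    z0q <- round((z0 + rnorm(1, 0, t / 2)) / t) * t
    if (z1q - z0q < 0.5 * (z1 - z0)) {
      message("slice quantization collapsed the contour; resampling")
      next
    }
    v[, 3] <- z0q + (v[, 3] - z0) / (z1 - z0) * (z1q - z0q)
    mesh <- tri_mesh(v, truth$mesh$faces, validate = FALSE)
    attr(mesh, "watertight") <- TRUE  # radial map preserves topology
    lm <- truth$landmarks
    # correlated landmark errors: a shared image-reading component plus an
    # independent per-landmark part; marginals are N(0, landmark_sd^2)
    shared <- rnorm(3, 0, sqrt(config$landmark_rho) * config$landmark_sd)
    ind_sd <- sqrt(1 - config$landmark_rho) * config$landmark_sd
    root <- lm$aortic_root_center + shared + rnorm(3, 0, ind_sd)
    truncus <- lm$truncus_point + shared + rnorm(3, 0, ind_sd)
    params <- config$atlas
    params$cone_base_radius <- params$cone_base_radius *
      exp(rnorm(1, 0, config$valve_scale_sd))
    out <- tryCatch({
      lmk <- heart_landmarks(root, truncus, lm$heart_axis_lr)
      # feasibility: the pulmonary sphere must have a usable radius
      va <- build_aortic_valve(lmk, params$cone_base_radius,
                               params$cone_height, params$cone_orientation)
      build_pulmonary_valve(lmk, va, params$valve_gap)
      list(mesh = mesh, landmarks = lmk, params = params)
    }, error = function(e) NULL)
    if (!is.null(out)) return(out)
    message("observer landmarks infeasible; resampling (attempt ",
            attempt, ")")
  }
  stop("could not generate a valid observer contour in 5 attempts")
}

#' Simulate one observer's structure set
#'
#' Applies the observer model (smooth radial contour displacement,
#' cranio-caudal slice quantization, landmark jitter) to a true heart and
#' builds the full atlas structure set from the perturbed contour. Attempts
#' that produce invalid geometry (e.g. a collapsed contour or a truncus
#' landmark swallowed by the aortic valve) are resampled from the next
#' substream, up to 5 times.
#'
#' @param truth a [generate_heart()] result.
#' @param observer_seed integer substream seed.
#' @param slice_thickness CT slice thickness for this patient, mm.
#' @param config a [cohort_config()].
#' @param grid optional shared [grid_spec()]; defaults to a grid around the
#'   true heart padded generously for the perturbations.
#' @param patient_id,observer_id identifiers carried through.
#' @return A [build_structure_set()] result.
#' @export
simulate_observer <- function(truth, observer_seed, slice_thickness,
                              config = cohort_config(), grid = NULL,
                              patient_id = NA, observer_id = NA) {
  pc <- perturb_contour(truth, observer_seed, slice_thickness, config)
  if (is.null(grid)) grid <- cohort_grid(truth, config)
  build_structure_set(pc$mesh, pc$landmarks, grid = grid,
                      params = pc$params, clip = TRUE,
                      patient_id = patient_id, observer_id = observer_id)
}

# shared per-patient analysis grid, padded for perturbation + quantization
cohort_grid <- function(truth, config, spacing = NULL) {
  if (is.null(spacing)) spacing <- config$analysis_spacing
  pad <- 3 * config$observer_sd + max(config$slice_thickness_mix) + 6
  grid_for_bbox(mesh_bbox(truth$mesh), spacing = spacing, pad = pad)
}

#' Simulate a tangential-field dose distribution
#'
#' Builds a patient dose grid covering the heart plus a margin and fills it
#' with `dose(x) = base + (Rx - base) * sigmoid(s(x) / w) +
#' scatter * (1 - sigmoid(s(x) / w)) * exp(-max(-s(x), 0) / decay)` where
#' `s(x)` is the signed distance to a field-edge plane. The plane offset is
#' placed by bisection so the true heart's V5GY equals the configured target,
#' emulating a field border crossing the anterior-left heart.
#'
#' @param truth a [generate_heart()] result.
#' @param config a [cohort_config()] (its `dose` component is used).
#' @param target_v5gy optional scalar overriding the configured target (the
#'   cohort machinery passes the per-patient draw here).
#' @return A [dose_grid()] with attributes `plane_normal` and
#'   `plane_offset`.
#' @export
simulate_dose <- function(truth, config = cohort_config(),
                          target_v5gy = NULL) {
  dc <- config$dose
  if (!is.null(target_v5gy)) dc$target_v5gy <- target_v5gy
  dc$target_v5gy <- mean(dc$target_v5gy)  # midpoint when given a range
  grid <- grid_for_bbox(mesh_bbox(truth$mesh), spacing = dc$grid_spacing,
                        pad = dc$grid_pad)
  heart <- voxelize(truth$mesh, grid)
  ang <- dc$field_angle_deg * pi / 180
  u <- c(sin(ang), cos(ang), 0)
  # signed-plane coordinate of every voxel centre
  g <- grid
  xc <- g$origin[1] + (seq_len(g$shape[1]) - 0.5) * g$spacing[1]
  yc <- g$origin[2] + (seq_len(g$shape[2]) - 0.5) * g$spacing[2]
  proj <- outer(outer(xc * u[1], yc * u[2], "+"),
                rep(0, g$shape[3]), "+")  # u has no z component
  dose_at <- function(s) {
    sig <- plogis(s / dc$penumbra_mm)
    dc$base_gy + (dc$prescription_gy - dc$base_gy) * sig +
      dc$scatter_gy * (1 - sig) * exp(-pmax(-s, 0) / dc$scatter_decay_mm)
  }
  hproj <- proj[heart$values]
  if (length(hproj) == 0) {
    warning("field plane placement: heart mask is empty on the dose grid")
    offset <- 0
  } else {
    frac_hot <- function(offset) mean(dose_at(hproj - offset) >= 5)
    lo <- min(hproj) - 20
    hi <- max(hproj) + 20
    for (i in 1:60) {  # frac_hot is non-increasing in the offset
      mid <- (lo + hi) / 2
      if (frac_hot(mid) > dc$target_v5gy) lo <- mid else hi <- mid
    }
    offset <- (lo + hi) / 2
    if (frac_hot(offset) == 0 || frac_hot(offset) == 1)
      warning("field-edge plane does not cross the heart")
  }
  dg <- dose_grid(grid, array(dose_at(proj - offset), dim = g$shape))
  attr(dg, "plane_normal") <- u
  attr(dg, "plane_offset") <- offset
  dg
}

# assemble one patient: truth anatomy, slice thickness, dose, analysis grid
make_patient <- function(config, i) {
  truth <- generate_heart(substream_seed(config$master_seed, i, 0, 1),
                          config)
  tv <- config$dose$target_v5gy
  if (length(tv) == 2) {
    set.seed(substream_seed(config$master_seed, i, 0, 3))
    tv <- runif(1, tv[1], tv[2])
  }
  list(id = sprintf("p%02d", i), truth = truth,
       slice = config$slice_thickness_mix[i],
       dose_target = tv,
       grid = cohort_grid(truth, config))
}

make_observer_pc <- function(config, patient, j) {
  perturb_contour(patient$truth,
                  substream_seed(config$master_seed, patient$index, j, 2),
                  patient$slice, config)
}

#' Generate a synthetic cohort on disk
#'
#' Writes, per patient, the true heart mesh (PLY), landmarks (JSON) and dose
#' grid (ASCII NRRD), and per (patient, observer) the seven structure meshes
#' and jittered landmarks, plus a `manifest.json` describing the tree. The
#' output is fully determined by `config$master_seed` (per-entity substreams
#' are derived by counters, not execution order).
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return The manifest, invisibly.
#' @export
generate_cohort <- function(config = cohort_config(), out_dir,
                            force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop("output directory exists and is not empty (use force = TRUE): ",
         out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(n_patients = config$n_patients,
                   n_observers = config$n_observers,
                   structures = atlas_structures(),
                   master_seed = config$master_seed,
                   patients = list())
  for (i in seq_len(config$n_patients)) {
    pat <- make_patient(config, i)
    pat$index <- i
    pdir <- file.path(out_dir, pat$id)
    dir.create(pdir, showWarnings = FALSE)
    write_ply(pat$truth$mesh, file.path(pdir, "truth.ply"))
    write_landmarks(pat$truth$landmarks, file.path(pdir, "landmarks.json"))
    dose <- simulate_dose(pat$truth, config, target_v5gy = pat$dose_target)
    write_nrrd(dose, file.path(pdir, "dose.nrrd"))
    observers <- list()
    for (j in seq_len(config$n_observers)) {
      odir <- file.path(pdir, sprintf("o%d", j))
      dir.create(odir, showWarnings = FALSE)
      pc <- make_observer_pc(config, pat, j)
      set <- build_structure_set(pc$mesh, pc$landmarks, grid = pat$grid,
                                 params = pc$params, clip = TRUE,
                                 patient_id = pat$id,
                                 observer_id = sprintf("o%d", j))
      write_landmarks(pc$landmarks, file.path(odir, "landmarks.json"))
      files <- list()
      for (nm in atlas_structures()) {
        f <- file.path(odir, paste0(nm, ".ply"))
        write_ply(structure_mesh(set, nm), f)
        files[[nm]] <- file.path(pat$id, sprintf("o%d", j),
                                 paste0(nm, ".ply"))
      }
      observers[[sprintf("o%d", j)]] <- files
    }
    manifest$patients[[pat$id]] <- list(
      truth = file.path(pat$id, "truth.ply"),
      landmarks = file.path(pat$id, "landmarks.json"),
      dose = file.path(pat$id, "dose.nrrd"),
      slice_thickness = pat$slice,
      observers = observers)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
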