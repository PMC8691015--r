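#' Run the full synthetic analysis pipeline in memory
#'
#' Generates the synthetic cohort patient by patient, builds every observer's
#' structure set, computes pairwise spatial agreement on the shared analysis
#' grid, rebuilds the structures on the patient dose grid to compute DMEAN,
#' D2CC and V5GY, and summarises everything in a per-structure variability
#' table. No intermediate data touch the disk unless `out_dir` is given.
#'
#' @param config a [cohort_config()].
#' @param out_dir optional directory for the CSV/JSON reports.
#' @param B bootstrap replicates for the beta-model SD interval.
#' @param verbose print per-patient progress.
#' @return List with `agreement` (one row per patient, structure, observer
#'   pair), `agreement_summary` (per structure), `dose_metrics` (one row per
#'   patient, observer, structure), `values` (long per-quantity cell values),
#'   `variability` (a [variability_report()]), and `config`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL, B = 1000,
                         verbose = FALSE) {
  agreement <- list()
  dose_rows <- list()
  vol_rows <- list()
  for (i in seq_len(config$n_patients)) {
    t0 <- Sys.time()
    pat <- make_patient(config, i)
    pat$index <- i
    dose <- simulate_dose(pat$truth, config, target_v5gy = pat$dose_target)
    sets <- list()
    for (j in seq_len(config$n_observers)) {
      oid <- sprintf("o%d", j)
      pc <- make_observer_pc(config, pat, j)
      sets[[oid]] <- build_structure_set(
        pc$mesh, pc$landmarks, grid = pat$grid, params = pc$params,
        clip = TRUE, patient_id = pat$id, observer_id = oid)
      dset <- build_structure_set(
        pc$mesh, pc$landmarks, grid = dose$grid, params = pc$params,
        clip = TRUE, patient_id = pat$id, observer_id = oid)
      for (nm in atlas_structures()) {
        s <- dset$structures[[nm]]
        vol_rows[[length(vol_rows) + 1]] <- data.frame(
          structure = nm, patient = pat$id, observer = oid,
          value = sets[[oid]]$structures[[nm]]$volume,
          stringsAsFactors = FALSE)
        if (sum(s$mask$values) == 0) {
          dose_rows[[length(dose_rows) + 1]] <- data.frame(
            patient = pat$id, observer = oid, structure = nm,
            dmean = NA_real_, d2cc = NA_real_, v5gy = NA_real_,
            flag = "empty", stringsAsFactors = FALSE)
        } else {
          m <- dose_metrics(dose, s$mask)
          dose_rows[[length(dose_rows) + 1]] <- data.frame(
            patient = pat$id, observer = oid, structure = nm,
            dmean = m$dmean, d2cc = m$d2cc, v5gy = m$v5gy,
            flag = ifelse(is.na(m$flag), "", m$flag),
            stringsAsFactors = FALSE)
        }
      }
    }
    agreement[[i]] <- pairwise_agreement(sets, resample = config$resample)
    if (verbose)
      message(sprintf("patient %s done in %.1f s", pat$id,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  agreement <- do.call(rbind, agreement)
  dose_df <- do.call(rbind, dose_rows)
  volumes <- do.call(rbind, vol_rows)

  cells <- function(col) {
    d <- data.frame(structure = dose_df$structure, patient = dose_df$patient,
                    observer = dose_df$observer, value = dose_df[[col]],
                    stringsAsFactors = FALSE)
    d[!is.na(d$value), ]
  }
  vol_cells <- volumes[volumes$value > 0, ]
  variability <- variability_report(vol_cells, cells("dmean"),
                                    cells("d2cc"), cells("v5gy"),
                                    B = B, seed = config$master_seed)
  out <- list(agreement = agreement,
              agreement_summary = aggregate_agreement(agreement),
              dose_metrics = dose_df,
              values = list(volumes = volumes),
              variability = variability,
              config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$agreement, file.path(out_dir, "agreement_records.csv"),
            row.names = FALSE)
  write.csv(result$agreement_summary,
            file.path(out_dir, "agreement_summary.csv"), row.names = FALSE)
  write.csv(result$dose_metrics, file.path(out_dir, "dose_metrics.csv"),
            row.names = FALSE)
  write.csv(result$values$volumes, file.path(out_dir, "volumes.csv"),
            row.names = FALSE)
  write.csv(result$variability, file.path(out_dir, "variability.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(n_patients = result$config$n_patients,
         n_observers = result$config$n_observers,
         master_seed = result$config$master_seed,
         n_agreement_records = nrow(result$agreement),
         n_dose_records = nrow(result$dose_metrics),
         flags = result$variability$flags[result$variability$flags != ""]),
    file.path(out_dir, "run_summary.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Interobserver CV of the true heart volume for a given contour noise
#'
#' Cheap closed-loop evaluation used to calibrate the generator: perturbs
#' every (patient, observer) contour exactly as the full pipeline does, but
#' measures heart volumes directly on the meshes (no voxelization) and
#' returns the log-normal model CV in percent.
#'
#' @param config a [cohort_config()].
#' @return CV of the heart volume, percent.
#' @export
heart_volume_cv <- function(config = cohort_config()) {
  rows <- list()
  for (i in seq_len(config$n_patients)) {
    pat <- make_patient(config, i)
    pat$index <- i
    for (j in seq_len(config$n_observers)) {
      pc <- make_observer_pc(config, pat, j)
      rows[[length(rows) + 1]] <- data.frame(
        structure = "heart", patient = pat$id, observer = sprintf("o%d", j),
        value = mesh_volume(pc$mesh), stringsAsFactors = FALSE)
    }
  }
  100 * lognormal_cv(do.call(rbind, rows))$estimate
}

#' Calibrate the observer noise to a target heart-volume CV
#'
#' Bisection on `observer_sd` (the smooth radial contour displacement scale)
#' so the recovered interobserver heart-volume CV matches the target. Used
#' for the dial-a-truth closed loop: any target CV in roughly 2-15% is
#' attainable within the search interval.
#'
#' Note that the slice-plane quantization of the observer model sets a floor
#' on the attainable CV (about 5% under the default slice-thickness mix, of
#' the same order as clinical heart-contouring variability); targets below
#' the floor resolve to the nearest attainable CV when it lies within
#' `slack` percentage points, and error otherwise.
#'
#' @param target_cv target CV in percent.
#' @param config a [cohort_config()]; its `observer_sd` is replaced.
#' @param interval search interval for `observer_sd`, mm.
#' @param tol stop when the recovered CV is within `tol` percentage points.
#' @param slack accept an endpoint solution whose CV is within `slack`
#'   percentage points of an out-of-range target.
#' @param max_iter maximum bisection steps.
#' @return The calibrated config, with attributes `observer_sd` and
#'   `achieved_cv`.
#' @export
tune_observer_sd <- function(target_cv, config = cohort_config(),
                             interval = c(0.3, 10), tol = 0.25,
                             slack = 1.5, max_iter = 20) {
  eval_cv <- function(sd) {
    config$observer_sd <- sd
    heart_volume_cv(config)
  }
  lo <- interval[1]
  hi <- interval[2]
  flo <- eval_cv(lo)
  fhi <- eval_cv(hi)
  done <- function(sd, cv) {
    config$observer_sd <- sd
    attr(config, "observer_sd") <- sd
    attr(config, "achieved_cv") <- cv
    config
  }
  if (target_cv <= flo) {
    if (flo - target_cv <= slack) return(done(lo, flo))
    stop(sprintf(
      "target CV %.2f%% below the attainable floor %.2f%% (slice quantization)",
      target_cv, flo))
  }
  if (target_cv >= fhi) {
    if (target_cv - fhi <= slack) return(done(hi, fhi))
    stop(sprintf("target CV %.2f%% above the attainable range (max %.2f%%)",
                 target_cv, fhi))
  }
  mid <- (lo + hi) / 2
  cv <- NA
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    cv <- eval_cv(mid)
    if (abs(cv - target_cv) <= tol) break
    if (cv < target_cv) lo <- mid else hi <- mid
  }
  done(mid, cv)
}

# ---------------------------------------------------------------------------
# Disk-based pipeline stages (CLI surface): operate on a generated dataset
# tree, so they also apply to externally supplied mesh/dose data following
# the same manifest layout.
# ---------------------------------------------------------------------------

#' Load a cohort dataset written by [generate_cohort()]
#'
#' @param dataset_dir directory containing `manifest.json`.
#' @return List with the manifest and the resolved directory.
#' @export
load_cohort <- function(dataset_dir) {
  mf <- file.path(dataset_dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dataset_dir)
  list(manifest = jsonlite::read_json(mf, simplifyVector = FALSE),
       dir = dataset_dir)
}

# build per-observer structure entries from mesh files on a shared grid
observer_entries_from_files <- function(dir, files, grid) {
  entries <- list()
  for (nm in names(files)) {
    mesh <- read_ply(file.path(dir, files[[nm]]))
    mask <- voxelize(mesh, grid, clip = TRUE)
    n <- sum(mask$values)
    entries[[nm]] <- list(mask = mask, mesh = mesh,
                          volume = mask_volume(mask),
                          centroid = if (n > 0) center_of_mass(mesh) else NULL)
  }
  entries
}

#' Pairwise agreement for a dataset on disk
#'
#' Reads every observer's structure meshes, voxelizes them on a shared
#' per-patient grid, and writes per-record and per-structure agreement CSVs.
#' Missing mesh files are reported and skipped; the run continues.
#'
#' @param dataset_dir dataset directory (see [generate_cohort()]).
#' @param out_dir output directory for CSVs (`NULL` to skip writing).
#' @param spacing analysis grid spacing, mm.
#' @param resample surface thinning pitch, mm.
#' @return List with `records`, `summary` and `skipped` (character vector of
#'   missing files).
#' @export
cohort_agreement <- function(dataset_dir, out_dir = NULL, spacing = 1,
                             resample = 2) {
  co <- load_cohort(dataset_dir)
  skipped <- character()
  all_records <- list()
  for (pid in names(co$manifest$patients)) {
    pat <- co$manifest$patients[[pid]]
    # shared grid covering every observer's heart
    lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
    meshes <- list()
    for (oid in names(pat$observers)) {
      f <- file.path(co$dir, pat$observers[[oid]][["heart"]])
      if (!file.exists(f)) { skipped <- c(skipped, f); next }
      m <- read_ply(f)
      bb <- mesh_bbox(m)
      lo <- pmin(lo, bb$lo); hi <- pmax(hi, bb$hi)
      meshes[[oid]] <- m
    }
    if (length(meshes) < 2) next
    grid <- grid_for_bbox(list(lo = lo, hi = hi), spacing = spacing, pad = 5)
    sets <- list()
    for (oid in names(pat$observers)) {
      files <- pat$observers[[oid]]
      ok <- vapply(files, function(f) file.exists(file.path(co$dir, f)),
                   logical(1))
      skipped <- c(skipped, unlist(files[!ok], use.names = FALSE))
      sets[[oid]] <- structure(list(
        patient_id = pid, observer_id = oid, grid = grid,
        structures = observer_entries_from_files(co$dir, files[ok], grid)),
        class = "structure_set")
    }
    all_records[[pid]] <- pairwise_agreement(sets, resample = resample)
  }
  records <- do.call(rbind, all_records)
  rownames(records) <- NULL
  out <- list(records = records, summary = aggregate_agreement(records),
              skipped = unique(skipped))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(records, file.path(out_dir, "agreement_records.csv"),
              row.names = FALSE)
    write.csv(out$summary, file.path(out_dir, "agreement_summary.csv"),
              row.names = FALSE)
  }
  out
}

#' Dose metrics for a dataset on disk
#'
#' Voxelizes every structure mesh on the patient's dose grid and computes the
#' cumulative DVH metrics per (patient, observer, structure).
#'
#' @param dataset_dir dataset directory.
#' @param out_dir output directory (`NULL` to skip writing); DVH CSVs are
#'   written under `out_dir/dvh/` when requested.
#' @param bin_width DVH bin width, Gy.
#' @param write_dvhs also write every per-structure DVH as CSV.
#' @return Data frame of dose metrics (plus structure volumes).
#' @export
cohort_dose_metrics <- function(dataset_dir, out_dir = NULL, bin_width = 0.1,
                                write_dvhs = FALSE) {
  co <- load_cohort(dataset_dir)
  rows <- list()
  for (pid in names(co$manifest$patients)) {
    pat <- co$manifest$patients[[pid]]
    dose <- read_nrrd(file.path(co$dir, pat$dose))
    if (!inherits(dose, "dose_grid"))
      stop("dose grid for ", pid, " is not a scalar dose volume")
    for (oid in names(pat$observers)) {
      files <- pat$observers[[oid]]
      for (nm in names(files)) {
        f <- file.path(co$dir, files[[nm]])
        if (!file.exists(f)) next
        mask <- voxelize(read_ply(f), dose$grid, clip = TRUE)
        if (sum(mask$values) == 0) {
          rows[[length(rows) + 1]] <- data.frame(
            patient = pid, observer = oid, structure = nm,
            volume = 0, dmean = NA_real_, d2cc = NA_real_, v5gy = NA_real_,
            flag = "empty", stringsAsFactors = FALSE)
          next
        }
        dvh <- cumulative_dvh(dose, mask, bin_width = bin_width,
                              structure = nm)
        d2 <- d2cc(dvh)
        rows[[length(rows) + 1]] <- data.frame(
          patient = pid, observer = oid, structure = nm,
          volume = mask_volume(mask), dmean = dmean(dose, mask),
          d2cc = as.numeric(d2), v5gy = v5gy(dvh),
          flag = ifelse(is.na(attr(d2, "flag")), "", attr(d2, "flag")),
          stringsAsFactors = FALSE)
        if (!is.null(out_dir) && write_dvhs) {
          dd <- file.path(out_dir, "dvh")
          dir.create(dd, recursive = TRUE, showWarnings = FALSE)
          write_dvh(dvh, file.path(dd, sprintf("%s_%s_%s.csv",
                                               pid, oid, nm)))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out, file.path(out_dir, "dose_metrics.csv"), row.names = FALSE)
  }
  out
}

#' Variability report from stage CSVs
#'
#' Builds the per-structure variability table from the dose-metrics CSV
#' produced by [cohort_dose_metrics()] (which carries structure volumes) or
#' from a [run_pipeline()] output directory.
#'
#' @param dose_metrics_csv path to `dose_metrics.csv`.
#' @param out_dir optional output directory (`variability.csv` + JSON).
#' @param B,seed bootstrap replicates and seed for the beta-model interval.
#' @return A [variability_report()] table.
#' @export
cohort_variability <- function(dose_metrics_csv, out_dir = NULL, B = 1000,
                               seed = 1) {
  d <- read.csv(dose_metrics_csv, stringsAsFactors = FALSE)
  need <- c("patient", "observer", "structure", "volume", "dmean", "d2cc",
            "v5gy")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("dose metrics file lacks columns: ", paste(miss, collapse = ", "))
  cells <- function(col, positive = FALSE) {
    x <- data.frame(structure = d$structure, patient = d$patient,
                    observer = d$observer, value = d[[col]],
                    stringsAsFactors = FALSE)
    x <- x[!is.na(x$value), ]
    if (positive) x <- x[x$value > 0, ]
    x
  }
  tab <- variability_report(cells("volume", TRUE), cells("dmean", TRUE),
                            cells("d2cc", TRUE), cells("v5gy"),
                            B = B, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tab, file.path(out_dir, "variability.csv"), row.names = FALSE)
    jsonlite::write_json(tab, file.path(out_dir, "variability.json"),
                         dataframe = "rows", auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  tab
}
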