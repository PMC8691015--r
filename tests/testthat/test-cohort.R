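test_that("generated hearts are watertight, in the volume range, and
           seed-reproducible", {
  cfg <- cohort_config()
  for (seed in seq(100, 1060, by = 20)) {  # 49 seeds
    th <- generate_heart(seed, cfg)
    expect_gte(th$volume, cfg$heart_volume_range[1])
    expect_lte(th$volume, cfg$heart_volume_range[2])
    expect_equal(nrow(mesh_boundary_edges(th$mesh)), 0)
  }
  a <- generate_heart(77, cfg)
  b <- generate_heart(77, cfg)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$landmarks$truncus_point, b$landmarks$truncus_point)
})

test_that("landmarks are anatomically placed", {
  cfg <- cohort_config()
  th <- generate_heart(4242, cfg)
  ctr <- center_of_mass(th$mesh)
  root <- th$landmarks$aortic_root_center
  tp <- th$landmarks$truncus_point
  expect_gt(root[3], ctr[3])                      # cranial pole
  expect_equal(tp[3], root[3])                    # at the root level
  expect_gt(tp[1], root[1])                       # anterior-left offset
  expect_gt(tp[2], root[2])
})

test_that("the observer perturbation is unbiased in location", {
  cfg <- cohort_config(landmark_sd = 0)
  th <- generate_heart(11, cfg)
  ctr <- center_of_mass(th$mesh)
  disp <- t(vapply(1:60, function(k) {
    pc <- cardatlas:::perturb_contour(th, 5000 + k, 3, cfg)
    center_of_mass(pc$mesh) - ctr
  }, numeric(3)))
  # mean displacement compatible with 0 at the Monte Carlo scale
  se <- apply(disp, 2, sd) / sqrt(nrow(disp))
  expect_true(all(abs(colMeans(disp)) < 4 * se + 0.3))
})

test_that("pairwise heart agreement degrades monotonically with observer
           noise", {
  # JSC of the complete heart over 3 observer pairs, increasing noise
  cfg0 <- cohort_config(landmark_sd = 0)
  th <- generate_heart(3, cfg0)
  mean_jsc <- vapply(c(1, 2, 4, 8), function(sd) {
    cfg <- cohort_config(observer_sd = sd, landmark_sd = 0)
    meshes <- lapply(1:3, function(j)
      cardatlas:::perturb_contour(th, 900 + j, 3, cfg)$mesh)
    pairs <- utils::combn(3, 2)
    mean(vapply(seq_len(ncol(pairs)), function(p)
      overlap_metrics(meshes[[pairs[1, p]]], meshes[[pairs[2, p]]],
                      spacing = 2)$jsc, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_jsc) < 0))
})

test_that("all observer noise sources to zero drives heart JSC towards 1", {
  # radial, landmark AND slice-quantization noise all small
  cfg <- cohort_config(observer_sd = 0.05, landmark_sd = 0)
  th <- generate_heart(3, cfg)
  m1 <- cardatlas:::perturb_contour(th, 901, 0.5, cfg)$mesh
  m2 <- cardatlas:::perturb_contour(th, 902, 0.5, cfg)$mesh
  expect_gt(overlap_metrics(m1, m2, spacing = 1)$jsc, 0.97)
})

test_that("thicker CT slices increase cranio-caudal disagreement", {
  cfg <- cohort_config(observer_sd = 1, landmark_sd = 0)
  th <- generate_heart(6, cfg)
  hd_z <- function(slice) {
    mean(vapply(1:4, function(j) {
      a <- cardatlas:::perturb_contour(th, 700 + j, slice, cfg)$mesh
      b <- cardatlas:::perturb_contour(th, 800 + j, slice, cfg)$mesh
      # cranio-caudal extent disagreement
      max(abs(max(a$vertices[, 3]) - max(b$vertices[, 3])),
          abs(min(a$vertices[, 3]) - min(b$vertices[, 3])))
    }, numeric(1)))
  }
  expect_gt(hd_z(10), hd_z(3))
})

test_that("pulmonary valve agreement is more sensitive to landmark noise
           than the heart", {
  cfg <- cohort_config(observer_sd = 1, landmark_sd = 6)
  th <- generate_heart(8, cfg)
  grid <- cardatlas:::cohort_grid(th, cfg, spacing = 2)
  sets <- lapply(1:3, function(j)
    simulate_observer(th, 1200 + j, 3, cfg, grid = grid,
                      patient_id = "p", observer_id = paste0("o", j)))
  rec <- pairwise_agreement(sets)
  jsc <- tapply(rec$jsc, rec$structure, mean)
  expect_gt(jsc["heart"], jsc["pulmonary_valve"])
})

test_that("the synthetic dose field has the prescribed structure", {
  cfg <- cohort_config(dose = dose_config(target_v5gy = 0.13))
  th <- generate_heart(15, cfg)
  dose <- simulate_dose(th, cfg)
  expect_equal(dose$grid$spacing, rep(2.5, 3))
  u <- attr(dose, "plane_normal")
  off <- attr(dose, "plane_offset")
  expect_equal(sum(u^2), 1, tolerance = 1e-12)
  # plateau deep inside the field, base level far outside
  expect_equal(max(dose$dose), cfg$dose$prescription_gy, tolerance = 0.01)
  expect_equal(min(dose$dose), cfg$dose$base_gy, tolerance = 0.05)
  # the placement hits the target V5GY for the true heart
  hm <- voxelize(th$mesh, dose$grid)
  v5 <- v5gy(cumulative_dvh(dose, hm))
  expect_equal(v5, 0.13, tolerance = 0.01)

  # per-patient targets drawn from a range stay inside it, reproducibly
  cfg2 <- cohort_config()
  p1 <- cardatlas:::make_patient(cfg2, 1)
  p2 <- cardatlas:::make_patient(cfg2, 2)
  rng <- cfg2$dose$target_v5gy
  expect_true(all(c(p1$dose_target, p2$dose_target) >= rng[1] &
                    c(p1$dose_target, p2$dose_target) <= rng[2]))
  expect_false(p1$dose_target == p2$dose_target)
  expect_identical(p1$dose_target,
                   cardatlas:::make_patient(cfg2, 1)$dose_target)
})

test_that("plane placement reaches a 10% heart V5GY when asked", {
  cfg <- cohort_config(dose = dose_config(target_v5gy = 0.10))
  th <- generate_heart(16, cfg)
  dose <- simulate_dose(th, cfg)
  hm <- voxelize(th$mesh, dose$grid)
  expect_equal(v5gy(cumulative_dvh(dose, hm)), 0.10, tolerance = 0.01)
})

test_that("generate_cohort writes the full deterministic tree", {
  cfg <- cohort_config(n_patients = 2, n_observers = 3,
                       analysis_spacing = 2.5, master_seed = 7)
  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  unlink(c(d1, d2), recursive = TRUE)
  suppressMessages(generate_cohort(cfg, d1))
  plys <- dir(d1, pattern = "\\.ply$", recursive = TRUE)
  # per observer 7 structures + 1 truth mesh per patient
  expect_equal(length(grep("truth", plys, invert = TRUE)), 2 * 3 * 7)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_error(generate_cohort(cfg, d1), "force")

  suppressMessages(generate_cohort(cfg, d2))
  files <- dir(d1, recursive = TRUE)
  expect_identical(files, dir(d2, recursive = TRUE))
  h1 <- tools::md5sum(file.path(d1, files))
  h2 <- tools::md5sum(file.path(d2, files))
  expect_true(all(unname(h1) == unname(h2)))
  unlink(c(d1, d2), recursive = TRUE)
})
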