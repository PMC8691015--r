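test_that("aortic valve cone has the prescribed caudal extent and volume", {
  lm <- heart_landmarks(c(3, -2, 50), c(25, 20, 50))
  av <- build_aortic_valve(lm, base_radius = 12)
  expect_equal(mesh_volume(av), 4.52, tolerance = 0.01)
  bb <- mesh_bbox(av)
  expect_equal(bb$hi[3], 50)        # starts at the aortic root...
  expect_equal(bb$lo[3], 50 - 30)   # ...going 3 cm caudally

  up <- build_aortic_valve(lm, base_radius = 12, orientation = "apex_up")
  bu <- mesh_bbox(up)
  expect_equal(c(bu$lo[3], bu$hi[3]), c(20, 50))
})

test_that("pulmonary valve sphere grows until it almost touches the aortic
           valve", {
  # truncus level with the root, 32 mm from the cone axis: the nearest point
  # of the valve surface is the base rim, 32 - 12 = 20 mm away
  lm <- heart_landmarks(c(0, 0, 50), c(32, 0, 50))
  av <- build_aortic_valve(lm, base_radius = 12)
  pv <- build_pulmonary_valve(lm, av, gap = 2)
  r <- sqrt(sum((pv$vertices[1, ] - lm$truncus_point)^2))
  expect_equal(r, 18, tolerance = 0.02)

  # gap 0: tangent (minimum surface distance ~ 0, never negative overlap)
  pv0 <- build_pulmonary_valve(lm, av, gap = 0)
  r0 <- sqrt(sum((pv0$vertices[1, ] - lm$truncus_point)^2))
  expect_equal(r0, 20, tolerance = 0.02)

  # no voxel overlap between the two valve volumes
  bb <- list(lo = pmin(mesh_bbox(av)$lo, mesh_bbox(pv)$lo),
             hi = pmax(mesh_bbox(av)$hi, mesh_bbox(pv)$hi))
  g <- grid_for_bbox(bb, spacing = 1, pad = 1)
  v <- boolean_volumes(voxelize(av, g), voxelize(pv, g))
  expect_equal(v$volIntersection, 0)

  # landmark inside the valve: rejected
  lm_bad <- heart_landmarks(c(0, 0, 50), c(5, 0, 45))
  av_bad <- build_aortic_valve(lm_bad, base_radius = 12)
  expect_error(build_pulmonary_valve(lm_bad, av_bad, gap = 2),
               "too close")
})

test_that("myocardium is the 1 cm shell below the aortic valve", {
  sph <- make_primitive("sphere", radius = 50, subdivisions = 4)
  g <- grid_for_bbox(mesh_bbox(sph), spacing = 1, pad = 2)
  heart <- voxelize(sph, g)

  # root far above the sphere: no cropping plane intersects
  lm_hi <- heart_landmarks(c(0, 0, 80), c(20, 0, 80))
  myo <- build_myocardium(heart, lm_hi, thickness = 10)
  expect_equal(mask_volume(myo) / mask_volume(heart), 1 - 0.8^3,
               tolerance = 0.03)

  # with a root plane through the sphere: subset + disjoint from the core
  lm <- heart_landmarks(c(0, 0, 30), c(20, 0, 30))
  myo2 <- build_myocardium(heart, lm, thickness = 10)
  expect_true(all(heart$values[myo2$values]))
  core <- inner_margin(heart, 10)
  expect_false(any(myo2$values & core$values))
  # everything lies below the root plane
  zc <- g$origin[3] + (seq_len(g$shape[3]) - 0.5) * g$spacing[3]
  above <- which(zc >= 30)
  expect_false(any(myo2$values[, , above]))
})

test_that("anterior wall split partitions the anterior shell symmetrically", {
  sph <- make_primitive("sphere", radius = 50, subdivisions = 4)
  g <- grid_for_bbox(mesh_bbox(sph), spacing = 1, pad = 2)
  heart <- voxelize(sph, g)
  shell <- outer_shell(heart, 10)
  lm <- heart_landmarks(c(0, 0, 80), c(20, 0, 80), heart_axis_lr = c(1, 0, 0))

  w <- split_anterior_walls(shell, lm, center = c(0, 0, 0))
  vl <- mask_volume(w$left_anterior)
  vr <- mask_volume(w$right_anterior)
  # each anterior wall is about a quarter of the shell
  expect_equal(vl / mask_volume(shell), 0.25, tolerance = 0.02)
  expect_equal(vr / mask_volume(shell), 0.25, tolerance = 0.02)
  # partition of the anterior half
  expect_false(any(w$left_anterior$values & w$right_anterior$values))
  yc <- g$origin[2] + (seq_len(g$shape[2]) - 0.5) * g$spacing[2]
  anterior <- shell$values &
    array(rep(yc > 0, each = g$shape[1]), g$shape)
  expect_true(all((w$left_anterior$values | w$right_anterior$values) ==
                    anterior))
})

test_that("mirroring the geometry in x swaps the anterior walls", {
  m <- random_blob(11)
  m <- mesh_translate(m, -center_of_mass(m))
  g <- grid_for_bbox(mesh_bbox(m), spacing = 1, pad = 2)
  shell <- outer_shell(voxelize(m, g), 5)
  lm <- heart_landmarks(c(0, 0, 60), c(20, 0, 60))
  w <- split_anterior_walls(shell, lm, center = c(0, 0, 0))

  mirr <- m
  mirr$vertices[, 1] <- -mirr$vertices[, 1]
  mirr <- tri_mesh(mirr$vertices, mirr$faces[, c(1, 3, 2)])
  gm <- grid_for_bbox(mesh_bbox(mirr), spacing = 1, pad = 2)
  shell_m <- outer_shell(voxelize(mirr, gm), 5)
  wm <- split_anterior_walls(shell_m, lm, center = c(0, 0, 0))
  expect_equal(mask_volume(wm$left_anterior),
               mask_volume(w$right_anterior), tolerance = 0.02)
  expect_equal(mask_volume(wm$right_anterior),
               mask_volume(w$left_anterior), tolerance = 0.02)
})

test_that("deep structures are the 2 cm inner margin, nested in the heart", {
  sph <- make_primitive("sphere", radius = 50, subdivisions = 4)
  g <- grid_for_bbox(mesh_bbox(sph), spacing = 1, pad = 2)
  heart <- voxelize(sph, g)
  deep <- build_deep_structures(heart)
  expect_equal(mask_volume(deep) / mask_volume(heart), (30 / 50)^3,
               tolerance = 0.05)
  expect_true(all(heart$values[deep$values]))
  lm <- heart_landmarks(c(0, 0, 30), c(20, 0, 30))
  myo <- build_myocardium(heart, lm)
  expect_false(any(deep$values & myo$values))  # 20 mm margin vs 10 mm shell
})

test_that("the full structure set is nested, complete and deterministic", {
  cfg <- cohort_config(n_patients = 1, n_observers = 1)
  th <- generate_heart(substream_seed(cfg$master_seed, 1, 0, 1), cfg)
  set1 <- build_structure_set(th$mesh, th$landmarks, spacing = 2)
  set2 <- build_structure_set(th$mesh, th$landmarks, spacing = 2)
  expect_identical(names(set1$structures), atlas_structures())
  expect_identical(set1$structures$heart$mask$values,
                   set2$structures$heart$mask$values)

  s <- set1$structures
  heart <- s$heart$mask$values
  expect_true(all(heart[s$myocardium$mask$values]))
  expect_true(all(heart[s$deep_structures$mask$values]))
  expect_true(all(s$myocardium$mask$values[
    s$left_anterior_myocardium$mask$values]))
  expect_true(all(s$myocardium$mask$values[
    s$right_anterior_myocardium$mask$values]))
  expect_false(any(s$deep_structures$mask$values & s$myocardium$mask$values))
  # volumes positive and heart the largest
  vols <- vapply(s, function(x) x$volume, numeric(1))
  expect_true(all(vols > 0))
  expect_equal(names(which.max(vols)), "heart")
})
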