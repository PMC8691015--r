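test_that("voxelization is exact for the aligned cube and accurate for curved
           solids", {
  g <- grid_spec(c(0, 0, 0), 1, c(10, 10, 10))
  expect_equal(sum(voxelize(unit_cube(), g)$values), 1000)

  sph <- make_primitive("sphere", radius = 20, subdivisions = 4)
  gs <- grid_for_bbox(mesh_bbox(sph), spacing = 1, pad = 2)
  va <- 4 / 3 * pi * 20^3 / 1000
  expect_equal(mask_volume(voxelize(sph, gs)), va, tolerance = 0.01)
})

test_that("voxel volumes converge to the mesh volume as spacing shrinks", {
  # the box is posed generically: lattice-aligned faces make the voxel error
  # alignment-dependent instead of surface-dominated
  box <- mesh_rotate(unit_cube(corner = c(0.3, 0.2, 0.7), side = 17),
                     cardatlas:::rot3("z", 0.41) %*%
                       cardatlas:::rot3("x", 0.33))
  for (mesh in list(make_primitive("sphere", radius = 20, subdivisions = 4),
                    make_primitive("cone", base_radius = 15, height = 40,
                                   base_center = c(0, 0, 20)),
                    box)) {
    vm <- mesh_volume(mesh)
    err <- vapply(c(2, 1, 0.5), function(sp) {
      g <- grid_for_bbox(mesh_bbox(mesh), spacing = sp, pad = 2 * sp)
      abs(mask_volume(voxelize(mesh, g)) - vm) / vm
    }, numeric(1))
    expect_true(all(diff(err) < 0))  # strictly decreasing for convex solids
    expect_lt(err[3], 0.01)
  }
})

test_that("a mesh outside the grid is rejected naming the axis", {
  g <- grid_spec(c(0, 0, 0), 1, c(10, 10, 5))
  expect_error(voxelize(unit_cube(), g), "z axis")
  expect_silent(voxelize(unit_cube(), g, clip = TRUE))
})

test_that("boolean volumes satisfy the set identities", {
  g <- grid_spec(c(0, 0, 0), 1, c(15, 10, 10))
  a <- voxelize(unit_cube(), g)
  b <- voxelize(unit_cube(corner = c(5, 0, 0)), g)

  # half-overlapping cubes: analytic overlap
  v <- boolean_volumes(a, b)
  expect_equal(v$volIntersection, 0.5)
  expect_equal(v$volUnion, 1.5)
  expect_equal(v$volUnion, v$volA + v$volB - v$volIntersection)

  # identity and disjoint cases
  vaa <- boolean_volumes(a, a)
  expect_equal(vaa$volIntersection, vaa$volA)
  expect_equal(vaa$volUnion, vaa$volA)
  dis <- binary_mask(g, array(FALSE, g$shape))
  dis$values[12:14, 1:3, 1:3] <- TRUE
  vd <- boolean_volumes(a, dis)
  expect_equal(vd$volIntersection, 0)
  expect_equal(vd$volUnion, vd$volA + vd$volB)

  g2 <- grid_spec(c(0, 0, 0), 2, c(8, 5, 5))
  expect_error(boolean_volumes(a, voxelize(unit_cube(), g2)),
               "different grids")
})

test_that("inclusion-exclusion holds exactly on random mask pairs", {
  for (seed in 1:10) {
    set.seed(seed)
    g <- grid_spec(c(0, 0, 0), 1, c(20, 20, 20))
    a <- binary_mask(g, array(runif(8000) < 0.4, g$shape))
    b <- binary_mask(g, array(runif(8000) < 0.4, g$shape))
    v <- boolean_volumes(a, b)
    expect_identical(v$volUnion, v$volA + v$volB - v$volIntersection)
  }
})

test_that("inner margin follows Euclidean distance", {
  sph <- make_primitive("sphere", radius = 50, subdivisions = 4)
  g <- grid_for_bbox(mesh_bbox(sph), spacing = 1, pad = 2)
  m <- voxelize(sph, g)

  er <- inner_margin(m, 20)
  expect_equal(mask_volume(er) / mask_volume(m), (30 / 50)^3,
               tolerance = 0.05)
  expect_identical(inner_margin(m, 0)$values, m$values)
  expect_warning(e60 <- inner_margin(m, 60), "erased")
  expect_equal(sum(e60$values), 0)

  # anti-extensive and monotone in the margin
  prev <- m$values
  for (mg in c(5, 10, 15)) {
    cur <- inner_margin(m, mg)$values
    expect_true(all(prev[cur]))  # cur subset of prev
    prev <- cur
  }
})

test_that("outer shell partitions the mask", {
  sph <- make_primitive("sphere", radius = 50, subdivisions = 4)
  g <- grid_for_bbox(mesh_bbox(sph), spacing = 1, pad = 2)
  m <- voxelize(sph, g)
  sh <- outer_shell(m, 10)
  core <- inner_margin(m, 10)
  expect_equal(mask_volume(sh) / mask_volume(m), 1 - 0.8^3,
               tolerance = 0.03)
  expect_true(all((sh$values | core$values) == m$values))
  expect_false(any(sh$values & core$values))

  # thickness >= inradius: shell is the whole mask
  sh_all <- suppressWarnings(outer_shell(m, 60))
  expect_identical(sh_all$values, m$values)
})

test_that("the voxel boundary mesh is watertight and encloses the mask
           volume exactly", {
  sph <- make_primitive("sphere", radius = 12, subdivisions = 3)
  g <- grid_for_bbox(mesh_bbox(sph), spacing = 1, pad = 2)
  m <- voxelize(sph, g)
  bm <- mask_to_mesh(m)
  expect_equal(nrow(mesh_boundary_edges(bm)), 0)
  expect_equal(mesh_volume(bm), mask_volume(m), tolerance = 1e-12)
})

test_that("grid and mask constructors validate their inputs", {
  expect_error(grid_spec(c(0, 0, 0), c(1, -1, 1), c(5, 5, 5)), "positive")
  expect_error(grid_spec(c(0, 0, 0), 1, c(5, 0, 5)), ">= 1")
  g <- grid_spec(c(0, 0, 0), 1, c(2, 2, 2))
  expect_error(binary_mask(g, array(TRUE, c(2, 2, 3))), "shape")
})
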