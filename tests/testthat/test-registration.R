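test_that("transform algebra: inversion and composition are exact", {
  g <- grid_spec(shape = c(32, 32, 32))
  id <- craniossm:::identity_transform(g)
  inv_id <- invert_transform(id, g)
  expect_equal(inv_id$scale, 1)
  expect_equal(inv_id$rotation, c(0, 0, 0))
  expect_equal(inv_id$translation, c(0, 0, 0))

  tr <- similarity_transform(scale = 1.13, rotation = c(0.2, -0.12, 0.31),
                             translation = c(4.5, -2, 7),
                             center = c(16, 15, 14), target_grid = g,
                             source_grid = g)
  inv <- invert_transform(tr, g)
  # composing with the inverse gives identity parameters
  comp <- craniossm:::compose_transforms(tr, inv)
  expect_equal(comp$scale, 1, tolerance = 1e-10)
  expect_equal(comp$rotation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(comp$translation, c(0, 0, 0), tolerance = 1e-8)
  # double inversion returns the original parameters
  inv2 <- invert_transform(inv, g)
  expect_equal(inv2$scale, tr$scale, tolerance = 1e-12)
  expect_equal(inv2$rotation, tr$rotation, tolerance = 1e-12)
  expect_equal(inv2$translation, tr$translation, tolerance = 1e-10)
  # and the point maps agree everywhere
  pts <- matrix(stats::runif(30, 0, 32), ncol = 3)
  expect_equal(craniossm:::transform_points(inv2, pts),
               craniossm:::transform_points(tr, pts), tolerance = 1e-9)
})

test_that("transforms serialize to JSON and back", {
  g <- grid_spec(shape = c(16, 16, 16), spacing = c(0.5, 0.5, 1))
  tr <- similarity_transform(scale = 0.97, rotation = c(0.1, 0, -0.2),
                             translation = c(1, 2, 3), center = c(8, 8, 8),
                             target_grid = g, source_grid = g)
  f <- withr::local_tempfile(fileext = ".json")
  write_transform(tr, f)
  tr2 <- read_transform(f)
  expect_equal(tr2$scale, tr$scale)
  expect_equal(tr2$rotation, tr$rotation)
  expect_equal(tr2$translation, tr$translation)
  expect_equal(tr2$target_grid$spacing, g$spacing)
})

test_that("warping through the identity is the identity", {
  p <- generate_phantom(small_phantom_spec())
  id <- craniossm:::identity_transform(grid_spec(p))
  expect_identical(warp(p, id)$data, p$data)
})

test_that("integer-voxel pure translations shift the lattice exactly", {
  p <- generate_phantom(small_phantom_spec())
  g <- grid_spec(p)
  # transform maps target point x to source point x + (3, 0, 0) voxels, so
  # the content moves by -3 along x
  tr <- similarity_transform(translation = c(3, 0, 0) * p$spacing,
                             target_grid = g, source_grid = g)
  w <- warp(p, tr)
  expect_identical(w$data[1:(48 - 3), , ], p$data[4:48, , ])
  expect_true(all(w$data[(48 - 2):48, , ] == 0L))
})

test_that("warp then inverse-warp preserves the shape", {
  p <- generate_phantom(small_phantom_spec())
  g <- grid_spec(p)
  tr <- similarity_transform(scale = 1.06, rotation = c(0.1, -0.08, 0.04),
                             translation = c(2.5, -1.5, 3),
                             center = c(24, 24, 24), target_grid = g,
                             source_grid = g)
  there <- warp(p, tr)
  back <- warp(there, invert_transform(tr, g))
  expect_gte(dsc(back, p), 0.98)
})

test_that("self-registration returns near-identity", {
  p <- generate_phantom(small_phantom_spec())
  est <- register_similarity(p, p)
  expect_lt(abs(est$scale - 1), 0.01)
  expect_lt(max(abs(est$rotation)) * 180 / pi, 0.5)
  expect_lt(max(abs(est$translation)), 0.5 * min(p$spacing))
  expect_true(est$converged)
})

test_that("a known similarity transform is recovered", {
  p <- generate_phantom(small_phantom_spec())
  g <- grid_spec(p)
  ctr <- craniossm:::foreground_centroid(p)
  true_tr <- similarity_transform(scale = 1.1, rotation = c(0, 10, 0) * pi / 180,
                                  translation = c(5, 3, -2) * p$spacing,
                                  center = ctr, target_grid = g,
                                  source_grid = g)
  moved <- warp(p, true_tr)
  est <- suppressWarnings(register_similarity(p, moved))
  ec <- canonical_params(est, ctr)
  tc <- canonical_params(true_tr, ctr)
  expect_lt(abs(ec$scale - tc$scale) / tc$scale, 0.02)
  expect_lt(max(abs(ec$rotation - tc$rotation)) * 180 / pi, 2)
  expect_lt(max(abs(ec$translation - tc$translation)), min(p$spacing))
})

test_that("pure translations are recovered in physical units", {
  p <- generate_phantom(phantom_spec(shape = c(40, 40, 40),
                                     radii = c(13, 11, 10), thickness = 4,
                                     spacing = c(1.5, 1, 1)))
  g <- grid_spec(p)
  ctr <- craniossm:::foreground_centroid(p)
  true_tr <- similarity_transform(translation = c(4 * 1.5, 0, 0),
                                  center = ctr, target_grid = g,
                                  source_grid = g)
  moved <- warp(p, true_tr)
  est <- suppressWarnings(register_similarity(p, moved))
  ec <- canonical_params(est, ctr)
  expect_lt(abs(ec$scale - 1), 0.01)
  expect_equal(ec$translation, c(6, 0, 0), tolerance = 0.5)
})

test_that("registration rejects empty inputs", {
  p <- generate_phantom(small_phantom_spec())
  empty <- binary_volume(array(0L, c(48, 48, 48)))
  expect_error(register_similarity(empty, p), "non-empty")
  expect_error(register_similarity(p, empty), "non-empty")
})
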