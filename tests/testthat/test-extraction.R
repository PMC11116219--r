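test_that("component counting matches a brute-force flood fill", {
  two <- binary_volume(array(0L, c(16, 16, 16)))
  two$data[2:5, 2:5, 2:5] <- 1L
  two$data[10:12, 10:12, 10:12] <- 1L
  cc <- count_components(two)
  expect_equal(cc$count, 2L)
  expect_setequal(cc$sizes, c(64L, 27L))

  single <- binary_volume(array(0L, c(5, 5, 5)))
  single$data[3, 3, 3] <- 1L
  expect_equal(count_components(single)$count, 1L)
  expect_equal(count_components(single)$sizes, 1L)

  for (seed in c(4, 21)) {
    v <- random_sparse_volume(c(14, 14, 14), seed = seed, density = 0.08)
    for (conn in c(6, 18, 26)) {
      oracle <- brute_components(v, conn)
      got <- count_components(v, conn)
      expect_equal(got$count, oracle$count)
      expect_equal(sort(got$sizes), sort(oracle$sizes))
    }
  }
})

test_that("a thick solid survives box opening unchanged", {
  cube <- cuboid_volume(c(20, 20, 20), c(5, 5, 5), c(14, 14, 14))
  out <- extract_implant(cube, extraction_config(median_kernel = 1,
                                                 opening_radius = 1,
                                                 element = "box"))
  expect_identical(out$data, cube$data)
  expect_false(attr(out, "qc_flag"))
})

test_that("ball opening only rounds the edges of a solid", {
  # a Euclidean ball cannot fit into right-angle corners, so ball opening
  # shaves edge/corner voxels of a cube and nothing else
  cube <- cuboid_volume(c(20, 20, 20), c(5, 5, 5), c(14, 14, 14))
  out <- extract_implant(cube, extraction_config(median_kernel = 1,
                                                 opening_radius = 1,
                                                 element = "ball"))
  expect_true(all(out$data <= cube$data))
  removed <- which(cube$data == 1L & out$data == 0L, arr.ind = TRUE)
  # every removed voxel sits on at least two faces of the cube (an edge)
  on_edge <- rowSums(removed == 5 | removed == 14) >= 2
  expect_true(all(on_edge))
  expect_gt(dsc(out, cube), 0.9)
  # the interior is untouched
  expect_true(all(out$data[6:13, 6:13, 6:13] == 1L))
})

test_that("speckle noise is removed while the implant is preserved", {
  p <- generate_phantom(phantom_spec())
  dd <- apply_defect(p, defect_spec("sphere", size_fraction = 0.12,
                                    seed = 5))
  raw <- dd$implant
  set.seed(42)
  bg <- which(raw$data == 0L & p$data == 0L)
  raw$data[sample(bg, 50)] <- 1L  # isolated single-voxel speckles
  clean <- extract_implant(raw)
  expect_gte(dsc(clean, dd$implant), 0.95)
})

test_that("extraction output is contained in the filtered input", {
  v <- random_blob_volume(c(24, 24, 24), seed = 13, fill = 0.15)
  cfg <- extraction_config(median_kernel = 3, opening_radius = 1, keep = 2)
  out1 <- extract_implant(v, cfg)
  filtered <- craniossm:::median_filter_binary(v, cfg$median_kernel)
  expect_true(all(out1$data <= filtered$data))
})

test_that("the opening + component pipeline is exactly idempotent", {
  # without the median, extraction is a morphological opening followed by
  # component selection, and re-extracting its own output is a no-op
  v <- random_blob_volume(c(24, 24, 24), seed = 13, fill = 0.15)
  cfg <- extraction_config(median_kernel = 1, opening_radius = 1, keep = 2)
  out1 <- suppressWarnings(extract_implant(v, cfg))
  out2 <- suppressWarnings(extract_implant(out1, cfg))
  expect_identical(out2$data, out1$data)
})

test_that("empty extraction warns and flags failure", {
  empty <- binary_volume(array(0L, c(8, 8, 8)))
  expect_warning(out <- extract_implant(empty), "empty")
  expect_true(attr(out, "extraction_failed"))
  expect_equal(sum(out$data), 0)
})

test_that("equal-size ties resolve to the earlier raster-order component", {
  v <- binary_volume(array(0L, c(12, 12, 12)))
  v$data[8:9, 8:9, 8:9] <- 1L   # later in raster order
  v$data[2:3, 2:3, 2:3] <- 1L   # earlier
  out <- suppressWarnings(
    extract_implant(v, extraction_config(median_kernel = 1,
                                         opening_radius = 0, keep = 1)))
  expect_equal(sum(out$data), 8)
  expect_true(all(which(out$data == 1L, arr.ind = TRUE) <= 3))
  expect_true(attr(out, "qc_flag"))  # the dropped twin is comparable
})
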