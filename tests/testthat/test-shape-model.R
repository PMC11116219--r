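# Most shape-model algebra is exercised on small synthetic pools built
# directly from flattened binary vectors (no registration involved), so the
# PCA contracts can be checked against brute-force linear algebra.

pool_from_matrix <- function(warped, shape = NULL) {
  if (is.null(shape)) shape <- c(ncol(warped), 1, 1)
  grid <- grid_spec(shape = shape)
  members <- lapply(seq_len(nrow(warped)), function(i)
    binary_volume(array(warped[i, ], shape)))
  structure(list(members = members, warped = warped,
                 transforms = replicate(nrow(warped),
                                        craniossm:::identity_transform(grid),
                                        simplify = FALSE),
                 reference_index = 1L, grid = grid),
            class = "shape_pool")
}

random_binary_matrix <- function(C, N, seed) {
  set.seed(seed)
  matrix(as.numeric(stats::runif(C * N) < 0.4), C, N)
}

test_that("mean shape equals brute-force voxelwise averaging", {
  X <- random_binary_matrix(6, 300, seed = 2)
  pool <- pool_from_matrix(X)
  m <- mean_shape(pool)
  oracle <- vapply(seq_len(300), function(j) sum(X[, j]) / 6, numeric(1))
  expect_equal(m, oracle)
  expect_true(all(m >= 0 & m <= 1))

  same <- pool_from_matrix(matrix(rep(X[1, ], 3), 3, byrow = TRUE))
  expect_equal(mean_shape(same), X[1, ])

  two <- pool_from_matrix(rbind(c(1, 0, 1), c(1, 0, 0)), c(3, 1, 1))
  expect_equal(mean_shape(two), c(1, 0, 0.5))
})

test_that("mean_template averages leading members and binarizes", {
  X <- random_binary_matrix(5, 64, seed = 3)
  pool <- pool_from_matrix(X, c(4, 4, 4))
  t1 <- mean_template(pool, subset_size = 1)
  expect_equal(as.vector(t1$data), X[1, ])
  t3 <- mean_template(pool, subset_size = 3, threshold = 0.5)
  expect_equal(as.vector(t3$data),
               as.integer(colMeans(X[1:3, ]) > 0.5))
  expect_error(mean_template(pool, subset_size = 0), ">= 1")
  expect_error(mean_template(pool, subset_size = 9), "exceeds")
})

test_that("PCA scores and variations match a brute-force eigendecomposition", {
  C <- 5; N <- 200
  X <- random_binary_matrix(C, N, seed = 7)
  pool <- pool_from_matrix(X, c(10, 10, 2))
  model <- fit_variations(pool, n_components = C)

  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(t(Xc) %*% Xc, symmetric = TRUE)  # N x N covariance (unscaled)
  r <- C - 1  # rank after centring
  scores_oracle <- Xc %*% ev$vectors[, seq_len(r), drop = FALSE]
  for (k in seq_len(r)) {
    agree <- max(abs(model$scores[, k] - scores_oracle[, k]))
    flipped <- max(abs(model$scores[, k] + scores_oracle[, k]))
    expect_lt(min(agree, flipped), 1e-6)
  }
  # variation rows are the matching principal axes
  for (k in seq_len(r)) {
    axis <- ev$vectors[, k]
    agree <- max(abs(model$variations[k, ] - axis))
    flipped <- max(abs(model$variations[k, ] + axis))
    expect_lt(min(agree, flipped), 1e-6)
  }
})

test_that("variation matrix is consistent with the stored scores", {
  X <- random_binary_matrix(6, 400, seed = 11)
  pool <- pool_from_matrix(X, c(20, 20, 1))
  model <- fit_variations(pool)
  Xc <- sweep(X, 2, model$mean)
  # applying the variation matrix to each centred member row reproduces its
  # score row
  recovered <- Xc %*% t(model$variations)
  expect_equal(recovered, model$scores, tolerance = 1e-8,
               ignore_attr = TRUE)
  # and it is the pseudo-inverse relation: variations == t(scores) . pinv(Xc^T)
  phi_direct <- t(model$scores) %*% craniossm:::pseudo_inverse(t(Xc))
  expect_equal(model$variations, phi_direct, tolerance = 1e-8)
})

test_that("an identical-member pool yields zero variations with a warning", {
  X <- matrix(rep(c(1, 0, 1, 1, 0, 0), 4), 4, byrow = TRUE)
  pool <- pool_from_matrix(X, c(6, 1, 1))
  expect_warning(model <- fit_variations(pool), "identical")
  expect_lt(max(abs(model$variations)), 1e-8)
})

test_that("projection weights follow the PCA scores and min-max rescale", {
  X <- random_binary_matrix(5, 150, seed = 13)
  pool <- pool_from_matrix(X, c(15, 10, 1))
  model <- fit_variations(pool)
  w <- project_shape(model, X[3, ])
  expect_equal(w$lambda_raw, model$scores[3, ], tolerance = 1e-8,
               ignore_attr = TRUE)
  # min-max arithmetic
  w2 <- shape_weights(c(2, 4, 6))
  expect_equal(w2$lambda_rescaled, c(0, 0.5, 1))
  expect_warning(w3 <- shape_weights(c(3, 3, 3)), "equal")
  expect_equal(w3$lambda_rescaled, c(0, 0, 0))
  expect_error(project_shape(model, rep(0, 10)), "length")
})

test_that("the two reconstruction routes agree and zero weights give the mean", {
  X <- random_binary_matrix(6, 250, seed = 17)
  pool <- pool_from_matrix(X, c(25, 10, 1))
  model <- fit_variations(pool)
  set.seed(1)
  lam <- stats::rnorm(6, sd = 4)
  f1 <- reconstruct_shape(model, lam, mode = "eq1", binarize = FALSE)
  f2 <- reconstruct_shape(model, lam, mode = "inverse_pca", binarize = FALSE)
  expect_lt(max(abs(f1 - f2)), 1e-8)

  zero <- reconstruct_shape(model, rep(0, 6), mode = "eq1")
  expect_identical(as.vector(zero$data), as.integer(model$mean > 0.5))

  vonly <- reconstruct_shape(model, rep(1, 6), mode = "variations_only",
                             binarize = FALSE)
  expect_equal(as.vector(vonly), colSums(model$variations),
               tolerance = 1e-10)
  expect_error(reconstruct_shape(model, lam, mode = "nope"))
})

test_that("training members self-reconstruct exactly at full rank", {
  X <- random_binary_matrix(7, 300, seed = 23)
  pool <- pool_from_matrix(X, c(30, 10, 1))
  model <- fit_variations(pool)
  for (i in c(1, 4, 7)) {
    w <- project_shape(model, X[i, ])
    rec <- reconstruct_shape(model, w)
    expect_gte(dsc(rec, pool$members[[i]]), 0.999)
  }
})

test_that("more components never fit the training set worse", {
  X <- random_binary_matrix(8, 200, seed = 29)
  pool <- pool_from_matrix(X, c(20, 10, 1))
  sse <- vapply(1:8, function(d0) {
    model <- fit_variations(pool, n_components = d0)
    tot <- 0
    for (i in 1:8) {
      w <- project_shape(model, X[i, ])
      f <- reconstruct_shape(model, w, binarize = FALSE)
      tot <- tot + sum((as.vector(f) - X[i, ])^2)
    }
    tot
  }, numeric(1))
  expect_true(all(diff(sse) <= 1e-8))
})

test_that("models survive a save/load round trip", {
  X <- random_binary_matrix(4, 64, seed = 31)
  pool <- pool_from_matrix(X, c(4, 4, 4))
  model <- fit_variations(pool)
  f <- withr::local_tempfile(fileext = ".rds")
  save_shape_model(model, f)
  m2 <- load_shape_model(f)
  expect_equal(m2$mean, model$mean)
  expect_equal(m2$variations, model$variations)
  saveRDS(list(), f)
  expect_error(load_shape_model(f), "shape model")
})

test_that("build_pool warps members onto the reference grid", {
  cohort <- generate_cohort(3, small_phantom_spec(), seed = 2,
                            angle_max_deg = 4, shift_max = 2)
  pool <- suppressWarnings(build_pool(cohort, reference_index = 2))
  expect_equal(nrow(pool$warped), 3L)
  # the reference's own row is its flattened data under an identity transform
  expect_equal(pool$warped[2, ], as.numeric(as.vector(cohort[[2]]$data)))
  expect_equal(pool$transforms[[2]]$scale, 1)
  # warped members resemble the reference
  ref <- pool$warped[2, ]
  for (i in c(1, 3)) {
    w <- pool$warped[i, ]
    expect_gte(2 * sum(w * ref) / (sum(w) + sum(ref)), 0.75)
  }
  expect_error(build_pool(cohort[1], 1), "at least 2")
  expect_error(build_pool(cohort, 5), "out of range")
})
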