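#' Build a shape pool in a common reference space
#'
#' Registers every complete shape to the designated reference member with a
#' similarity transform and warps it onto the reference grid, establishing
#' the voxelwise correspondence on which the shape model is built (the
#' foreground voxels act as dense landmarks). The reference member itself
#' gets an identity transform.
#'
#' @param volumes list of at least two non-empty [binary_volume()]s.
#' @param reference_index index of the reference member whose grid defines
#'   the common space.
#' @param config a [reg_config()] passed to [register_similarity()].
#' @return An object of class `shape_pool`: `members` (the inputs), `warped`
#'   (C x |D_j| numeric matrix of flattened warped shapes, column-major voxel
#'   order), `transforms`, `reference_index`, `grid` (the reference
#'   [grid_spec()]).
#' @export
build_pool <- function(volumes, reference_index = 1, config = reg_config()) {
  if (!is.list(volumes) || length(volumes) < 2L)
    stop("a shape pool needs at least 2 volumes", call. = FALSE)
  lapply(volumes, stop_if_not_volume)
  C <- length(volumes)
  if (reference_index < 1 || reference_index > C)
    stop("reference_index out of range", call. = FALSE)
  ref <- volumes[[reference_index]]
  grid <- grid_spec(ref)
  warped <- matrix(0, nrow = C, ncol = prod(grid$shape))
  transforms <- vector("list", C)
  for (i in seq_len(C)) {
    if (i == reference_index) {
      transforms[[i]] <- identity_transform(grid)
      warped[i, ] <- flatten_volume(ref)
    } else {
      tr <- register_similarity(volumes[[i]], ref, config)
      transforms[[i]] <- tr
      warped[i, ] <- flatten_volume(warp(volumes[[i]], tr))
    }
  }
  structure(list(members = volumes, warped = warped,
                 transforms = transforms,
                 reference_index = as.integer(reference_index), grid = grid),
            class = "shape_pool")
}

#' @export
print.shape_pool <- function(x, ...) {
  cat("<shape_pool> ", nrow(x$warped), " shapes on a ",
      paste(x$grid$shape, collapse = " x "), " reference grid (member ",
      x$reference_index, ")\n", sep = "")
  invisible(x)
}

#' Mean shape of a pool
#'
#' Voxelwise average of the warped shapes: a real-valued occupancy in
#' \[0, 1\] on the reference grid.
#'
#' @param pool a [build_pool()] result.
#' @return Numeric vector of length |D_j| (flattened, column-major).
#' @export
mean_shape <- function(pool) {
  stopifnot(inherits(pool, "shape_pool"))
  colMeans(pool$warped)
}

#' Binarized mean-shape template
#'
#' Averages the first `subset_size` warped members and binarizes, giving the
#' mean-skull templates used for template-subtraction completion (e.g. a mean
#' over 30 or 50 complete skulls). With `subset_size = 1` this is the first
#' member itself.
#'
#' @param pool a [build_pool()] result.
#' @param subset_size number of leading members to average (>= 1, <= pool
#'   size).
#' @param threshold binarization threshold on the mean occupancy.
#' @return A [binary_volume()] on the reference grid.
#' @export
mean_template <- function(pool, subset_size = nrow(pool$warped),
                          threshold = 0.5) {
  stopifnot(inherits(pool, "shape_pool"))
  if (subset_size < 1) stop("subset_size must be >= 1", call. = FALSE)
  if (subset_size > nrow(pool$warped))
    stop("subset_size exceeds pool size", call. = FALSE)
  m <- colMeans(pool$warped[seq_len(subset_size), , drop = FALSE])
  unflatten_volume(m, pool$grid, threshold)
}

# Moore-Penrose pseudo-inverse by SVD with a relative singular-value cutoff.
pseudo_inverse <- function(M, rcond = 1e-10) {
  sv <- svd(M)
  keep <- sv$d > rcond * max(sv$d, 0)
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' Fit the shape-variation model (PCA on the warped pool)
#'
#' Computes the PCA scores of the warped shape matrix and derives the
#' variation matrix by multiplying the scores with the Moore-Penrose
#' pseudo-inverse of the (mean-centred) warped matrix. Each row of the
#' variation matrix is a principal mode of voxelwise shape variation; the
#' scores of a shape are recovered by applying the variation matrix to the
#' centred shape vector, and the shape is rebuilt as the mean plus the
#' score-weighted sum of variations (the inverse-PCA reconstruction).
#'
#' Centring convention: scores are PCA scores of the mean-centred data, and
#' the variation matrix acts on centred inputs, which makes projection and
#' reconstruction exact inverses on the training span.
#'
#' For economy with C << |D_j| the SVD is taken through the C x C Gram matrix
#' rather than the full covariance; the result is identical up to the
#' singular-value cutoff.
#'
#' @param pool a [build_pool()] result.
#' @param n_components number of retained components d0, `1 <= d0 <= C`.
#' @return An object of class `shape_model`: `mean` (numeric |D_j|),
#'   `variations` (C x |D_j| matrix, one mode per row), `scores` (C x C
#'   matrix, training-member scores), `singular_values`, `n_components`,
#'   `grid`, `template` (binarized mean as a [binary_volume()]).
#' @export
fit_variations <- function(pool, n_components = nrow(pool$warped)) {
  stopifnot(inherits(pool, "shape_pool"))
  C <- nrow(pool$warped)
  if (n_components < 1 || n_components > C)
    stop("n_components must be in [1, pool size]", call. = FALSE)
  sbar <- mean_shape(pool)
  Xc <- sweep(pool$warped, 2, sbar)
  gram <- Xc %*% t(Xc)
  eg <- eigen(gram, symmetric = TRUE)
  d2 <- pmax(eg$values, 0)
  # Rank decision on the eigenvalue (variance) scale: the Gram eigenvalues
  # carry numerical noise of order eps * ||G||, which the square root would
  # inflate to ~1e-8 relative singular values, so a cutoff on the singular
  # values alone would keep pure-noise modes.
  keep <- d2 > 1e-12 * max(d2, 0)
  d <- sqrt(d2)
  d[!keep] <- 0  # components below the cutoff carry exactly zero scores
  if (!any(keep))
    warning("all pool members are identical; shape variations are zero",
            call. = FALSE)
  # scores = U D (PCA scores of the centred data), zero beyond the rank
  scores <- eg$vectors %*% diag(d, C, C)
  # variation matrix = scores^T . pinv(Xc^T); computed through the Gram
  # factors: pinv(Xc^T) = U D^+ V^T with V = Xc^T U D^-1, so
  # Phi = D^+ U^T Xc  (rows are the principal axes).
  dinv <- ifelse(keep, 1 / d, 0)
  variations <- (dinv * t(eg$vectors)) %*% Xc
  structure(list(mean = sbar, variations = variations, scores = scores,
                 singular_values = d,
                 n_components = as.integer(n_components), grid = pool$grid,
                 template = unflatten_volume(sbar, pool$grid, 0.5),
                 reference = pool$members[[pool$reference_index]],
                 provenance = list(n_members = C,
                                   reference_index = pool$reference_index,
                                   transforms = pool$transforms)),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat("<shape_model> ", nrow(x$variations), " modes on a ",
      paste(x$grid$shape, collapse = " x "), " grid, d0 = ",
      x$n_components, "\n", sep = "")
  invisible(x)
}

#' Project a shape into the model's PCA space
#'
#' Applies the variation matrix to the centred flattened shape, yielding one
#' weight per retained mode, plus the min-max rescaled weights in \[0, 1\].
#' When all raw weights are equal the rescaled weights are all zero (with a
#' warning), since min-max normalization is undefined there.
#'
#' @param model a [fit_variations()] result.
#' @param warped_flat flattened binary vector of length |D_j| (a shape
#'   already warped to the reference grid), or a [binary_volume()] on that
#'   grid.
#' @return An object of class `shape_weights`: `lambda_raw`,
#'   `lambda_rescaled` (both length d0).
#' @export
project_shape <- function(model, warped_flat) {
  stopifnot(inherits(model, "shape_model"))
  if (is_binary_volume(warped_flat)) {
    if (!same_grid(warped_flat, model$grid))
      stop("volume is not on the model's reference grid", call. = FALSE)
    warped_flat <- flatten_volume(warped_flat)
  }
  if (length(warped_flat) != length(model$mean))
    stop("shape vector length ", length(warped_flat),
         " does not match the model grid (", length(model$mean), ")",
         call. = FALSE)
  d0 <- model$n_components
  lam <- as.vector(model$variations[seq_len(d0), , drop = FALSE] %*%
                     (as.numeric(warped_flat) - model$mean))
  shape_weights(lam)
}

#' @rdname project_shape
#' @param lambda_raw raw weight vector (one per retained mode).
#' @export
shape_weights <- function(lambda_raw) {
  lambda_raw <- as.numeric(lambda_raw)
  rng <- range(lambda_raw)
  if (diff(rng) == 0) {
    if (length(lambda_raw) > 1)
      warning("all weights equal; min-max rescaling degenerates to zeros",
              call. = FALSE)
    resc <- rep(0, length(lambda_raw))
  } else {
    resc <- (lambda_raw - rng[1]) / (rng[2] - rng[1])
  }
  structure(list(lambda_raw = lambda_raw, lambda_rescaled = resc),
            class = "shape_weights")
}

#' Reconstruct a shape from model weights
#'
#' Three reconstruction routes:
#' \describe{
#'   \item{`"eq1"`}{mean plus the explicit weighted sum of variation modes,
#'     accumulated mode by mode.}
#'   \item{`"inverse_pca"`}{mean plus the weight vector times the variation
#'     matrix (the inverse-PCA matrix product). Algebraically identical to
#'     `"eq1"`; both are kept as separate code paths and checked against each
#'     other.}
#'   \item{`"variations_only"`}{the weighted sum of variation modes without
#'     the mean, for probing how much shape the modes alone carry (with unit
#'     weights or projected weights).}
#' }
#'
#' @param model a [fit_variations()] result.
#' @param weights a [shape_weights()] object or bare numeric vector of length
#'   d0.
#' @param mode `"eq1"`, `"inverse_pca"` or `"variations_only"`.
#' @param threshold binarization threshold applied to the real-valued
#'   reconstruction.
#' @param use_rescaled use the min-max rescaled weights instead of the raw
#'   ones. Raw weights preserve the exact PCA-inverse identity; rescaled
#'   weights reproduce the normalized-weight variant.
#' @param binarize if `FALSE`, return the real-valued reconstruction as a 3D
#'   array instead of a [binary_volume()].
#' @return A [binary_volume()] on the model grid, or a numeric array when
#'   `binarize = FALSE`.
#' @export
reconstruct_shape <- function(model, weights,
                              mode = c("inverse_pca", "eq1",
                                       "variations_only"),
                              threshold = 0.5, use_rescaled = FALSE,
                              binarize = TRUE) {
  stopifnot(inherits(model, "shape_model"))
  mode <- match.arg(mode)
  lam <- if (inherits(weights, "shape_weights")) {
    if (use_rescaled) weights$lambda_rescaled else weights$lambda_raw
  } else as.numeric(weights)
  d0 <- model$n_components
  if (length(lam) != d0)
    stop("expected ", d0, " weights, got ", length(lam), call. = FALSE)
  phi <- model$variations[seq_len(d0), , drop = FALSE]
  field <- switch(mode,
    eq1 = {
      acc <- model$mean
      for (i in seq_len(d0)) acc <- acc + lam[i] * phi[i, ]
      acc
    },
    inverse_pca = model$mean + as.vector(lam %*% phi),
    variations_only = as.vector(lam %*% phi)
  )
  field <- array(field, model$grid$shape)
  if (!binarize) return(field)
  binary_volume(array(field > threshold, model$grid$shape),
                spacing = model$grid$spacing, origin = model$grid$origin)
}

#' Save / load a fitted shape model
#'
#' Persists the mean shape, variation matrix, scores, grid and per-member
#' transforms to a single archive for later completion runs.
#'
#' @param model a [fit_variations()] result.
#' @param path archive path (`.rds`).
#' @return `save_shape_model` returns `path` invisibly; `load_shape_model`
#'   the restored model.
#' @export
save_shape_model <- function(model, path) {
  stopifnot(inherits(model, "shape_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_shape_model
#' @export
load_shape_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "shape_model"))
    stop("file does not contain a shape model: ", path, call. = FALSE)
  model
}
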