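#' Registration settings
#'
#' Controls for [register_similarity()]. The defaults implement a
#' deterministic multi-resolution scheme suited to binary masks: both masks
#' are Gaussian-smoothed (so the mean-squares objective has usable gradients
#' off the surface), the transform is initialized from foreground moments
#' (centroid translation, cube-root volume-ratio scale, zero rotation), and
#' the 7 parameters are optimized coarse-to-fine.
#'
#' @param smooth_sigma Gaussian sigma in voxels applied to both masks at
#'   full resolution; each pyramid level smooths with `smooth_sigma * shrink`.
#' @param shrink integer shrink factors for the Nelder-Mead pyramid, finest
#'   last.
#' @param maxit Nelder-Mead iteration budget per level (same length as
#'   `shrink`).
#' @param refine if `TRUE`, a short quasi-Newton (BFGS) polish runs at full
#'   resolution after the pyramid.
#' @param refine_maxit BFGS iteration budget for the polish.
#' @return A list of class `reg_config`.
#' @export
reg_config <- function(smooth_sigma = 1, shrink = c(4, 2),
                       maxit = c(400, 500), refine = TRUE,
                       refine_maxit = 10) {
  stopifnot(length(shrink) == length(maxit), all(shrink >= 1))
  structure(list(smooth_sigma = smooth_sigma, shrink = as.integer(shrink),
                 maxit = as.integer(maxit), refine = isTRUE(refine),
                 refine_maxit = as.integer(refine_maxit)),
            class = "reg_config")
}

# Downsampled copy of a grid (spacing grows, shape shrinks; origin fixed at
# the same first-voxel-centre).
shrink_grid <- function(grid, factor) {
  if (factor == 1L) return(grid)
  grid_spec(shape = pmax(1L, as.integer(floor(grid$shape / factor))),
            spacing = grid$spacing * factor, origin = grid$origin)
}

params_to_transform <- function(par, center, target_grid, source_grid,
                                converged = TRUE) {
  similarity_transform(scale = exp(par[1]), rotation = par[2:4],
                       translation = par[5:7], center = center,
                       target_grid = target_grid, source_grid = source_grid,
                       converged = converged)
}

#' Register a moving binary volume to a fixed one
#'
#' Estimates the similarity transform (isotropic scale, rotation,
#' translation) that maps the moving shape into the space of the fixed
#' (reference) shape, by minimizing the mean squared difference between the
#' Gaussian-smoothed masks over the fixed grid. The optimization is fully
#' deterministic: moment-based initialization, Nelder-Mead over the shrink
#' pyramid, optional BFGS polish, no random restarts.
#'
#' @param moving,fixed [binary_volume()] objects with at least one foreground
#'   voxel each.
#' @param config a [reg_config()].
#' @return A [similarity_transform()] whose `target_grid` is the fixed grid;
#'   `converged` is `FALSE` (with a warning) if the optimizer hit its
#'   iteration budget at the finest level.
#' @export
register_similarity <- function(moving, fixed, config = reg_config()) {
  stop_if_not_volume(moving, "moving")
  stop_if_not_volume(fixed, "fixed")
  n_mov <- sum(moving$data)
  n_fix <- sum(fixed$data)
  if (n_mov == 0L || n_fix == 0L)
    stop("registration needs non-empty foreground in both volumes",
         call. = FALSE)
  src <- grid_spec(moving)
  tgt <- grid_spec(fixed)

  center <- foreground_centroid(fixed)
  t0 <- foreground_centroid(moving) - center
  s0 <- ((n_mov * prod(moving$spacing)) / (n_fix * prod(fixed$spacing)))^(1 / 3)
  par <- c(log(s0), 0, 0, 0, t0)

  # Scale the simplex steps to the natural units of each parameter:
  # ~5% in scale, ~3 degrees, ~one fine voxel.
  parscale <- c(0.05, rep(0.05, 3), rep(min(tgt$spacing), 3))

  # The metric only carries information near the fixed foreground; evaluate
  # it on the foreground bounding box (padded past the smoothing support)
  # instead of the full grid. The returned transform still targets the full
  # fixed grid.
  pad <- ceiling(4 * config$smooth_sigma * max(config$shrink) + 4)
  idx <- which(fixed$data == 1L, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, tgt$shape)
  crop_grid <- grid_spec(shape = hi - lo + 1L, spacing = tgt$spacing,
                         origin = tgt$origin + (lo - 1) * tgt$spacing)

  make_objective <- function(f) {
    lev_grid <- shrink_grid(crop_grid, f)
    sig <- config$smooth_sigma * f
    fix_s <- array(cpp_smooth_gaussian(as.numeric(fixed$data), tgt$shape,
                                       rep(sig, 3)), tgt$shape)
    fix_crop <- fix_s[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    mov_s <- cpp_smooth_gaussian(as.numeric(moving$data), src$shape,
                                 rep(sig * min(tgt$spacing) / min(src$spacing), 3))
    fix_lev <- if (f == 1L) fix_crop else
      warp_field(fix_crop, crop_grid, lev_grid, identity_transform(lev_grid))
    mov_arr <- array(mov_s, src$shape)
    function(p) {
      tr <- params_to_transform(p, center, lev_grid, src)
      w <- warp_field(mov_arr, src, lev_grid, tr)
      mean((w - fix_lev)^2)
    }
  }

  converged <- TRUE
  for (lev in seq_along(config$shrink)) {
    fit <- stats::optim(par, make_objective(config$shrink[lev]),
                        method = "Nelder-Mead",
                        control = list(maxit = config$maxit[lev],
                                       parscale = parscale,
                                       reltol = 1e-8))
    par <- fit$par
    if (lev == length(config$shrink)) converged <- fit$convergence == 0L
  }
  if (config$refine) {
    # fixed-budget quasi-Newton polish at full resolution; the convergence
    # verdict stays with the Nelder-Mead pyramid
    fit <- stats::optim(par, make_objective(1L), method = "BFGS",
                        control = list(maxit = config$refine_maxit,
                                       parscale = parscale, reltol = 1e-10))
    par <- fit$par
  }
  if (!converged)
    warning("registration optimizer reached its iteration budget; ",
            "returning best transform found", call. = FALSE)
  params_to_transform(par, center, tgt, src, converged = converged)
}
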