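#' Similarity transform between volume spaces
#'
#' A 7-parameter spatial map (isotropic scale, three rotation angles, three
#' translations) used to bring every shape into the space of the reference.
#' The transform is stored in resampling convention: it maps a physical point
#' `p` of the *target* (reference) space into the *source* (moving) space as
#'
#'   `p_src = s * R * (p - center) + center + translation`
#'
#' with `R = Rz(rz) %*% Ry(ry) %*% Rx(rx)` (angles in radians). [warp()]
#' pulls the moving image onto the target grid through this map, which is the
#' standard way to resample without holes. Registering a moving image to a
#' fixed one therefore *is* the warp of the moving shape into the fixed space.
#'
#' @param scale positive scalar.
#' @param rotation numeric length-3, rotation angles (radians) about x, y, z.
#' @param translation numeric length-3, mm.
#' @param center numeric length-3, fixed point of rotation/scaling, mm.
#' @param target_grid a [grid_spec()] for the space the transform resamples
#'   onto (the reference grid).
#' @param source_grid optional [grid_spec()] of the moving image's grid,
#'   kept so the transform can be inverted without re-supplying it.
#' @param converged logical flag set by [register_similarity()].
#' @return An object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, rotation = c(0, 0, 0),
                                 translation = c(0, 0, 0),
                                 center = c(0, 0, 0), target_grid = NULL,
                                 source_grid = NULL, converged = TRUE) {
  scale <- as.numeric(scale)
  if (length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("scale must be a positive scalar", call. = FALSE)
  structure(list(scale = scale, rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center), target_grid = target_grid,
                 source_grid = source_grid, converged = isTRUE(converged)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat("<similarity_transform> scale ", format(x$scale),
      ", rotation (deg) (", paste(format(x$rotation * 180 / pi, digits = 4),
                                  collapse = ", "),
      "), translation (mm) (", paste(format(x$translation, digits = 4),
                                     collapse = ", "), ")",
      if (!x$converged) " [not converged]", "\n", sep = "")
  invisible(x)
}

# Rotation matrix, ZYX convention: R = Rz %*% Ry %*% Rx.
rotation_matrix <- function(angles) {
  ca <- cos(angles); sa <- sin(angles)
  rx <- rbind(c(1, 0, 0), c(0, ca[1], -sa[1]), c(0, sa[1], ca[1]))
  ry <- rbind(c(ca[2], 0, sa[2]), c(0, 1, 0), c(-sa[2], 0, ca[2]))
  rz <- rbind(c(ca[3], -sa[3], 0), c(sa[3], ca[3], 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# Euler angles (ZYX) back out of a rotation matrix.
euler_from_matrix <- function(R) {
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal lock: fold everything into rx
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz)
}

# Apply the transform to an n x 3 matrix of physical points.
transform_points <- function(tr, pts) {
  pts <- matrix(pts, ncol = 3)
  R <- rotation_matrix(tr$rotation)
  sweep(tr$scale * (sweep(pts, 2, tr$center) %*% t(R)), 2,
        tr$center + tr$translation, "+")
}

#' Invert a similarity transform
#'
#' Returns the transform mapping the source space back onto the target, so
#' that `warp(warp(v, tr), invert(tr))` recovers `v` up to interpolation and
#' `invert(invert(tr))` equals `tr`.
#'
#' @param tr a [similarity_transform()].
#' @param original_grid [grid_spec()] of the space the inverse should
#'   resample onto (the moving image's grid); defaults to `tr$source_grid`.
#' @return A [similarity_transform()].
#' @export
invert_transform <- function(tr, original_grid = NULL) {
  if (is.null(original_grid)) original_grid <- tr$source_grid
  R <- rotation_matrix(tr$rotation)
  inv_scale <- 1 / tr$scale
  inv_rot <- euler_from_matrix(t(R))
  inv_trans <- as.vector(-inv_scale * t(R) %*% tr$translation)
  similarity_transform(scale = inv_scale, rotation = inv_rot,
                       translation = inv_trans, center = tr$center,
                       target_grid = original_grid,
                       source_grid = tr$target_grid,
                       converged = tr$converged)
}

# Composition: apply `inner` first, then `outer` (as point maps).
compose_transforms <- function(outer, inner) {
  Ro <- rotation_matrix(outer$rotation)
  Ri <- rotation_matrix(inner$rotation)
  Rc <- Ro %*% Ri
  s <- outer$scale * inner$scale
  t_new <- as.vector(outer$scale * Ro %*%
                       (inner$center + inner$translation - outer$center)) +
    outer$center + outer$translation - inner$center
  similarity_transform(scale = s, rotation = euler_from_matrix(Rc),
                       translation = t_new, center = inner$center,
                       target_grid = inner$target_grid,
                       source_grid = outer$source_grid,
                       converged = outer$converged && inner$converged)
}

identity_transform <- function(grid) {
  similarity_transform(target_grid = grid, source_grid = grid)
}

# Voxel-index affine (0-based): source index = A %*% target index + b.
index_affine <- function(tr, source_grid, target_grid) {
  R <- rotation_matrix(tr$rotation)
  M <- tr$scale * R
  A <- diag(1 / source_grid$spacing) %*% M %*% diag(target_grid$spacing)
  b <- (as.vector(M %*% (target_grid$origin - tr$center)) + tr$center +
          tr$translation - source_grid$origin) / source_grid$spacing
  list(A = A, b = b)
}

# Resample an arbitrary numeric array living on source_grid onto target_grid.
warp_field <- function(field, source_grid, target_grid, tr) {
  ab <- index_affine(tr, source_grid, target_grid)
  out <- cpp_resample_trilinear(as.numeric(field),
                                as.integer(source_grid$shape),
                                as.integer(target_grid$shape), ab$A, ab$b)
  array(out, target_grid$shape)
}

#' Warp a binary volume through a similarity transform
#'
#' Resamples `vol` onto the transform's target grid by trilinear
#' interpolation of the 0/1 occupancy, then re-binarizes at `threshold`.
#' Linear interpolation plus thresholding gives smoother warped surfaces than
#' nearest-neighbour sampling, which matters for the subtraction-based
#' implant borders downstream.
#'
#' @param vol a [binary_volume()].
#' @param tr a [similarity_transform()] with a `target_grid`.
#' @param threshold binarization threshold on the interpolated occupancy.
#' @return A [binary_volume()] on the target grid.
#' @export
warp <- function(vol, tr, threshold = 0.5) {
  stop_if_not_volume(vol, "vol")
  if (is.null(tr$target_grid))
    stop("transform has no target_grid", call. = FALSE)
  src <- grid_spec(vol)
  field <- warp_field(vol$data, src, tr$target_grid, tr)
  binary_volume(array(field > threshold, tr$target_grid$shape),
                spacing = tr$target_grid$spacing,
                origin = tr$target_grid$origin)
}

#' Serialize / restore a similarity transform
#'
#' Writes the 7 parameters plus the grids to a small JSON sidecar so a
#' completion run can be reproduced or inverted later.
#'
#' @param tr a [similarity_transform()].
#' @param path JSON file path.
#' @return `write_transform` returns `path` invisibly; `read_transform`
#'   returns the [similarity_transform()].
#' @export
write_transform <- function(tr, path) {
  grid_as_list <- function(g) if (is.null(g)) NULL else
    list(shape = g$shape, spacing = g$spacing, origin = g$origin)
  obj <- list(scale = tr$scale, rotation = tr$rotation,
              translation = tr$translation, center = tr$center,
              target_grid = grid_as_list(tr$target_grid),
              source_grid = grid_as_list(tr$source_grid),
              converged = tr$converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid_from_list <- function(g) if (is.null(g)) NULL else
    grid_spec(shape = g$shape, spacing = g$spacing, origin = g$origin)
  similarity_transform(scale = obj$scale, rotation = obj$rotation,
                       translation = obj$translation, center = obj$center,
                       target_grid = grid_from_list(obj$target_grid),
                       source_grid = grid_from_list(obj$source_grid),
                       converged = obj$converged)
}
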