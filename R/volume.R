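#' Binary voxel occupancy volume
#'
#' The package's central container: a 3D array of \{0,1\} voxel occupancy with
#' geometry metadata. Voxel indices are 1-based in R; the physical position of
#' voxel `(i, j, k)` is `origin + (c(i, j, k) - 1) * spacing` along each axis.
#' Arrays are stored in R's native column-major order, so the first index is
#' the fastest-varying axis; this same order is used whenever a volume is
#' flattened into a vector for shape-model algebra.
#'
#' @param data 3D array (or object coercible to one) of 0/1 occupancy. Logical
#'   and numeric inputs are accepted; numeric values must already be 0 or 1
#'   (use [read_volume()] or `as_binary = TRUE` to threshold arbitrary data).
#' @param spacing numeric length-3, voxel size in mm along each axis (> 0).
#' @param origin numeric length-3, physical position (mm) of voxel (1,1,1).
#' @param as_binary if `TRUE`, values > 0.5 are mapped to 1 and the rest to 0
#'   instead of erroring on non-binary input.
#' @return An object of class `binary_volume` with elements `data` (integer
#'   3D array of 0/1), `spacing` and `origin`.
#' @examples
#' v <- binary_volume(array(0L, c(4, 4, 4)))
#' dim(v$data)
#' @export
binary_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                          as_binary = FALSE) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("binary_volume expects a 3D array, got ", length(dim(data)),
         " dimensions", call. = FALSE)
  if (is.logical(data)) {
    data <- array(as.integer(data), dim(data))
  } else if (as_binary) {
    data <- array(as.integer(data > 0.5), dim(data))
  } else {
    if (anyNA(data) || any(data != 0 & data != 1))
      stop("volume data must be strictly binary (0/1); ",
           "set as_binary = TRUE or use read_volume() to threshold",
           call. = FALSE)
    data <- array(as.integer(data), dim(data))
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  cat("<binary_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing (", paste(format(x$spacing), collapse = ", "),
      ") mm, origin (", paste(format(x$origin), collapse = ", "),
      ") mm, foreground ", sum(x$data), " voxels\n", sep = "")
  invisible(x)
}

is_binary_volume <- function(x) inherits(x, "binary_volume")

stop_if_not_volume <- function(x, arg = "volume") {
  if (!is_binary_volume(x))
    stop(arg, " must be a binary_volume", call. = FALSE)
  invisible(x)
}

#' Grid specification of a volume
#'
#' The triple (shape, spacing, origin) that identifies the sampling grid of a
#' volume, used as the fixed/target space of transforms.
#'
#' @param vol a `binary_volume`, or pass `shape`/`spacing`/`origin` directly.
#' @param shape,spacing,origin grid components when `vol` is missing.
#' @return A list of class `grid_spec` with `shape`, `spacing`, `origin`.
#' @export
grid_spec <- function(vol = NULL, shape = NULL, spacing = c(1, 1, 1),
                      origin = c(0, 0, 0)) {
  if (!is.null(vol)) {
    stop_if_not_volume(vol)
    shape <- dim(vol$data)
    spacing <- vol$spacing
    origin <- vol$origin
  }
  if (is.null(shape) || length(shape) != 3L || any(shape < 1))
    stop("grid shape must be 3 integers >= 1", call. = FALSE)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 origin = as.numeric(origin)), class = "grid_spec")
}

same_grid <- function(a, b, tol = 1e-6) {
  ga <- if (inherits(a, "grid_spec")) a else grid_spec(a)
  gb <- if (inherits(b, "grid_spec")) b else grid_spec(b)
  identical(ga$shape, gb$shape) &&
    all(abs(ga$spacing - gb$spacing) < tol) &&
    all(abs(ga$origin - gb$origin) < tol)
}

#' Foreground voxel count and physical volume
#'
#' @param vol a `binary_volume`.
#' @return Named numeric vector with `voxels` (count) and `mm3`
#'   (count times the voxel volume).
#' @export
volume_stats <- function(vol) {
  stop_if_not_volume(vol)
  n <- sum(vol$data)
  c(voxels = n, mm3 = n * prod(vol$spacing))
}

# Flatten in the package's fixed (column-major) order.
flatten_volume <- function(vol) as.vector(vol$data)

# Rebuild a volume from a flat vector on a grid, binarizing at `threshold`.
unflatten_volume <- function(vec, grid, threshold = 0.5) {
  binary_volume(array(as.numeric(vec) > threshold, grid$shape),
                spacing = grid$spacing, origin = grid$origin)
}

# Elementwise set operations on same-grid volumes.
vol_and_not <- function(a, b) {  # a minus b, clamped at zero
  binary_volume(array(a$data == 1L & b$data == 0L, dim(a$data)),
                a$spacing, a$origin)
}

vol_union <- function(a, b) {
  binary_volume(array(a$data == 1L | b$data == 1L, dim(a$data)),
                a$spacing, a$origin)
}

vol_intersect <- function(a, b) {
  binary_volume(array(a$data == 1L & b$data == 1L, dim(a$data)),
                a$spacing, a$origin)
}

# Physical coordinates (mm) of the foreground centroid.
foreground_centroid <- function(vol) {
  idx <- which(vol$data == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("volume has no foreground voxels", call. = FALSE)
  vox <- unname(colMeans(idx)) - 1
  vol$origin + vox * vol$spacing
}
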