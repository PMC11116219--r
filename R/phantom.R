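#' Skull-phantom specification
#'
#' Parametric description of a hollow ellipsoidal shell standing in for a
#' complete cranial vault: an outer ellipsoid minus a concentric inner one,
#' optionally rotated, shifted, and decorated with a small solid "facial"
#' lobe that mimics the cranium-versus-face imbalance of real skull masks.
#' The cranium is structurally a smooth closed shell, so shells with
#' population variation in size, orientation and thickness exercise the same
#' geometry the shape model sees on real data.
#'
#' @param shape grid dimensions (voxels).
#' @param spacing voxel size in mm.
#' @param radii three outer semi-axes in voxels (kept distinct so the
#'   orientation of a phantom is well defined).
#' @param thickness shell thickness in voxels (>= 1).
#' @param rotation three rotation angles in radians.
#' @param translation shift of the shell centre from the grid centre, voxels.
#' @param facial_lobe if `TRUE`, attach a small solid ellipsoid at the +x
#'   pole of the shell.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                         radii = c(24, 20, 17), thickness = 5,
                         rotation = c(0, 0, 0), translation = c(0, 0, 0),
                         facial_lobe = FALSE) {
  radii <- as.numeric(radii)
  if (thickness < 1) stop("thickness must be >= 1 voxel", call. = FALSE)
  if (any(radii <= thickness))
    stop("radii must exceed the shell thickness", call. = FALSE)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 radii = radii, thickness = as.numeric(thickness),
                 rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 facial_lobe = isTRUE(facial_lobe)),
            class = "phantom_spec")
}

# Voxel-centre coordinates of a grid, centred on the grid midpoint, as an
# n x 3 matrix in voxel units.
centered_grid_coords <- function(shape) {
  mid <- (shape - 1) / 2
  xs <- seq_len(shape[1]) - 1 - mid[1]
  ys <- seq_len(shape[2]) - 1 - mid[2]
  zs <- seq_len(shape[3]) - 1 - mid[3]
  cbind(rep(xs, times = shape[2] * shape[3]),
        rep(rep(ys, each = shape[1]), times = shape[3]),
        rep(zs, each = shape[1] * shape[2]))
}

#' Generate a hollow-shell skull phantom
#'
#' @param spec a [phantom_spec()].
#' @return A [binary_volume()] on the spec's grid. Errors if the rotated,
#'   shifted shell does not fit inside the grid.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  R <- rotation_matrix(spec$rotation)
  # max extent of the rotated outer ellipsoid along each axis:
  # half-width_i = sqrt(sum_j (R[i,j] * r_j)^2)
  half <- sqrt((R^2) %*% (spec$radii^2))
  lim <- (spec$shape - 1) / 2
  if (any(half + abs(spec$translation) > lim))
    stop("phantom does not fit inside the grid; enlarge the grid or shrink ",
         "radii/translation", call. = FALSE)
  pts <- centered_grid_coords(spec$shape)
  pts <- sweep(pts, 2, spec$translation)
  # rotate grid points back into the ellipsoid's own frame
  local <- pts %*% R  # = t(t(R) %*% t(pts))
  outer_q <- (local[, 1] / spec$radii[1])^2 +
    (local[, 2] / spec$radii[2])^2 + (local[, 3] / spec$radii[3])^2
  ri <- spec$radii - spec$thickness
  inner_q <- (local[, 1] / ri[1])^2 + (local[, 2] / ri[2])^2 +
    (local[, 3] / ri[3])^2
  mask <- outer_q <= 1 & inner_q > 1
  if (spec$facial_lobe) {
    lobe_r <- pmax(2, spec$radii * 0.25)
    lobe_c <- c(spec$radii[1] + lobe_r[1] * 0.4, 0, 0)
    lq <- ((local[, 1] - lobe_c[1]) / lobe_r[1])^2 +
      ((local[, 2] - lobe_c[2]) / lobe_r[2])^2 +
      ((local[, 3] - lobe_c[3]) / lobe_r[3])^2
    mask <- mask | lq <= 1
  }
  binary_volume(array(mask, spec$shape), spacing = spec$spacing)
}

#' Generate a cohort of varied skull phantoms
#'
#' Samples `n` phantom specs around `base_spec` with inter-subject variation
#' in overall size (±7%, which similarity registration can absorb), per-axis
#' shape (±6%, which it cannot), shell thickness (±1 voxel), orientation (up
#' to ±8 degrees per axis) and position (up to ±3 voxels), mirroring the
#' variability of skull cohorts that register well under a similarity
#' transform. All randomness flows from `seed`; the same seed reproduces the
#' same cohort.
#'
#' @param n number of phantoms (>= 2).
#' @param base_spec a [phantom_spec()] giving the population mean.
#' @param seed integer seed.
#' @param size_spread,radius_sd,angle_max_deg,shift_max,thickness_jitter
#'   spread controls: global size factor range, per-axis relative jitter,
#'   max rotation per axis (degrees), max shift (voxels), thickness jitter
#'   (voxels).
#' @return A list of `n` [binary_volume()] objects.
#' @export
generate_cohort <- function(n, base_spec = phantom_spec(), seed = 1,
                            size_spread = 0.07, radius_sd = 0.03,
                            angle_max_deg = 8, shift_max = 3,
                            thickness_jitter = 1) {
  if (n < 2) stop("a cohort needs n >= 2 phantoms", call. = FALSE)
  rng <- local_rng(seed)
  lapply(seq_len(n), function(i) {
    size <- 1 + rng$unif(1, -size_spread, size_spread)
    radii <- base_spec$radii * size *
      pmin(1.06, pmax(0.94, 1 + rng$norm(3) * radius_sd))
    th <- max(2, base_spec$thickness +
                round(rng$unif(1, -thickness_jitter, thickness_jitter)))
    spec <- phantom_spec(
      shape = base_spec$shape, spacing = base_spec$spacing, radii = radii,
      thickness = th,
      rotation = rng$unif(3, -angle_max_deg, angle_max_deg) * pi / 180,
      translation = rng$unif(3, -shift_max, shift_max),
      facial_lobe = base_spec$facial_lobe)
    generate_phantom(spec)
  })
}

# Self-contained RNG so no global .Random.seed state leaks in or out.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, globalenv())
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    out
  }
  list(norm = function(n, sd = 1) draw(stats::rnorm, n, sd = sd),
       unif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max),
       int = function(n, max) draw(function(n, max) sample.int(max, n, replace = TRUE), n, max))
}

#' Defect specification
#'
#' Describes a synthetic cranial defect cut out of a complete phantom, with
#' a known ground-truth implant. Defect regions are spheres or cubes seated
#' on the shell; their size is calibrated so the removed bone is a stated
#' fraction of the total shell volume.
#'
#' @param kind one of `"sphere"`, `"cube"`, `"multi_lobe"`,
#'   `"border_crossing"`. `multi_lobe` places `count` disjoint spherical
#'   defects; `border_crossing` centres the defect on the superior (+z) pole
#'   so it straddles the crown the way clinical craniectomy defects straddle
#'   the skull midline.
#' @param size_fraction target implant volume as a fraction of the complete
#'   shape's foreground, in (0, 0.5).
#' @param count number of defects (>= 1), used by `multi_lobe`.
#' @param seed integer seed controlling where on the shell the defect sits.
#' @return A list of class `defect_spec`.
#' @export
defect_spec <- function(kind = c("sphere", "cube", "multi_lobe",
                                 "border_crossing"),
                        size_fraction = 0.1, count = 1, seed = 1) {
  kind <- match.arg(kind)
  if (size_fraction <= 0 || size_fraction >= 0.5)
    stop("size_fraction must be in (0, 0.5)", call. = FALSE)
  if (count < 1) stop("count must be >= 1", call. = FALSE)
  structure(list(kind = kind, size_fraction = size_fraction,
                 count = as.integer(count), seed = as.integer(seed)),
            class = "defect_spec")
}

# Region mask (logical vector over the grid) of a sphere/cube of half-width h
# (voxel units) centred at voxel-space point ctr.
defect_region <- function(shape, ctr, h, cube = FALSE) {
  pts <- centered_grid_coords(shape)
  mid <- (shape - 1) / 2
  d <- sweep(pts, 2, ctr - 1 - mid)
  if (cube) apply(abs(d) <= h, 1, all) else rowSums(d^2) <= h^2
}

# Bisect the region half-width until the removed volume hits the target
# fraction of the complete foreground (to within 2% relative), determinate.
calibrate_halfwidth <- function(complete_vec, shape, ctr, target, cube) {
  lo <- 0.5
  hi <- max(shape)
  total <- sum(complete_vec)
  for (i in 1:40) {
    h <- (lo + hi) / 2
    frac <- sum(complete_vec & defect_region(shape, ctr, h, cube)) / total
    if (abs(frac - target) < 0.02 * target) return(h)
    if (frac < target) lo <- h else hi <- h
  }
  (lo + hi) / 2
}

#' Cut a defect out of a complete shape
#'
#' Produces a defective shape and its ground-truth implant as an exact
#' partition of the complete shape: `defective` ∪ `implant` = `complete` and
#' `defective` ∩ `implant` = ∅, voxel for voxel.
#'
#' @param complete a non-empty [binary_volume()].
#' @param spec a [defect_spec()].
#' @return A list with `defective` and `implant`, both [binary_volume()]s on
#'   the input grid. Errors if the defect region misses the shape entirely.
#' @export
apply_defect <- function(complete, spec) {
  stop_if_not_volume(complete, "complete")
  stopifnot(inherits(spec, "defect_spec"))
  fg <- which(complete$data == 1L)
  if (length(fg) == 0L)
    stop("complete shape is empty", call. = FALSE)
  shape <- dim(complete$data)
  vec <- as.vector(complete$data) == 1L
  rng <- local_rng(spec$seed)
  n_lobes <- if (spec$kind == "multi_lobe") spec$count else 1L
  per_lobe <- spec$size_fraction / n_lobes
  region <- rep(FALSE, length(vec))
  fg_idx <- arrayInd(fg, shape)
  for (k in seq_len(n_lobes)) {
    if (spec$kind == "border_crossing") {
      # seat the defect at the superior pole of the shell
      top <- fg_idx[fg_idx[, 3] == max(fg_idx[, 3]), , drop = FALSE]
      ctr <- colMeans(top)
    } else {
      # pick a foreground voxel far from previously used centres
      pick <- fg_idx[rng$int(1, nrow(fg_idx)), ]
      if (k > 1L) {
        cand <- fg_idx[rng$int(25, nrow(fg_idx)), , drop = FALSE]
        prev <- attr(region, "centers")
        dmin <- apply(cand, 1, function(p)
          min(sqrt(colSums((t(prev) - p)^2))))
        pick <- cand[which.max(dmin), ]
      }
      ctr <- pick
    }
    h <- calibrate_halfwidth(vec, shape, ctr, per_lobe,
                             cube = spec$kind == "cube")
    lobe <- defect_region(shape, ctr, h, cube = spec$kind == "cube")
    centers <- rbind(attr(region, "centers"), ctr)
    region <- region | lobe
    attr(region, "centers") <- centers
  }
  implant_vec <- vec & region
  if (!any(implant_vec))
    stop("defect region does not intersect the shape", call. = FALSE)
  defective <- binary_volume(array(vec & !implant_vec, shape),
                             complete$spacing, complete$origin)
  implant <- binary_volume(array(implant_vec, shape),
                           complete$spacing, complete$origin)
  list(defective = defective, implant = implant)
}
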