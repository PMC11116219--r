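# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdir().

# Random blob mask: thresholded smoothed noise, reproducible per seed.
random_blob_volume <- function(shape = c(32, 32, 32), seed = 1,
                               spacing = c(1, 1, 1), fill = 0.25) {
  set.seed(seed)
  noise <- array(stats::rnorm(prod(shape)), shape)
  sm <- craniossm:::cpp_smooth_gaussian(as.numeric(noise), as.integer(shape),
                                        rep(2, 3))
  thr <- stats::quantile(sm, 1 - fill)
  binary_volume(array(sm > thr, shape), spacing = spacing)
}

# Sparse speckle mask.
random_sparse_volume <- function(shape = c(16, 16, 16), seed = 1,
                                 density = 0.05) {
  set.seed(seed)
  binary_volume(array(stats::runif(prod(shape)) < density, shape))
}

# Axis-aligned solid cuboid.
cuboid_volume <- function(shape, lo, hi, spacing = c(1, 1, 1)) {
  arr <- array(FALSE, shape)
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  binary_volume(arr, spacing = spacing)
}

# Small default phantom for fast tests.
small_phantom_spec <- function(...) {
  phantom_spec(shape = c(48, 48, 48), radii = c(17, 14, 12), thickness = 4,
               ...)
}

# Brute-force surface voxels: foreground with a background face neighbour
# (out-of-bounds is background). Returns an n x 3 index matrix (1-based).
brute_surface_indices <- function(vol) {
  d <- dim(vol$data)
  idx <- which(vol$data == 1L, arr.ind = TRUE)
  on_surface <- apply(idx, 1, function(p) {
    for (ax in 1:3) {
      for (s in c(-1L, 1L)) {
        q <- p
        q[ax] <- q[ax] + s
        if (q[ax] < 1L || q[ax] > d[ax]) return(TRUE)
        if (vol$data[q[1], q[2], q[3]] == 0L) return(TRUE)
      }
    }
    FALSE
  })
  idx[on_surface, , drop = FALSE]
}

# All-pairs directed surface distances in mm (brute force).
brute_directed_distances <- function(from_idx, to_idx, spacing) {
  from_mm <- sweep(from_idx - 1, 2, spacing, "*")
  to_mm <- sweep(to_idx - 1, 2, spacing, "*")
  apply(from_mm, 1, function(p) {
    sqrt(min(colSums((t(to_mm) - p)^2)))
  })
}

# Brute-force flood fill component count (26/18/6-connectivity).
brute_components <- function(vol, connectivity = 26) {
  d <- dim(vol$data)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  m <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6" = offs[m == 1, , drop = FALSE],
                 "18" = offs[m >= 1 & m <= 2, , drop = FALSE],
                 "26" = offs[m >= 1, , drop = FALSE])
  seen <- array(FALSE, d)
  sizes <- integer(0)
  fg <- which(vol$data == 1L, arr.ind = TRUE)
  for (r in seq_len(nrow(fg))) {
    p0 <- fg[r, ]
    if (seen[p0[1], p0[2], p0[3]]) next
    stack <- list(p0)
    seen[p0[1], p0[2], p0[3]] <- TRUE
    size <- 0L
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (any(q < 1L) || any(q > d)) next
        if (vol$data[q[1], q[2], q[3]] == 1L && !seen[q[1], q[2], q[3]]) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    sizes <- c(sizes, size)
  }
  list(count = length(sizes), sizes = sizes)
}

# Express a similarity transform as parameters about a chosen centre, so two
# transforms with different stored centres can be compared.
canonical_params <- function(tr, center) {
  R <- craniossm:::rotation_matrix(tr$rotation)
  M <- tr$scale * R
  offset <- as.vector(-M %*% tr$center) + tr$center + tr$translation
  list(scale = tr$scale,
       rotation = tr$rotation,
       translation = as.vector(M %*% center) + offset - center)
}
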