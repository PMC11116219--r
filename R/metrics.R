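#' Dice similarity coefficient
#'
#' Volumetric overlap `2|A∩B| / (|A| + |B|)` between two same-grid binary
#' masks. Two empty masks are defined to agree perfectly (DSC 1).
#'
#' @param a,b [binary_volume()]s on the same grid.
#' @return Scalar in \[0, 1\].
#' @export
dsc <- function(a, b) {
  stop_if_not_volume(a, "a"); stop_if_not_volume(b, "b")
  if (!same_grid(a, b))
    stop("masks are not on the same grid", call. = FALSE)
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0) return(1.0)
  2 * sum(a$data == 1L & b$data == 1L) / (na + nb)
}

# Surface voxels: foreground voxels with at least one background face
# neighbour (voxels outside the volume count as background).
surface_mask <- function(vol) {
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1), c(0, 0, 0))
  eroded <- cpp_neighborhood(as.integer(vol$data), dim(vol$data), offs, 1L)
  array(vol$data == 1L & eroded == 0L, dim(vol$data))
}

# Distances (mm) from each surface voxel of `from` to the nearest surface
# voxel of `to`, via an exact Euclidean distance transform of `to`'s surface.
directed_surface_distances <- function(surf_from, surf_to, spacing) {
  d <- cpp_edt(as.integer(surf_to), dim(surf_to), spacing)
  d[as.vector(surf_from)]
}

#' Border (surface) Dice at a distance tolerance
#'
#' Boundary-overlap score: the fraction of surface voxels of either mask that
#' lie within `tolerance_mm` of the other mask's surface,
#' `(matched_A + matched_B) / (|∂A| + |∂B|)`. Surfaces are face-connectivity
#' boundary voxels; distances are Euclidean in physical units. The tolerance
#' defaults to one voxel's physical size (the smallest spacing component).
#'
#' @param a,b [binary_volume()]s on the same grid.
#' @param tolerance_mm match tolerance in mm.
#' @return Scalar in \[0, 1\]; 1 when both masks are empty, 0 when exactly
#'   one is.
#' @export
border_dsc <- function(a, b, tolerance_mm = NULL) {
  stop_if_not_volume(a, "a"); stop_if_not_volume(b, "b")
  if (!same_grid(a, b))
    stop("masks are not on the same grid", call. = FALSE)
  if (is.null(tolerance_mm)) tolerance_mm <- min(a$spacing)
  sa <- surface_mask(a); sb <- surface_mask(b)
  na <- sum(sa); nb <- sum(sb)
  if (na + nb == 0) return(1.0)
  if (na == 0 || nb == 0) return(0.0)
  dab <- directed_surface_distances(sa, sb, a$spacing)
  dba <- directed_surface_distances(sb, sa, a$spacing)
  (sum(dab <= tolerance_mm) + sum(dba <= tolerance_mm)) / (na + nb)
}

#' 95th-percentile Hausdorff surface distance
#'
#' The 95th percentile of the pooled directed surface distances (A to B and
#' B to A together), in mm. Pooling the two directions before taking the
#' percentile makes the measure symmetric by construction; the percentile is
#' the standard empirical quantile (`stats::quantile`, type 7). An empty mask
#' gives `Inf` with a warning.
#'
#' @param a,b [binary_volume()]s on the same grid.
#' @param probs percentile level, default 0.95.
#' @return Distance in mm (0 for identical masks).
#' @export
hd95 <- function(a, b, probs = 0.95) {
  stop_if_not_volume(a, "a"); stop_if_not_volume(b, "b")
  if (!same_grid(a, b))
    stop("masks are not on the same grid", call. = FALSE)
  sa <- surface_mask(a); sb <- surface_mask(b)
  if (sum(sa) == 0 || sum(sb) == 0) {
    warning("empty mask: Hausdorff distance is infinite", call. = FALSE)
    return(Inf)
  }
  dab <- directed_surface_distances(sa, sb, a$spacing)
  dba <- directed_surface_distances(sb, sa, a$spacing)
  unname(stats::quantile(c(dab, dba), probs))
}

#' Evaluate a predicted mask against a ground-truth mask
#'
#' @param pred,truth [binary_volume()]s on the same grid.
#' @param tolerance_mm border-DSC tolerance (default: one voxel).
#' @return One-row `data.frame` with columns `dsc`, `bdsc`, `hd95`,
#'   `tolerance_mm`.
#' @export
evaluate_pair <- function(pred, truth, tolerance_mm = NULL) {
  if (is.null(tolerance_mm)) tolerance_mm <- min(truth$spacing)
  data.frame(dsc = dsc(pred, truth),
             bdsc = border_dsc(pred, truth, tolerance_mm),
             hd95 = hd95(pred, truth),
             tolerance_mm = tolerance_mm)
}

#' Evaluate folders of paired masks
#'
#' Pairs prediction and ground-truth files by filename stem (extension and a
#' trailing `_completed`/`_implant`/`_implant_raw` tag stripped) and scores
#' every pair, appending a `mean` row.
#'
#' @param pred_dir,truth_dir directories of `.nrrd`/`.nii[.gz]` masks, or two
#'   single files.
#' @param tolerance_mm border-DSC tolerance.
#' @return `data.frame` with one row per case plus a final `mean` row,
#'   columns `case`, `dsc`, `bdsc`, `hd95`.
#' @export
evaluate_cases <- function(pred_dir, truth_dir, tolerance_mm = NULL) {
  stem_of <- function(p) {
    s <- sub("\\.(nrrd|nhdr|nii|nii\\.gz)$", "", basename(p),
             ignore.case = TRUE)
    sub("_(completed|implant|implant_raw)$", "", s)
  }
  list_masks <- function(d) {
    if (file.exists(d) && !dir.exists(d)) return(d)
    list.files(d, pattern = "\\.(nrrd|nhdr|nii|nii\\.gz)$", full.names = TRUE,
               ignore.case = TRUE)
  }
  preds <- list_masks(pred_dir)
  truths <- list_masks(truth_dir)
  names(preds) <- vapply(preds, stem_of, character(1))
  names(truths) <- vapply(truths, stem_of, character(1))
  common <- intersect(names(preds), names(truths))
  if (length(common) == 0L)
    stop("no prediction/ground-truth pairs matched by filename stem",
         call. = FALSE)
  rows <- lapply(sort(common), function(s) {
    m <- evaluate_pair(read_volume(preds[[s]]), read_volume(truths[[s]]),
                       tolerance_mm)
    cbind(case = s, m[, c("dsc", "bdsc", "hd95")])
  })
  out <- do.call(rbind, rows)
  means <- vapply(out[, c("dsc", "bdsc", "hd95")], mean, numeric(1))
  rbind(out, data.frame(case = "mean", dsc = means[["dsc"]],
                        bdsc = means[["bdsc"]], hd95 = means[["hd95"]]))
}
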