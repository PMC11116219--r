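#' Completion results
#'
#' Both completion routes return a `completion_result` holding the defective
#' shape warped into the reference space (`warped_defective`), the estimated
#' missing part there (`missing_part`), their union (`completed_reference`),
#' and the completed shape and missing part carried back to the input's
#' original grid through the inverse transform (`completed_original`,
#' `missing_original`). By construction `missing_part` and `warped_defective`
#' are disjoint and union to `completed_reference`.
#'
#' @name completion_result
NULL

new_completion_result <- function(warped_defective, missing_part, transform,
                                  defective, method, template_label,
                                  threshold = 0.5) {
  completed_ref <- vol_union(warped_defective, missing_part)
  inv <- invert_transform(transform, grid_spec(defective))
  completed_original <- warp(completed_ref, inv, threshold)
  missing_original <- warp(missing_part, inv, threshold)
  structure(list(warped_defective = warped_defective,
                 missing_part = missing_part,
                 completed_reference = completed_ref,
                 completed_original = completed_original,
                 missing_original = missing_original,
                 transform = transform, method = method,
                 template = template_label),
            class = "completion_result")
}

#' @export
print.completion_result <- function(x, ...) {
  cat("<completion_result> method '", x$method, "' (template ", x$template,
      "); missing part ", sum(x$missing_part$data), " voxels\n", sep = "")
  invisible(x)
}

#' Complete a defective shape by template subtraction
#'
#' Registers the defective shape to a complete template, subtracts the warped
#' defective shape from the template (clamped at zero on the binary grids, so
#' the missing part is exactly the template voxels absent from the warped
#' input), and inverts the registration to return the completed shape in the
#' patient's original space.
#'
#' Because the defect itself biases the registration (the optimizer tries to
#' explain the hole by shrinking or shifting the shape), the registration can
#' be refined: after a first completion, the completed shape — which has no
#' hole — is re-registered to the template and the completion is recomputed
#' with the refined transform. One refinement pass (`passes = 2`, the
#' default) removes most of the defect-induced bias; the whole procedure
#' stays deterministic. When a pass finds only a negligible missing part
#' (below `refine_threshold` of the input volume) there is no defect bias to
#' correct and the remaining passes are skipped, so completing an
#' already-complete shape never degrades it.
#'
#' @param defective non-empty [binary_volume()].
#' @param template non-empty complete [binary_volume()]: a single reference
#'   shape or a binarized mean shape from [mean_template()].
#' @param config a [reg_config()].
#' @param passes number of registration passes (>= 1); passes beyond the
#'   first re-register the previous pass's completed shape.
#' @param refine_threshold missing-part volume fraction below which further
#'   passes are skipped.
#' @param template_label free-text tag recorded in the result.
#' @return A [completion_result].
#' @export
complete_by_template <- function(defective, template, config = reg_config(),
                                 passes = 2, refine_threshold = 0.05,
                                 template_label = "template") {
  stop_if_not_volume(defective, "defective")
  stop_if_not_volume(template, "template")
  tr <- register_similarity(defective, template, config)
  result <- NULL
  for (pass in seq_len(max(1, passes))) {
    if (pass > 1L) {
      if (sum(result$missing_part$data) <
            refine_threshold * sum(defective$data)) break
      tr <- register_similarity(result$completed_original, template, config)
    }
    y_warp <- warp(defective, tr)
    missing <- vol_and_not(template, y_warp)
    result <- new_completion_result(y_warp, missing, tr, defective,
                                    method = "template",
                                    template_label = template_label)
  }
  result
}

#' Complete a defective shape with the statistical shape model
#'
#' Registers the defective shape to the model's reference space (the pool's
#' reference member serves as the fixed image, the same shape every pool
#' member was registered to during model building), projects the warped
#' defective shape onto the variation modes, reconstructs the whole skull by
#' inverse PCA, and subtracts the warped defective shape from the
#' reconstruction to isolate the missing part. The completed shape is
#' returned in the original space via the inverted registration. The model
#' reconstructs the complete skull and never the implant directly, so the
#' procedure needs no example defects and is insensitive to the defect
#' pattern.
#'
#' As in [complete_by_template()], registration passes beyond the first
#' re-register the previous pass's (hole-free) completed shape to cancel the
#' defect-induced registration bias.
#'
#' @param defective non-empty [binary_volume()].
#' @param model a [fit_variations()] result.
#' @param config a [reg_config()].
#' @param threshold binarization threshold for the real-valued
#'   reconstruction before subtraction.
#' @param use_rescaled feed min-max rescaled weights (instead of raw PCA
#'   scores) into the reconstruction.
#' @param passes number of registration passes (>= 1).
#' @param refine_threshold missing-part volume fraction below which further
#'   passes are skipped.
#' @return A [completion_result]; its `weights` attribute carries the
#'   projected [shape_weights()] of the final pass.
#' @export
complete_by_ssm <- function(defective, model, config = reg_config(),
                            threshold = 0.5, use_rescaled = FALSE,
                            passes = 2, refine_threshold = 0.05) {
  stop_if_not_volume(defective, "defective")
  stopifnot(inherits(model, "shape_model"))
  fixed <- if (!is.null(model$reference)) model$reference else model$template
  tr <- register_similarity(defective, fixed, config)
  res <- NULL
  for (pass in seq_len(max(1, passes))) {
    if (pass > 1L) {
      if (sum(res$missing_part$data) <
            refine_threshold * sum(defective$data)) break
      tr <- register_similarity(res$completed_original, fixed, config)
    }
    y_warp <- warp(defective, tr)
    w <- project_shape(model, flatten_volume(y_warp))
    recon <- reconstruct_shape(model, w, mode = "inverse_pca",
                               threshold = threshold,
                               use_rescaled = use_rescaled)
    missing <- vol_and_not(recon, y_warp)
    res <- new_completion_result(y_warp, missing, tr, defective,
                                 method = "ssm",
                                 template_label = sprintf("SSM(d0=%d)",
                                                          model$n_components))
    attr(res, "weights") <- w
  }
  res
}

#' Write the artifacts of a completion run
#'
#' Writes the raw missing part (`<stem>_implant_raw`), the completed shape
#' (`<stem>_completed`) and the transform sidecar (`<stem>_transform.json`)
#' next to each other.
#'
#' @param result a [completion_result].
#' @param dir output directory (created if missing).
#' @param stem filename stem.
#' @param format `"nrrd"` or `"nii.gz"`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_completion <- function(result, dir, stem, format = "nrrd") {
  stopifnot(inherits(result, "completion_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- match.arg(format, c("nrrd", "nii.gz"))
  paths <- c(
    implant_raw = file.path(dir, paste0(stem, "_implant_raw.", ext)),
    completed = file.path(dir, paste0(stem, "_completed.", ext)),
    transform = file.path(dir, paste0(stem, "_transform.json"))
  )
  write_volume(result$missing_original, paths[["implant_raw"]])
  write_volume(result$completed_original, paths[["completed"]])
  write_transform(result$transform, paths[["transform"]])
  invisible(paths)
}
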