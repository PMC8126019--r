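# Assembly of the full radiomics feature vector.
#
# Per modality: 16 first-order + 16 LBP + 8 shape + 22 GLCM + 11 GLRLM +
# 256 SIFT = 329 values; four modalities give 1316.  The shape block is
# recomputed under each modality prefix (the printed battery counts 32
# geometry features); the underlying mask statistics are computed once and
# replicated.

#' Feature name registry
#'
#' The normative, ordered list of feature names for a given modality set.
#' Each name is `<modality>_<family>_<feature>`; families are `firstorder`,
#' `LBP`, `shape`, `GLCM`, `GLRLM`, `SIFT` in that order within each modality
#' block, modalities in canonical order.
#'
#' @param modalities Modality tags (default all four).
#' @return Data frame with columns `name`, `modality`, `family`, `feature`.
#' @export
feature_registry <- function(modalities = modality_tags()) {
  stopifnot(all(modalities %in% MODALITIES))
  modalities <- intersect(MODALITIES, modalities)
  block <- rbind(
    data.frame(family = "firstorder", feature = FIRSTORDER_NAMES),
    data.frame(family = "LBP", feature = paste0("LBP_", FIRSTORDER_NAMES)),
    data.frame(family = "shape", feature = SHAPE_NAMES),
    data.frame(family = "GLCM", feature = GLCM_NAMES),
    data.frame(family = "GLRLM", feature = GLRLM_NAMES),
    data.frame(family = "SIFT",
               feature = c(sprintf("SIFT_Mean_%03d", 1:128),
                           sprintf("SIFT_SD_%03d", 1:128))))
  out <- do.call(rbind, lapply(modalities, function(m)
    cbind(modality = m, block)))
  out$name <- paste(out$modality, out$family, out$feature, sep = "_")
  rownames(out) <- NULL
  out[, c("name", "modality", "family", "feature")]
}

#' Extract the full feature vector of one ROI instance
#'
#' @param roi A `roi_instance` from [extract_rois()].
#' @param n_levels Gray levels for discretization (default 64).
#' @return Named numeric vector, length `329 * n_modalities` (1316 for four
#'   modalities), ordered as in [feature_registry()]; all values finite.
#' @export
extract_all <- function(roi, n_levels = 64L) {
  stopifnot(inherits(roi, "roi_instance"))
  mods <- names(roi$patches)
  shp <- shape_features(roi$mask, roi$voxel_spacing)
  out <- numeric(0)
  for (m in mods) {
    patch <- roi$patches[[m]]
    slices <- roi_slices(roi, m)
    if (!length(slices))
      stop("ROI ", roi$subject_id, "/", roi$region_label,
           " has no slice with enough pixels")
    tm <- texture_matrices(slices, n_levels = n_levels)
    block <- c(firstorder_features(patch, n_levels),
               lbp_features(slices),
               shp,
               glcm_features(tm),
               glrlm_features(tm),
               sift_features(slices))
    names(block) <- paste(m, c(rep("firstorder", 16), rep("LBP", 16),
                               rep("shape", 8), rep("GLCM", 22),
                               rep("GLRLM", 11), rep("SIFT", 256)),
                          names(block), sep = "_")
    out <- c(out, block)
  }
  if (any(!is.finite(out))) {
    bad <- names(out)[!is.finite(out)]
    stop("non-finite feature value(s) for ", roi$subject_id, "/",
         roi$region_label, ": ", paste(utils::head(bad, 5), collapse = ", "))
  }
  out
}

#' Extract the feature table of a cohort
#'
#' One row per (subject, region) ROI instance; columns `subject_id`,
#' `region_label`, then the named features in registry order.
#'
#' @param samples List of `mp_sample` objects.
#' @param n_levels Gray levels for discretization.
#' @param min_voxels,min_slice_voxels ROI size thresholds, see
#'   [extract_rois()].
#' @param verbose Print progress.
#' @return Data frame feature table.
#' @export
extract_cohort_features <- function(samples, n_levels = 64L,
                                    min_voxels = 10L, min_slice_voxels = 5L,
                                    verbose = FALSE) {
  rows <- list()
  for (s in samples) {
    rois <- extract_rois(s, min_voxels, min_slice_voxels)
    for (roi in rois) {
      fv <- extract_all(roi, n_levels)
      rows[[length(rows) + 1L]] <-
        c(list(subject_id = roi$subject_id, region_label = roi$region_label),
          as.list(fv))
      if (verbose)
        message("extracted ", roi$subject_id, "/", roi$region_label)
    }
  }
  if (!length(rows)) return(data.frame())
  nm <- names(rows[[1L]])
  stopifnot(all(vapply(rows, function(r) identical(names(r), nm), TRUE)))
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Split a feature table into matrix and labels
#'
#' @param features Feature table from [extract_cohort_features()].
#' @return List with numeric matrix `x` (rownames `subject_id/region`) and
#'   factor `y` of region labels in anatomical order.
#' @export
feature_matrix <- function(features) {
  meta <- c("subject_id", "region_label")
  x <- as.matrix(features[, setdiff(names(features), meta), drop = FALSE])
  rownames(x) <- paste(features$subject_id, features$region_label, sep = "/")
  y <- factor(features$region_label, levels = names(REGIONS))
  list(x = x, y = y)
}
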