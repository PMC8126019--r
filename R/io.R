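# Sample container, NIfTI IO, ROI extraction and gray-level discretization.

#' Construct and validate a multiparametric sample
#'
#' @param subject_id Subject identifier string.
#' @param modalities Named list of 3-D numeric arrays; names from
#'   [modality_tags()]. All arrays must share one shape.
#' @param label_mask 3-D integer array with codes 0 (background) and 1-4
#'   (necrosis, solid, peritumoral, edema); codes outside 0-4 are rejected.
#' @param voxel_spacing Numeric length-3, mm per axis.
#' @return An object of class `mp_sample`.
#' @export
new_mp_sample <- function(subject_id, modalities, label_mask,
                          voxel_spacing = c(1, 1, 1)) {
  if (is.null(names(modalities)) || !all(names(modalities) %in% MODALITIES))
    stop("modalities must be named with tags among: ",
         paste(MODALITIES, collapse = ", "))
  if (length(modalities) < 1L) stop("at least one modality is required")
  d <- dim(modalities[[1L]])
  if (length(d) != 3L) stop("modality volumes must be 3-D arrays")
  for (nm in names(modalities)) {
    if (!identical(dim(modalities[[nm]]), d))
      stop("modality '", nm, "' shape differs from the others")
  }
  if (!identical(dim(label_mask), d))
    stop("label mask shape differs from the modality volumes")
  codes <- sort(unique(as.integer(label_mask)))
  bad <- setdiff(codes, 0:4)
  if (length(bad))
    stop("label mask contains unknown code(s): ", paste(bad, collapse = ", "))
  storage.mode(label_mask) <- "integer"
  structure(list(subject_id = as.character(subject_id),
                 modalities = modalities[intersect(MODALITIES, names(modalities))],
                 label_mask = label_mask,
                 voxel_spacing = as.numeric(voxel_spacing)),
            class = "mp_sample")
}

#' @export
print.mp_sample <- function(x, ...) {
  d <- dim(x$label_mask)
  cat("Multiparametric sample", x$subject_id, "\n")
  cat("  volume:", paste(d, collapse = " x "), "voxels, spacing",
      paste(x$voxel_spacing, collapse = " x "), "mm\n")
  cat("  modalities:", paste(names(x$modalities), collapse = ", "), "\n")
  tab <- table(factor(x$label_mask[x$label_mask > 0], levels = 1:4,
                      labels = names(REGIONS)))
  cat("  region voxels:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a cohort to NIfTI + manifest
#'
#' One `.nii.gz` per modality plus one label-mask `.nii.gz` per subject, and a
#' cohort manifest CSV (`subject_id`, one path column per modality, `mask`).
#'
#' @param samples List of `mp_sample` objects.
#' @param dir Output directory (created if missing).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mods <- names(samples[[1L]]$modalities)
  rows <- lapply(samples, function(s) {
    paths <- character(0)
    for (m in mods) {
      p <- file.path(dir, paste0(s$subject_id, "_", m, ".nii.gz"))
      img <- RNifti::asNifti(s$modalities[[m]],
                             pixdim = s$voxel_spacing, datatype = "double")
      RNifti::writeNifti(img, p)
      paths[m] <- p
    }
    pm <- file.path(dir, paste0(s$subject_id, "_mask.nii.gz"))
    img <- RNifti::asNifti(s$label_mask, pixdim = s$voxel_spacing,
                           datatype = "int16")
    RNifti::writeNifti(img, pm)
    c(subject_id = s$subject_id, paths, mask = pm)
  })
  manifest <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Load one sample from a manifest row
#'
#' @param entry Named list/one-row data frame with `subject_id`, a path per
#'   modality tag, and `mask`.
#' @param modalities Modality tags to load (default: all tags present in
#'   `entry`). With `allow_missing = FALSE`, a requested-but-absent modality is
#'   an error; with `TRUE` a degraded-mode sample with the available
#'   modalities is returned (e.g. TCIA-style cohorts lacking ADC).
#' @param allow_missing Logical, see above.
#' @return A validated `mp_sample`.
#' @export
load_sample <- function(entry, modalities = NULL, allow_missing = FALSE) {
  entry <- as.list(entry)
  present <- intersect(MODALITIES, names(entry))
  present <- present[!is.na(unlist(entry[present])) &
                       nzchar(unlist(entry[present]))]
  if (is.null(modalities)) modalities <- present
  missing <- setdiff(modalities, present)
  if (length(missing)) {
    if (!allow_missing)
      stop("missing modality file(s) for ", entry$subject_id, ": ",
           paste(missing, collapse = ", "))
    warning("sample ", entry$subject_id, " lacks modality(ies) ",
            paste(missing, collapse = ", "), "; loading degraded sample")
    modalities <- setdiff(modalities, missing)
  }
  if (!length(modalities)) stop("no modality left to load")
  vols <- lapply(entry[modalities], function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    v <- RNifti::readNifti(p)
    array(as.numeric(v), dim = dim(v))
  })
  maskimg <- RNifti::readNifti(entry$mask)
  spacing <- RNifti::pixdim(maskimg)[1:3]
  mask <- array(as.integer(maskimg), dim = dim(maskimg))
  new_mp_sample(entry$subject_id, vols, mask, spacing)
}

#' Extract per-region ROI instances from a sample
#'
#' One instance per region present with at least `min_voxels` voxels; smaller
#' regions are skipped with a warning. Axial slices (third axis) of the
#' cropped region with at least `min_slice_voxels` in-mask pixels form the
#' instance's slice list used by 2-D texture and SIFT features.
#'
#' @param sample A `mp_sample`.
#' @param min_voxels Minimum 3-D voxel count per region (default 10).
#' @param min_slice_voxels Minimum in-plane pixel count per slice (default 5).
#' @return List of `roi_instance` objects (possibly empty): each has
#'   `subject_id`, `region_label`, cropped logical `mask`, per-modality cropped
#'   arrays with `NA` outside the region (`patches`), and `voxel_spacing`.
#' @export
extract_rois <- function(sample, min_voxels = 10L, min_slice_voxels = 5L) {
  stopifnot(inherits(sample, "mp_sample"))
  out <- list()
  for (r in seq_along(REGIONS)) {
    sel <- sample$label_mask == r
    n <- sum(sel)
    if (n == 0L) next
    if (n < min_voxels) {
      warning("region '", names(REGIONS)[r], "' of ", sample$subject_id,
              " has ", n, " voxel(s) < min_voxels = ", min_voxels,
              "; skipped")
      next
    }
    idx <- which(sel, arr.ind = TRUE)
    rng <- apply(idx, 2, range)
    sub <- function(a) a[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                         rng[1, 3]:rng[2, 3], drop = FALSE]
    cmask <- sub(sel)
    patches <- lapply(sample$modalities, function(v) {
      p <- sub(v)
      p[!cmask] <- NA_real_
      p
    })
    out[[length(out) + 1L]] <- structure(
      list(subject_id = sample$subject_id,
           region_label = names(REGIONS)[r],
           region_code = r,
           mask = cmask,
           patches = patches,
           min_slice_voxels = as.integer(min_slice_voxels),
           voxel_spacing = sample$voxel_spacing),
      class = "roi_instance")
  }
  out
}

# Axial slices of one modality patch with enough in-mask pixels.
roi_slices <- function(roi, modality) {
  p <- roi$patches[[modality]]
  keep <- which(apply(!is.na(p), 3, sum) >= roi$min_slice_voxels)
  lapply(keep, function(k) p[, , k, drop = TRUE])
}

#' Discretize intensities to gray levels
#'
#' Fixed-bin-count discretization over the observed (non-`NA`) range: the
#' minimum maps to level 1, the maximum to `n_levels`; a constant input maps
#' entirely to level 1. Monotone: input ordering is preserved.
#'
#' @param x Numeric vector, matrix or array (NA = outside ROI).
#' @param n_levels Number of gray levels (default 64).
#' @return Integer levels in `1..n_levels`, same shape as `x`, `NA` preserved.
#' @export
discretize <- function(x, n_levels = 64L) {
  stopifnot(n_levels >= 2L)
  v <- x[!is.na(x)]
  if (!length(v)) stop("cannot discretize an empty patch")
  lo <- min(v); hi <- max(v)
  out <- x
  if (hi == lo) {
    out[!is.na(out)] <- 1L
  } else {
    lev <- floor((x - lo) / (hi - lo) * n_levels) + 1L
    lev[lev > n_levels] <- n_levels
    out <- lev
  }
  storage.mode(out) <- "integer"
  out
}
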