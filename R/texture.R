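# Gray-level co-occurrence and run-length texture matrices and features.
#
# Texture is computed slice-wise (clinical MRI is anisotropic through-plane):
# distance-1 offsets at 0/45/90/135 degrees within each axial slice, counts
# accumulated symmetrically and pooled over slices per direction, normalised
# per direction, features averaged over the four directions.  The direction
# set is closed under 90-degree in-plane rotation.

TEXTURE_DIRECTIONS <- list(d0 = c(0L, 1L), d45 = c(1L, 1L),
                           d90 = c(1L, 0L), d135 = c(1L, -1L))

GLCM_NAMES <- c("Autocorrelation", "JointAverage", "ClusterProminence",
                "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
                "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
                "Dissimilarity", "Energy", "Entropy", "Homogeneity1",
                "Homogeneity2", "IMC1", "IMC2", "IDMN", "IDN",
                "InverseVariance", "MaximumProbability", "SumEntropy")

GLRLM_NAMES <- c("SRE", "LRE", "GLN", "RLN", "RP", "LGLRE", "HGLRE",
                 "SRLGLE", "SRHGLE", "LRLGLE", "LRHGLE")

# Symmetric pair counts of one discretized slice for one (dr, dc) offset.
glcm_counts_slice <- function(lev, offset, n_levels) {
  nr <- nrow(lev); nc <- ncol(lev)
  dr <- offset[1]; dc <- offset[2]
  C <- matrix(0, n_levels, n_levels)
  rlo <- max(1L, 1L - dr); rhi <- min(nr, nr - dr)
  clo <- max(1L, 1L - dc); chi <- min(nc, nc - dc)
  if (rlo > rhi || clo > chi) return(C)
  r0 <- rlo:rhi; c0 <- clo:chi
  a <- lev[r0, c0, drop = FALSE]
  b <- lev[r0 + dr, c0 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(C)
  code <- (a[ok] - 1L) * n_levels + b[ok]
  cnt <- tabulate(code, nbins = n_levels^2)
  C <- matrix(cnt, n_levels, n_levels, byrow = TRUE)
  C + t(C)
}

# Maximal same-level runs along one direction of a discretized slice.
# Returns a count matrix n_levels x max_len.  NA pixels break runs; every
# in-mask pixel belongs to exactly one run per direction.
glrlm_counts_slice <- function(lev, offset, n_levels, max_len) {
  lines <- switch(paste(offset, collapse = ","),
    "0,1" = lapply(seq_len(nrow(lev)), function(i) lev[i, ]),
    "1,0" = lapply(seq_len(ncol(lev)), function(j) lev[, j]),
    "1,1" = {
      idx <- row(lev) - col(lev)
      split(lev[order(idx, row(lev))], sort(idx))
    },
    "1,-1" = {
      idx <- row(lev) + col(lev)
      split(lev[order(idx, row(lev))], sort(idx))
    },
    stop("unsupported offset"))
  R <- matrix(0, n_levels, max_len)
  for (v in lines) {
    v <- as.integer(v)
    if (!length(v)) next
    r <- rle(ifelse(is.na(v), -1L, v))
    keep <- r$values > 0L
    if (!any(keep)) next
    g <- r$values[keep]; l <- pmin(r$lengths[keep], max_len)
    for (q in seq_along(g)) R[g[q], l[q]] <- R[g[q], l[q]] + 1
  }
  R
}

#' Build texture matrices from ROI slices
#'
#' Discretizes the pooled slice intensities to `n_levels` gray levels (unless
#' `discretize_input = FALSE`, in which case values must already be integer
#' levels), then accumulates, per direction, the symmetric distance-1 GLCM and
#' the run-length matrix over all slices.
#'
#' @param slices List of 2-D matrices with `NA` outside the ROI.
#' @param n_levels Number of gray levels (default 64).
#' @param discretize_input Discretize intensities first (default `TRUE`).
#' @return An object of class `texture_matrices`: per-direction normalised
#'   symmetric `glcm` (entries sum to 1; all-zero when a direction has no
#'   pair), per-direction `glrlm` count matrices, `n_voxels` (in-mask pixels
#'   of the aggregated planes), `n_levels`, `directions`.
#' @export
texture_matrices <- function(slices, n_levels = 64L, discretize_input = TRUE) {
  stopifnot(length(slices) >= 1L)
  if (discretize_input) {
    pooled <- unlist(lapply(slices, as.numeric))
    lo <- min(pooled, na.rm = TRUE); hi <- max(pooled, na.rm = TRUE)
    slices <- lapply(slices, function(s) {
      if (hi == lo) {
        out <- s; out[!is.na(out)] <- 1L
      } else {
        out <- floor((s - lo) / (hi - lo) * n_levels) + 1L
        out[out > n_levels] <- n_levels
      }
      storage.mode(out) <- "integer"
      out
    })
  } else {
    slices <- lapply(slices, function(s) { storage.mode(s) <- "integer"; s })
    if (max(unlist(slices), na.rm = TRUE) > n_levels)
      stop("pre-discretized levels exceed n_levels")
  }
  max_len <- max(vapply(slices, function(s) max(dim(s)), 1L))
  nvox <- sum(vapply(slices, function(s) sum(!is.na(s)), 1L))
  glcm <- list(); glrlm <- list()
  for (dn in names(TEXTURE_DIRECTIONS)) {
    off <- TEXTURE_DIRECTIONS[[dn]]
    C <- matrix(0, n_levels, n_levels)
    R <- matrix(0, n_levels, max_len)
    for (s in slices) {
      C <- C + glcm_counts_slice(s, off, n_levels)
      R <- R + glrlm_counts_slice(s, off, n_levels, max_len)
    }
    if (sum(C) > 0) C <- C / sum(C)
    glcm[[dn]] <- C
    glrlm[[dn]] <- R
  }
  structure(list(glcm = glcm, glrlm = glrlm, n_levels = n_levels,
                 n_voxels = nvox, directions = TEXTURE_DIRECTIONS),
            class = "texture_matrices")
}

# 22 Haralick-family statistics of one normalised symmetric GLCM.
glcm_stats_single <- function(P) {
  L <- nrow(P)
  if (sum(P) == 0) P[1, 1] <- 1  # degenerate direction: treat as constant
  i <- seq_len(L)
  px <- rowSums(P)                      # symmetric: px == py
  mu <- sum(i * px)
  sigma2 <- sum((i - mu)^2 * px)
  ii <- matrix(i, L, L); jj <- t(ii)
  # difference and sum distributions
  dmat <- abs(ii - jj); smat <- ii + jj
  pd <- vapply(0:(L - 1), function(k) sum(P[dmat == k]), 0)
  ps <- vapply(2:(2 * L), function(k) sum(P[smat == k]), 0)
  kd <- 0:(L - 1)
  da <- sum(kd * pd)
  HX <- shannon_entropy(px)
  HXY <- shannon_entropy(P)
  pxpy <- px[ii] * px[jj]
  nz <- pxpy > 0
  HXY1 <- -sum(P[nz] * log2(pxpy[nz]))
  HXY2 <- -sum(pxpy[nz] * log2(pxpy[nz]))
  imc1 <- if (HX > 0) (HXY - HXY1) / HX else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * log(2) * (HXY2 - HXY))))
  corr <- if (sigma2 > 0) (sum(ii * jj * P) - mu^2) / sigma2 else 0
  offd <- dmat > 0
  out <- c(
    Autocorrelation = sum(ii * jj * P),
    JointAverage = mu,
    ClusterProminence = sum((ii + jj - 2 * mu)^4 * P),
    ClusterShade = sum((ii + jj - 2 * mu)^3 * P),
    ClusterTendency = sum((ii + jj - 2 * mu)^2 * P),
    Contrast = sum((ii - jj)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = shannon_entropy(pd),
    DifferenceVariance = sum((kd - da)^2 * pd),
    Dissimilarity = sum(dmat * P),
    Energy = sum(P^2),
    Entropy = HXY,
    Homogeneity1 = sum(P / (1 + dmat)),
    Homogeneity2 = sum(P / (1 + dmat^2)),
    IMC1 = imc1,
    IMC2 = imc2,
    IDMN = sum(P / (1 + dmat^2 / L^2)),
    IDN = sum(P / (1 + dmat / L)),
    InverseVariance = sum(P[offd] / dmat[offd]^2),
    MaximumProbability = max(P),
    SumEntropy = shannon_entropy(ps))
  out
}

#' GLCM texture features
#'
#' The 22 co-occurrence statistics (entropies in bits), computed per direction
#' and averaged over the four in-plane directions. Zero-variance convention:
#' correlation and IMC1 are 0 when their denominators vanish.
#'
#' @param tm A [texture_matrices()] object.
#' @param directions Direction names to average over (default all four);
#'   directions with no voxel pair are skipped.
#' @return Named numeric vector of length 22.
#' @export
glcm_features <- function(tm, directions = names(TEXTURE_DIRECTIONS)) {
  stopifnot(inherits(tm, "texture_matrices"))
  mats <- tm$glcm[directions]
  nonempty <- vapply(mats, function(P) sum(P) > 0, TRUE)
  if (any(nonempty)) mats <- mats[nonempty]
  per_dir <- vapply(mats, glcm_stats_single, numeric(length(GLCM_NAMES)))
  out <- rowMeans(per_dir)
  names(out) <- GLCM_NAMES
  out
}

# 11 classic run-length statistics of one count matrix.
glrlm_stats_single <- function(R, n_voxels) {
  Nr <- sum(R)
  if (Nr == 0) return(stats::setNames(numeric(11), GLRLM_NAMES))
  g <- seq_len(nrow(R)); l <- seq_len(ncol(R))
  gg <- matrix(g, nrow(R), ncol(R)); ll <- t(matrix(l, ncol(R), nrow(R)))
  rg <- rowSums(R); rl <- colSums(R)
  out <- c(
    SRE = sum(R / ll^2) / Nr,
    LRE = sum(R * ll^2) / Nr,
    GLN = sum(rg^2) / Nr,
    RLN = sum(rl^2) / Nr,
    RP = Nr / n_voxels,
    LGLRE = sum(R / gg^2) / Nr,
    HGLRE = sum(R * gg^2) / Nr,
    SRLGLE = sum(R / (gg^2 * ll^2)) / Nr,
    SRHGLE = sum(R * gg^2 / ll^2) / Nr,
    LRLGLE = sum(R * ll^2 / gg^2) / Nr,
    LRHGLE = sum(R * gg^2 * ll^2) / Nr)
  out
}

#' GLRLM texture features
#'
#' The 11 classic run statistics (SRE, LRE, GLN, RLN, RP, LGLRE, HGLRE,
#' SRLGLE, SRHGLE, LRLGLE, LRHGLE), per direction, averaged over the four
#' in-plane directions.
#'
#' @param tm A [texture_matrices()] object.
#' @param directions Direction names to average over (default all four).
#' @return Named numeric vector of length 11.
#' @export
glrlm_features <- function(tm, directions = names(TEXTURE_DIRECTIONS)) {
  stopifnot(inherits(tm, "texture_matrices"))
  per_dir <- vapply(tm$glrlm[directions], glrlm_stats_single, numeric(11),
                    n_voxels = tm$n_voxels)
  out <- rowMeans(per_dir)
  names(out) <- GLRLM_NAMES
  out
}
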