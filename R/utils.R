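#' @keywords internal
"_PACKAGE"

# Canonical modality and region orders used throughout the package.
MODALITIES <- c("T1CE", "T2W", "FLAIR", "ADC")
REGIONS <- c(necrosis = 1L, solid = 2L, peritumoral = 3L, edema = 4L)

#' Region label codes
#'
#' The integer codes used in label masks: 0 background, 1 necrosis, 2 solid
#' part, 3 peritumoral tissue, 4 peritumoral edema.
#'
#' @return Named integer vector mapping region name to mask code.
#' @export
region_codes <- function() REGIONS

#' Modality tags in canonical order
#'
#' @return Character vector `c("T1CE", "T2W", "FLAIR", "ADC")`.
#' @export
modality_tags <- function() MODALITIES

# Discrete Gaussian kernel, truncated at +/- 4 sd (sd in sample units).
gaussian_kernel <- function(sd) {
  if (sd <= 0) return(1)
  r <- max(1L, ceiling(4 * sd))
  k <- exp(-(seq(-r, r))^2 / (2 * sd^2))
  k / sum(k)
}

# n x n banded smoothing matrix for 1-D Gaussian convolution with truncated
# (renormalised at interior, raw at edges is avoided by row renormalisation)
# kernel.  Rows sum to 1 so region means are preserved near edges.
smoothing_matrix <- function(n, sd) {
  if (sd <= 0) return(diag(n))
  k <- gaussian_kernel(sd)
  r <- (length(k) - 1L) / 2L
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    S[i, j[ok]] <- k[ok]
    S[i, ] <- S[i, ] / sum(S[i, ])
  }
  S
}

# Apply a matrix linearly along one axis of a 3-D array.
apply_along_axis <- function(x, S, axis) {
  d <- dim(x)
  perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                 `3` = c(3L, 1L, 2L))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- S %*% matrix(xp, nrow = dp[1L])
  xp <- array(m, dp)
  aperm(xp, order(perm))
}

# Separable Gaussian smoothing of a 3-D array; sd per axis in voxels.
smooth_gaussian3d <- function(x, sd) {
  sd <- rep_len(sd, 3L)
  d <- dim(x)
  for (ax in 1:3) {
    if (sd[ax] > 0) x <- apply_along_axis(x, smoothing_matrix(d[ax], sd[ax]), ax)
  }
  x
}

# Separable Gaussian blur of a 2-D matrix.
smooth_gaussian2d <- function(x, sd) {
  if (sd <= 0) return(x)
  S1 <- smoothing_matrix(nrow(x), sd)
  S2 <- smoothing_matrix(ncol(x), sd)
  S1 %*% x %*% t(S2)
}

# Shannon entropy (bits) of a probability vector; 0 log 0 := 0.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Derive a per-subject seed below 2^31 from a base seed and an index.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483629)
}
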