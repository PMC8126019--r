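# Synthetic multiparametric phantom cohorts.
#
# Each phantom subject is four nested ellipsoidal shells (necrosis innermost,
# then solid part, peritumoral tissue, peritumoral edema) embedded in a
# background, imaged in four modalities (T1CE, T2W, FLAIR, ADC).  Every
# region x modality has its own intensity profile: mean, noise standard
# deviation, texture correlation length (voxels) and histogram skew.  Texture
# is produced by Gaussian smoothing of white noise with a region-specific
# kernel width, which gives the co-occurrence / run-length / LBP features a
# real signal to detect.

#' Default region intensity profiles
#'
#' Per-region, per-modality profile parameters for the phantom generator.
#' Means follow the qualitative contrast logic of glioblastoma MRI: necrosis
#' dark and edema intermediate on contrast-enhanced T1, edema bright on
#' T2/FLAIR, and ADC means inverted relative to T1-CE (necrosis brightest on
#' ADC) so the four modality blocks are not redundant copies of one another.
#' Units are arbitrary scanner units.
#'
#' @return A list of four 4x4 matrices (`mean`, `sd`, `clen`, `skew`), rows =
#'   regions (necrosis, solid, peritumoral, edema), columns = modalities.
#' @export
default_region_profiles <- function() {
  rn <- names(REGIONS)
  m <- function(...) {
    x <- matrix(c(...), nrow = 4, byrow = TRUE,
                dimnames = list(rn, MODALITIES))
    x
  }
  list(
    #        T1CE  T2W  FLAIR ADC
    mean = m(30,   70,  35,   85,    # necrosis
             80,   55,  60,   40,    # solid part
             55,   65,  70,   55,    # peritumoral tissue
             40,   80,  85,   70),   # peritumoral edema
    sd   = m(8,    8,   7,    9,
             7,    6,   6,    7,
             6,    7,   6,    6,
             9,    8,   8,    8),
    clen = m(2.5,  2.5, 2.2,  2.5,
             1.0,  1.0, 1.0,  1.0,
             1.8,  1.6, 1.8,  1.6,
             3.0,  3.0, 2.8,  3.0),
    skew = m(0.0,  0.0, 0.0,  0.0,
             0.4,  0.4, 0.4,  0.4,
             -0.3, -0.3, -0.3, -0.3,
             0.6,  0.6, 0.6,  0.6)
  )
}

#' Specify a phantom cohort
#'
#' @param grid_shape Integer vector of voxel counts per axis.
#' @param center Tumor center in voxel coordinates.
#' @param semi_axes 4x3 matrix of ellipsoid semi-axes (voxels), one row per
#'   shell from innermost (necrosis) to outermost (edema); must be strictly
#'   increasing down each column so the shells nest.
#' @param region_profiles Profile list as from [default_region_profiles()].
#' @param separation Scalar in \[0, 1\] scaling inter-region profile
#'   differences; 0 makes all four regions statistically identical (profiles
#'   collapse to their across-region mean and the label-to-shell assignment is
#'   randomised), 1 gives the full default contrast with anatomical nesting.
#' @param n_subjects Number of subjects in the cohort.
#' @param voxel_spacing Voxel spacing in mm per axis.
#' @param jitter Logical; jitter geometry per subject (uniform +/-10% on
#'   semi-axes, +/-2 voxels on center) so shape features vary across subjects.
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 32L),
                         center = grid_shape / 2,
                         semi_axes = rbind(necrosis    = c(6, 5, 4),
                                           solid       = c(11, 10, 7),
                                           peritumoral = c(16, 14, 10),
                                           edema       = c(22, 20, 13)),
                         region_profiles = default_region_profiles(),
                         separation = 1,
                         n_subjects = 23L,
                         voxel_spacing = c(1, 1, 1),
                         jitter = TRUE,
                         seed = 42L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8),
            length(center) == 3L, nrow(semi_axes) == 4L,
            ncol(semi_axes) == 3L, length(voxel_spacing) == 3L,
            all(voxel_spacing > 0), length(seed) == 1L)
  if (!is.numeric(separation) || length(separation) != 1L ||
      separation < 0 || separation > 1)
    stop("`separation` must be a scalar in [0, 1]")
  if (any(semi_axes <= 0)) stop("all semi-axes must be positive")
  if (any(apply(semi_axes, 2, diff) <= 0))
    stop("shells must be strictly nested: semi-axes must increase outward")
  for (nm in c("mean", "sd", "clen", "skew")) {
    p <- region_profiles[[nm]]
    stopifnot(is.matrix(p), nrow(p) == 4L, ncol(p) == 4L)
  }
  structure(list(grid_shape = as.integer(grid_shape), center = center,
                 semi_axes = semi_axes, region_profiles = region_profiles,
                 separation = separation, n_subjects = as.integer(n_subjects),
                 voxel_spacing = voxel_spacing, jitter = isTRUE(jitter),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Interpolate a profile matrix toward its across-region column mean:
# separation 0 collapses all regions onto the common profile.
.interp_profile <- function(p, separation) {
  common <- matrix(colMeans(p), nrow = nrow(p), ncol = ncol(p), byrow = TRUE)
  common + separation * (p - common)
}

# Marginal skewing transform: standardised lognormal in z, mean 0, variance 1,
# skewness increasing with `a`; identity at a = 0.
.skew_transform <- function(z, a) {
  if (abs(a) < 1e-8) return(z)
  s <- sign(a); a <- abs(a)
  v <- (exp(a * z * s) - exp(a^2 / 2)) / sqrt(exp(a^2) * (exp(a^2) - 1))
  v * s
}

# Correlated unit-variance noise field: smoothed white noise, renormalised by
# the theoretical interior variance reduction of the truncated kernel.
.texture_field <- function(dims, clen) {
  z <- array(stats::rnorm(prod(dims)), dims)
  if (clen <= 0) return(z)
  z <- smooth_gaussian3d(z, clen)
  k <- gaussian_kernel(clen)
  z / sqrt(sum(k^2))^3
}

#' Generate one phantom subject
#'
#' Deterministic given `(spec$seed, subject_index)`.  Each region's voxels are
#' drawn as a spatially correlated (Gaussian-smoothed white noise), optionally
#' skewed field added to the region mean, with all profile parameters
#' interpolated toward the across-region mean by `1 - separation`.  With
#' probability `1 - separation` the subject's label-to-shell assignment is a
#' random permutation, so at `separation = 0` the region labels carry no
#' geometric information either.
#'
#' @param spec A [phantom_spec()].
#' @param subject_index 1-based subject index, `<= spec$n_subjects`.
#' @return A `mp_sample` object: `subject_id`, named list `modalities` of 3-D
#'   arrays, integer `label_mask` (0 background, 1-4 regions), `voxel_spacing`.
#' @export
generate_phantom <- function(spec, subject_index = 1L) {
  stopifnot(inherits(spec, "phantom_spec"),
            subject_index >= 1L, subject_index <= spec$n_subjects)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(spec$seed, subject_index))

  d <- spec$grid_shape
  axes <- spec$semi_axes
  ctr <- spec$center
  if (spec$jitter) {
    axes <- axes * matrix(stats::runif(12, 0.9, 1.1), 4, 3)
    ctr <- ctr + stats::runif(3, -2, 2)
    if (any(apply(axes, 2, diff) <= 0))
      stop("jittered shells are no longer nested; widen the shell gaps")
  }
  # label-to-shell assignment (shell 1 = innermost)
  perm <- if (stats::runif(1) < 1 - spec$separation) sample(4L) else 1:4

  # rasterize: innermost shell containing each voxel
  cx <- seq_len(d[1]); cy <- seq_len(d[2]); cz <- seq_len(d[3])
  shell_id <- array(0L, d)
  for (s in 4:1) {
    q <- outer(outer(((cx - ctr[1]) / axes[s, 1])^2,
                     ((cy - ctr[2]) / axes[s, 2])^2, "+"),
               ((cz - ctr[3]) / axes[s, 3])^2, "+")
    shell_id[q <= 1] <- s
  }
  mask <- array(0L, d)
  for (s in 1:4) mask[shell_id == s] <- perm[s]
  for (r in 1:4) {
    if (!any(mask == r))
      stop("degenerate geometry: region '", names(REGIONS)[r],
           "' is empty after rasterization")
  }

  prof <- spec$region_profiles
  mean_m <- .interp_profile(prof$mean, spec$separation)
  sd_m   <- .interp_profile(prof$sd,   spec$separation)
  clen_m <- .interp_profile(prof$clen, spec$separation)
  skew_m <- .interp_profile(prof$skew, spec$separation)

  modalities <- vector("list", length(MODALITIES))
  names(modalities) <- MODALITIES
  for (m in seq_along(MODALITIES)) {
    # background: dim, weakly textured, unaffected by separation
    vol <- 10 + 5 * .texture_field(d, 1.0)
    for (r in 1:4) {
      f <- .texture_field(d, clen_m[r, m])
      f <- .skew_transform(f, skew_m[r, m])
      sel <- mask == r
      vol[sel] <- mean_m[r, m] + sd_m[r, m] * f[sel]
    }
    modalities[[m]] <- vol
  }

  new_mp_sample(subject_id = sprintf("S%03d", subject_index),
                modalities = modalities, label_mask = mask,
                voxel_spacing = spec$voxel_spacing)
}

#' Generate a phantom cohort
#'
#' @param spec A [phantom_spec()] with `n_subjects >= 2` (leave-one-out
#'   cross-validation is undefined for a single subject).
#' @return List of `mp_sample` objects, reproducible from `spec$seed`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$n_subjects < 2L)
    stop("n_subjects must be >= 2 (leave-one-out cross-validation undefined)")
  lapply(seq_len(spec$n_subjects), function(i) generate_phantom(spec, i))
}

# Save/restore the global RNG state so generators are pure functions of their
# seeds and do not disturb the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
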