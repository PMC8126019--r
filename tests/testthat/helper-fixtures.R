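# Shared fixtures, built in code and cached for the duration of the run.

.fixtures <- new.env(parent = emptyenv())

small_spec <- function(n_subjects = 6L, separation = 1, seed = 11L) {
  phantom_spec(grid_shape = c(40L, 40L, 24L), center = c(20, 20, 12),
               semi_axes = rbind(necrosis    = c(4, 4, 3),
                                 solid       = c(8, 7, 5),
                                 peritumoral = c(11, 10, 7),
                                 edema       = c(15, 13, 9)),
               n_subjects = n_subjects, separation = separation, seed = seed)
}

small_sample <- function() {
  if (is.null(.fixtures$sample))
    .fixtures$sample <- generate_phantom(small_spec(), 1L)
  .fixtures$sample
}

small_rois <- function() {
  if (is.null(.fixtures$rois))
    .fixtures$rois <- extract_rois(small_sample())
  .fixtures$rois
}

small_feature_table <- function() {
  if (is.null(.fixtures$features)) {
    coh <- generate_cohort(small_spec())
    .fixtures$features <- suppressWarnings(extract_cohort_features(coh))
  }
  .fixtures$features
}

# Well-separated 2-class Gaussian toy data.
toy_gaussians <- function(n_per = 10L, sep = 10, p = 5L, seed = 3L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = sep), n_per, p))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = rep(c("necrosis", "solid"), each = n_per))
}
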