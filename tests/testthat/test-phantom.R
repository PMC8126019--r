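test_that("generation is deterministic given (seed, subject_index)", {
  spec <- small_spec()
  a <- generate_phantom(spec, 2L)
  b <- generate_phantom(spec, 2L)
  expect_identical(a, b)
  coh <- generate_cohort(small_spec(n_subjects = 3L))
  expect_identical(coh[[2L]], generate_phantom(small_spec(n_subjects = 3L), 2L))
})

test_that("every generated sample contains all four region codes", {
  for (i in 1:3) {
    s <- generate_phantom(small_spec(), i)
    expect_setequal(unique(as.integer(s$label_mask)), 0:4)
    expect_true(all(vapply(1:4, function(r) sum(s$label_mask == r) > 0, TRUE)))
  }
})

test_that("cohort size and LOOCV precondition are enforced", {
  coh <- generate_cohort(small_spec(n_subjects = 23L))
  expect_length(coh, 23L)
  expect_true(all(vapply(coh, function(s)
    length(unique(s$label_mask[s$label_mask > 0])) == 4L, TRUE)))
  expect_error(generate_cohort(small_spec(n_subjects = 1L)), "n_subjects")
})

test_that("spec validation rejects bad geometry and separation", {
  expect_error(phantom_spec(separation = 1.5), "separation")
  expect_error(phantom_spec(semi_axes = rbind(c(5, 5, 5), c(4, 6, 6),
                                              c(10, 10, 10), c(12, 12, 12))),
               "nested")
  expect_error(phantom_spec(semi_axes = rbind(c(-1, 2, 2), c(3, 3, 3),
                                              c(5, 5, 5), c(7, 7, 7))),
               "positive")
})

test_that("separation=0 with zero noise collapses all regions to one value", {
  prof <- default_region_profiles()
  prof$sd[] <- 0
  spec <- phantom_spec(grid_shape = c(32L, 32L, 20L), center = c(16, 16, 10),
                       semi_axes = rbind(c(4, 4, 3), c(7, 6, 5),
                                         c(10, 9, 7), c(13, 12, 9)),
                       region_profiles = prof, separation = 0,
                       n_subjects = 2L, seed = 4L)
  s <- generate_phantom(spec, 1L)
  for (m in modality_tags()) {
    vals <- lapply(1:4, function(r) unique(s$modalities[[m]][s$label_mask == r]))
    expect_true(all(vapply(vals, length, 1L) == 1L))
    expect_equal(length(unique(unlist(vals))), 1L)
  }
})

test_that("region sample means follow the declared profiles at separation=1", {
  spec <- small_spec(n_subjects = 12L, seed = 21L)
  coh <- generate_cohort(spec)
  prof <- default_region_profiles()
  for (m in seq_along(modality_tags())) {
    mn <- sapply(coh, function(s) vapply(1:4, function(r)
      mean(s$modalities[[m]][s$label_mask == r]), 0))
    est <- rowMeans(mn)
    se <- apply(mn, 1, stats::sd) / sqrt(ncol(mn))
    expect_true(all(abs(est - prof$mean[, m]) < 3 * pmax(se, 1e-6)))
    expect_identical(order(est), order(prof$mean[, m]))
  }
})

test_that("autocorrelation length increases with the correlation-length knob", {
  # empirical lag-1 autocorrelation of 2-D slices grows with clen
  acf1 <- function(clen, seed) {
    set.seed(seed)
    f <- habitomics:::.texture_field(c(48L, 48L, 3L), clen)
    s <- f[, , 2]
    stats::cor(as.vector(s[-1, ]), as.vector(s[-nrow(s), ]))
  }
  vals <- vapply(c(0.5, 1.5, 3), function(cl)
    mean(vapply(1:5, function(sd) acf1(cl, sd), 0)), 0)
  expect_true(all(diff(vals) > 0))
})

test_that("voxelwise mean and variance match the profile at large n", {
  spec <- small_spec(seed = 31L)
  s <- generate_phantom(spec, 1L)
  prof <- default_region_profiles()
  # edema: largest region, >10^3 voxels
  v <- s$modalities$T2W[s$label_mask == 4L]
  expect_gt(length(v), 1000)
  expect_lt(abs(mean(v) - prof$mean[4, "T2W"]) / prof$mean[4, "T2W"], 0.1)
  expect_lt(abs(stats::sd(v) - prof$sd[4, "T2W"]) / prof$sd[4, "T2W"], 0.25)
})
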