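dirs <- habitomics:::TEXTURE_DIRECTIONS

test_that("GLCM/GLRLM match brute-force enumeration on random 6x6 images", {
  set.seed(101)
  for (rep in 1:40) {
    img <- matrix(sample(1:4, 36, replace = TRUE), 6, 6)
    if (rep > 30) img[sample(36, 5)] <- NA  # masked variants
    tm <- texture_matrices(list(img), n_levels = 4L,
                           discretize_input = FALSE)
    for (dn in names(dirs)) {
      P <- naive_glcm(img, dirs[[dn]], 4L)
      expect_lt(max(abs(tm$glcm[[dn]] - P)), 1e-12)
      got <- glcm_features(tm, directions = dn)
      want <- naive_glcm_features(P)
      expect_lt(max(abs(got - want[names(got)])), 1e-10)
      R <- naive_glrlm(img, dirs[[dn]], 4L, ncol(tm$glrlm[[dn]]))
      expect_identical(unname(tm$glrlm[[dn]]), unname(R))
      gotr <- glrlm_features(tm, directions = dn)
      wantr <- naive_glrlm_features(R, sum(!is.na(img)))
      expect_lt(max(abs(gotr - wantr[names(gotr)])), 1e-10)
    }
  }
})

test_that("GLCM is symmetric, normalised, and conserves GLRLM mass", {
  set.seed(7)
  slices <- lapply(1:3, function(i) matrix(rnorm(100), 10, 10))
  tm <- texture_matrices(slices, n_levels = 8L)
  for (dn in names(dirs)) {
    expect_equal(sum(tm$glcm[[dn]]), 1, tolerance = 1e-12)
    expect_equal(tm$glcm[[dn]], t(tm$glcm[[dn]]))
    R <- tm$glrlm[[dn]]
    lens <- matrix(seq_len(ncol(R)), nrow(R), ncol(R), byrow = TRUE)
    expect_equal(sum(R * lens), tm$n_voxels)
  }
})

test_that("constant patch: contrast 0, energy 1, entropy 0, homogeneity 1", {
  tm <- texture_matrices(list(matrix(2.5, 5, 5)))
  f <- glcm_features(tm)
  expect_equal(unname(f[c("Contrast", "Entropy")]), c(0, 0))
  expect_equal(unname(f[c("Energy", "Homogeneity1", "Correlation")]),
               c(1, 1, 0))
})

test_that("strict checkerboard has GLCM correlation -1 at 0 degrees", {
  img <- outer(1:8, 1:8, function(r, c) (r + c) %% 2 + 1)
  tm <- texture_matrices(list(img), n_levels = 2L, discretize_input = FALSE)
  f <- glcm_features(tm, directions = "d0")
  expect_equal(unname(f["Correlation"]), -1)
  expect_equal(unname(f["Contrast"]), 1)  # |1-2|^2 everywhere
})

test_that("run-length closed forms: constant and alternating 1xN lines", {
  N <- 12L
  tm <- texture_matrices(list(matrix(1L, 1, N)), n_levels = 2L,
                         discretize_input = FALSE)
  f0 <- glrlm_features(tm, directions = "d0")
  expect_equal(unname(f0["LRE"]), N^2)
  expect_equal(unname(f0["RP"]), 1 / N)
  alt <- matrix(rep(c(1L, 2L), length.out = N), 1, N)
  tma <- texture_matrices(list(alt), n_levels = 2L, discretize_input = FALSE)
  fa <- glrlm_features(tma, directions = "d0")
  expect_equal(unname(fa["SRE"]), 1)
  expect_equal(unname(fa["RP"]), 1)
})

test_that("rotating a slice by 90 degrees leaves averaged features unchanged", {
  set.seed(33)
  img <- matrix(sample(1:6, 81, replace = TRUE), 9, 9)
  rot <- t(img[nrow(img):1, ])
  f1 <- glcm_features(texture_matrices(list(img), 6L,
                                       discretize_input = FALSE))
  f2 <- glcm_features(texture_matrices(list(rot), 6L,
                                       discretize_input = FALSE))
  expect_equal(f1, f2, tolerance = 1e-12)
  g1 <- glrlm_features(texture_matrices(list(img), 6L,
                                        discretize_input = FALSE))
  g2 <- glrlm_features(texture_matrices(list(rot), 6L,
                                        discretize_input = FALSE))
  expect_equal(g1, g2, tolerance = 1e-12)
})
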