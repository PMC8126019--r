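planted_data <- function(n_per = 10L, shift = 5, p_noise = 100L, seed = 1L) {
  set.seed(seed)
  n <- n_per * 4L
  x <- matrix(rnorm(n * p_noise), n, p_noise)
  planted <- rnorm(n) + shift * rep(0:3, each = n_per)
  x <- cbind(planted = planted, x)
  colnames(x) <- c("planted", paste0("noise", seq_len(p_noise)))
  list(x = x, y = rep(names(region_codes()), each = n_per))
}

test_that("a planted 5-sigma feature ranks first and scores sum to 1", {
  d <- planted_data()
  imp <- rank_importance(d$x, d$y, n_seeds = 5L, top_k = 20L, seed = 2L)
  expect_equal(sum(imp$ranking$score), 1, tolerance = 1e-9)
  expect_equal(imp$ranking$name[1], "planted")
  expect_length(imp$top_k, 20L)
  expect_identical(imp$ranking$rank, seq_len(ncol(d$x)))
  expect_true(all(diff(imp$ranking$score) <= 1e-12))
})

test_that("all-noise features have no dominant importance score", {
  set.seed(9)
  x <- matrix(rnorm(48 * 60), 48, 60)
  colnames(x) <- paste0("noise", 1:60)
  y <- rep(names(region_codes()), each = 12L)
  imp <- rank_importance(x, y, n_seeds = 5L, seed = 3L)
  # permutation check: the top score should be comparable to the null spread
  expect_lt(imp$ranking$score[1], 5 / ncol(x))
})

test_that("importance ranking is deterministic given the seed", {
  d <- planted_data(n_per = 6L)
  a <- rank_importance(d$x, d$y, n_seeds = 3L, seed = 7L)
  b <- rank_importance(d$x, d$y, n_seeds = 3L, seed = 7L)
  expect_identical(a$ranking, b$ranking)
})

test_that("correlation with the ordinal region label behaves as expected", {
  y <- rep(names(region_codes()), each = 5L)
  lab <- as.numeric(region_codes()[y])
  set.seed(4)
  x <- cbind(linear = lab,
             mono = exp(lab),
             noise = rnorm(20))
  cs <- correlation_matrix(x, y, "spearman")
  expect_equal(unname(cs$r["linear", "region"]), 1, tolerance = 1e-12)
  expect_equal(unname(cs$r["mono", "region"]), 1, tolerance = 1e-12)
  cp <- correlation_matrix(x, y, "pearson")
  expect_lt(cp$r["mono", "region"], 1)
  expect_gt(cp$r["mono", "region"], 0)
  expect_equal(cp$r, t(cp$r))
  expect_equal(unname(diag(cp$r)), rep(1, 4))
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(15)
  x <- rnorm(30); y <- x + rnorm(30)
  labels <- rep(names(region_codes()), length.out = 30)
  a <- correlation_matrix(cbind(f = x, g = y), labels, "spearman")
  b <- correlation_matrix(cbind(f = exp(2 * x), g = y^3 + 5 * y), labels,
                          "spearman")
  expect_equal(a$r["f", "g"], b$r["f", "g"], tolerance = 1e-12)
})

test_that("Pearson matches hand-computed covariance over sigma products", {
  x <- c(1, 2, 4, 7, 11); y <- c(2, 1, 5, 8, 9)
  labels <- rep(names(region_codes()), length.out = 5)
  cm <- correlation_matrix(cbind(a = x, b = y), labels, "pearson")
  expect_equal(unname(cm$r["a", "b"]), naive_pearson(x, y),
               tolerance = 1e-12)
})

test_that("zero-variance features are flagged with coefficient 0", {
  labels <- rep(names(region_codes()), each = 3L)
  x <- cbind(const = rep(2, 12), ok = rnorm(12))
  cm <- correlation_matrix(x, labels, "pearson")
  expect_true("const" %in% cm$flagged)
  expect_equal(unname(cm$r["const", "ok"]), 0)
  expect_equal(unname(cm$r["const", "const"]), 1)
})

test_that("heatmap rendering is a pure function of the matrix", {
  labels <- rep(names(region_codes()), each = 3L)
  set.seed(5)
  cm <- correlation_matrix(matrix(rnorm(36), 12, 3,
                                  dimnames = list(NULL, c("a", "b", "c"))),
                           labels, "pearson")
  f <- withr::local_tempfile(fileext = ".png")
  out <- plot_correlation_heatmap(cm, file = f)
  expect_identical(out$r, cm$r)
  expect_true(file.exists(f) && file.size(f) > 0)
})
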