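test_that("well-separated Gaussian classes reach accuracy 1 with 1-NN", {
  d <- toy_gaussians()
  cv <- habitat_loocv(d$x, d$y, "knn", list(k = 1L), seed = 2L)
  expect_equal(cv$metrics$overall_accuracy, 1)
  expect_true(all(rowSums(cv$probs) == 1))
})

test_that("permuted labels score within the binomial interval of chance", {
  # n large enough that the well-known pessimistic bias of leave-one-out on
  # label-free data is small against the binomial width
  set.seed(42)
  n <- 80L
  x <- matrix(rnorm(n * 10), n, 10)
  colnames(x) <- paste0("f", 1:10)
  y <- sample(rep(names(region_codes()), each = n / 4))
  cv <- habitat_loocv(x, y, "random_forest", list(num_trees = 200L),
                      seed = 3L)
  p <- 1 / 4
  half <- 1.96 * sqrt(p * (1 - p) / n)
  expect_gte(cv$metrics$overall_accuracy, p - half - 1e-9)
  expect_lte(cv$metrics$overall_accuracy, p + half + 1e-9)
})

test_that("LOOCV is reproducible from the seed for every family", {
  d <- toy_gaussians(n_per = 6L, sep = 2)
  for (fam in c("random_forest", "knn", "naive_bayes", "mlp")) {
    params <- if (fam == "mlp") list(hidden = c(8L, 4L), max_epochs = 50L)
              else list()
    a <- habitat_loocv(d$x, d$y, fam, params, seed = 9L)
    b <- habitat_loocv(d$x, d$y, fam, params, seed = 9L)
    expect_identical(a$probs, b$probs)
    expect_identical(a$predictions, b$predictions)
  }
})

test_that("every sample is predicted exactly once, probabilities sum to 1", {
  d <- toy_gaussians(n_per = 8L, sep = 3)
  cv <- habitat_loocv(d$x, d$y, "naive_bayes", seed = 1L)
  expect_equal(nrow(cv$probs), 16L)
  expect_equal(unname(rowSums(cv$probs)), rep(1, 16L), tolerance = 1e-9)
  expect_equal(sum(cv$confusion), 16L)
})

test_that("fold preprocessing never uses the held-out row (no leakage)", {
  d <- toy_gaussians(n_per = 6L, sep = 3)
  cv1 <- habitat_loocv(d$x, d$y, "knn", list(k = 3L), seed = 4L)
  x2 <- d$x
  x2[5, ] <- x2[5, ] + 1000  # corrupt one row
  cv2 <- habitat_loocv(x2, d$y, "knn", list(k = 3L), seed = 4L)
  # fold 5's training stats exclude row 5, so they must be unchanged
  expect_equal(cv1$fold_centers[5, ], cv2$fold_centers[5, ])
  # every other fold trains on row 5 and must see the corruption
  expect_false(isTRUE(all.equal(cv1$fold_centers[1, ], cv2$fold_centers[1, ])))
})

test_that("a training fold missing a class is scored on remaining classes", {
  x <- matrix(rnorm(20), 10, 2)
  colnames(x) <- c("a", "b")
  y <- c("necrosis", rep(c("solid", "edema"), length.out = 9))
  expect_message(cv <- habitat_loocv(x, y, "knn", list(k = 3L), seed = 1L),
                 "lacks class")
  expect_equal(unname(cv$probs[1, "necrosis"]), 0)
})

test_that("canonical grids cover the conventional search ranges", {
  g <- default_grid("knn")
  expect_equal(g$k, 1:30)
  expect_setequal(g$metric, c("euclidean", "manhattan", "minkowski"))
  gr <- default_grid("random_forest")
  expect_equal(gr$mtry, seq(100L, 2000L, by = 100L))
  expect_equal(gr$max_depth, seq(0L, 110L, by = 10L))
})

test_that("grid search picks the only point, caps mtry, prefers first tie", {
  d <- toy_gaussians(n_per = 5L, sep = 8)
  g1 <- grid_search(d$x, d$y, "knn", list(k = 3L, metric = "euclidean"),
                    seed = 1L)
  expect_equal(g1$best$k, 3L)
  g2 <- grid_search(d$x, d$y, "random_forest",
                    list(mtry = c(100L, 200L), num_trees = 30L), seed = 1L)
  expect_true(all(g2$results$mtry <= ncol(d$x)))
  # separable data: both points reach accuracy 1; first declared point wins
  expect_equal(g2$best$mtry, min(ncol(d$x), 100L))
})

test_that("grid search recovers k=1 when only the nearest neighbour helps", {
  # 12 twin-pairs on a line, class alternating between adjacent pairs: the
  # nearest neighbour (the twin) always matches, the next two neighbours come
  # from adjacent opposite-class pairs, so k=3 provably misclassifies
  set.seed(6)
  ctr <- 100 * (1:12)
  base <- cbind(ctr, ctr) + matrix(rnorm(24, sd = 0.01), 12, 2)
  twin <- base + 0.01
  x <- rbind(base, twin)
  colnames(x) <- c("u", "v")
  y <- rep(rep(c("necrosis", "solid"), 6), 2)
  g <- grid_search(x, y, "knn", list(k = c(1L, 3L), metric = "euclidean"),
                   seed = 1L)
  expect_equal(g$best$k, 1L)
})

test_that("metrics follow the one-vs-rest formulas", {
  cm <- matrix(c(9, 1, 0, 0,
                 1, 85, 2, 1,
                 0, 0, 0, 0,
                 0, 1, 0, 0), 4, 4, byrow = TRUE,
               dimnames = list(names(region_codes()), names(region_codes())))
  r <- metrics_from_confusion(cm)
  k1 <- r$per_class[1, ]  # TP=9 FN=1 FP=1 TN=89
  expect_equal(k1$recall, 0.90)
  expect_equal(k1$precision, 0.90)
  expect_equal(k1$f1, 0.90)
  expect_equal(k1$accuracy, 0.98)
  # empty class: zero denominators reported as 0 and flagged
  k3 <- r$per_class[3, ]
  expect_equal(c(k3$recall, k3$precision, k3$f1), c(0, 0, 0))
  expect_true(k3$degenerate)
  expect_equal(r$overall_accuracy, sum(diag(cm)) / sum(cm))
})

test_that("perfect and all-one-class predictors hit the closed forms", {
  perfect <- diag(5, 4)
  rownames(perfect) <- colnames(perfect) <- names(region_codes())
  rp <- metrics_from_confusion(perfect)
  expect_true(all(rp$per_class[, c("recall", "precision", "f1",
                                   "accuracy")] == 1))
  allnec <- matrix(0, 4, 4,
                   dimnames = list(names(region_codes()),
                                   names(region_codes())))
  allnec[, 1] <- 10
  ra <- metrics_from_confusion(allnec)
  expect_equal(ra$per_class$recall, c(1, 0, 0, 0))
  expect_equal(ra$per_class$precision[1], 0.25)
})

test_that("AUC equals brute-force concordant-pair counting", {
  set.seed(12)
  for (rep in 1:20) {
    sc <- round(runif(6), 1)  # small set with ties
    pos <- sample(c(TRUE, FALSE), 6, replace = TRUE)
    if (!any(pos) || all(pos)) next
    expect_equal(habitomics:::auc_rank(sc, pos), naive_auc(sc, pos))
  }
  expect_equal(habitomics:::auc_rank(1:6, c(rep(FALSE, 3), rep(TRUE, 3))), 1)
  expect_equal(habitomics:::auc_rank(rep(1, 6),
                                     c(rep(FALSE, 3), rep(TRUE, 3))), 0.5)
})

test_that("multiclass AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  probs <- matrix(runif(40 * 2), 40, 2)
  probs <- probs / rowSums(probs)
  colnames(probs) <- c("necrosis", "solid")
  labels <- sample(c("necrosis", "solid"), 40, replace = TRUE)
  ours <- roc_auc(probs, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels == "necrosis",
                                        probs[, "necrosis"], quiet = TRUE,
                                        direction = "<")))
  expect_equal(unname(ours["necrosis"]), ref, tolerance = 1e-12)
})

test_that("majority vote follows the 50% threshold and probability tie-break", {
  expect_equal(majority_vote(c("A", "A", "B")), "A")
  expect_equal(majority_vote(c("B", "B", "B")), "B")
  probs <- rbind(c(A = 0.6, B = 0.4), c(A = 0.6, B = 0.4))
  expect_equal(majority_vote(c("A", "B"), probs), "A")
  probs2 <- rbind(c(A = 0.1, B = 0.9), c(A = 0.6, B = 0.4))
  expect_equal(majority_vote(c("A", "B"), probs2), "B")
})

test_that("ROC curve runs from (1,1) to (0,0) and is monotone", {
  set.seed(14)
  sc <- rnorm(20); pos <- sc + rnorm(20) > 0
  rc <- roc_curve(sc, pos)
  expect_equal(rc$fpr[1], 1); expect_equal(rc$tpr[1], 1)
  expect_equal(rc$fpr[nrow(rc)], 0); expect_equal(rc$tpr[nrow(rc)], 0)
  expect_true(all(diff(rc$fpr) <= 0) && all(diff(rc$tpr) <= 0))
})
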