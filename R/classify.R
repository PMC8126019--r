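# Classifier families, leave-one-out cross-validation and grid search.
#
# Four learner families are compared: k-nearest neighbours (hand-rolled so
# manhattan/minkowski metrics and full class-probability vectors are
# available), Gaussian naive Bayes (e1071), random forest (ranger,
# defaults n_trees = 500, 8 candidate features per split), and a two-hidden-
# layer multilayer perceptron.

CLASSIFIERS <- c("random_forest", "knn", "naive_bayes", "mlp")

default_params <- function(classifier) {
  switch(classifier,
         random_forest = list(num_trees = 500L, mtry = 8L, max_depth = 0L),
         knn = list(k = 5L, metric = "euclidean", minkowski_p = 3),
         naive_bayes = list(),
         mlp = list(hidden = c(128L, 64L), lr = 1e-3, max_epochs = 300L,
                    patience = 20L),
         stop("unknown classifier: ", classifier))
}

#' Conventional hyperparameter search grids
#'
#' The canonical grids used for the classifier comparison: kNN with
#' k = 1..30 and euclidean/manhattan/minkowski metrics; random forest with
#' candidate-features-per-split 100, 200, ..., 2000 (capped at the feature
#' count by [grid_search()]) and maximum depth 0 (unlimited), 10, ..., 110.
#'
#' @param classifier Classifier family name.
#' @return Named list of parameter vectors suitable for [grid_search()].
#' @export
default_grid <- function(classifier) {
  switch(match.arg(classifier, CLASSIFIERS),
         knn = list(k = 1:30,
                    metric = c("euclidean", "manhattan", "minkowski")),
         random_forest = list(mtry = seq(100L, 2000L, by = 100L),
                              max_depth = seq(0L, 110L, by = 10L)),
         naive_bayes = list(),
         mlp = list(hidden = list(c(64L), c(128L, 64L), c(256L, 128L))))
}

knn_distances <- function(train, test, metric, p = 3) {
  switch(metric,
    euclidean = {
      sq_tr <- rowSums(train^2); sq_te <- rowSums(test^2)
      d2 <- outer(sq_te, sq_tr, "+") - 2 * test %*% t(train)
      sqrt(pmax(d2, 0))
    },
    manhattan = {
      t(apply(test, 1, function(v) colSums(abs(t(train) - v))))
    },
    minkowski = {
      t(apply(test, 1, function(v) colSums(abs(t(train) - v)^p)^(1 / p)))
    },
    stop("unknown metric: ", metric))
}

fit_classifier <- function(x, y, classifier, params = list(), seed = 1L) {
  classifier <- match.arg(classifier, CLASSIFIERS)
  params <- utils::modifyList(default_params(classifier), params)
  y <- droplevels(factor(y))
  model <- switch(classifier,
    knn = list(x = x, y = y, k = params$k, metric = params$metric,
               p = params$minkowski_p),
    naive_bayes = {
      m <- e1071::naiveBayes(as.data.frame(x), y)
      # guard: zero within-class variance would produce NaN densities
      m$tables <- lapply(m$tables, function(tb) {
        tb[, 2] <- pmax(tb[, 2], 1e-9); tb
      })
      m
    },
    random_forest = {
      md <- params$max_depth
      ranger::ranger(x = as.data.frame(x), y = y,
                     num.trees = params$num_trees,
                     mtry = min(params$mtry, ncol(x)),
                     max.depth = if (is.null(md) || md == 0) NULL else md,
                     probability = TRUE, seed = seed, num.threads = 1L)
    },
    mlp = mlp_fit(x, y, hidden = params$hidden, lr = params$lr,
                  max_epochs = params$max_epochs, patience = params$patience,
                  seed = seed))
  structure(list(classifier = classifier, params = params, model = model,
                 levels = levels(y)), class = "habitat_model")
}

predict_probs <- function(fit, newx, all_levels = fit$levels) {
  P <- switch(fit$classifier,
    knn = {
      m <- fit$model
      D <- knn_distances(m$x, newx, m$metric, m$p)
      k <- min(m$k, nrow(m$x))
      t(apply(D, 1, function(d) {
        nb <- order(d)[seq_len(k)]  # deterministic: ties by train index
        tabulate(as.integer(m$y[nb]), nbins = nlevels(m$y)) / k
      }))
    },
    naive_bayes = {
      P <- stats::predict(fit$model, as.data.frame(newx), type = "raw")
      P[!is.finite(P)] <- 0
      rs <- rowSums(P)
      P[rs == 0, ] <- 1 / ncol(P)
      P / pmax(rowSums(P), 1e-300)
    },
    random_forest = stats::predict(fit$model, as.data.frame(newx),
                                   num.threads = 1L)$predictions,
    mlp = mlp_predict(fit$model, newx))
  P <- matrix(P, nrow = nrow(newx))
  colnames(P) <- fit$levels
  # embed in the full class set (training fold may have lacked a class)
  full <- matrix(0, nrow(newx), length(all_levels),
                 dimnames = list(NULL, all_levels))
  full[, fit$levels] <- P
  full
}

#' Leave-one-out cross-validation of a subregion classifier
#'
#' Each (subject, region) sample is held out once; the classifier is fitted on
#' the remaining samples and predicts the held-out class probabilities.
#' Features are standardized per fold using the training rows only (columns
#' with zero training variance get scale 1). A training fold missing a class
#' is fitted on the remaining classes with a message; its prediction assigns
#' that class probability 0.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Region labels (factor or character).
#' @param classifier One of `"random_forest"`, `"knn"`, `"naive_bayes"`,
#'   `"mlp"`.
#' @param params Named list of hyperparameters overriding the family defaults
#'   (random forest: `num_trees = 500`, `mtry = 8`, `max_depth = 0` =
#'   unlimited; knn: `k`, `metric`, `minkowski_p`; mlp: `hidden`, `lr`, ...).
#' @param seed Integer seed; per-fold seeds derive from it, so the result is
#'   reproducible.
#' @param standardize Standardize features per fold (default `TRUE`).
#' @return An object of class `habitat_cv`: `predictions` data frame
#'   (`sample`, `truth`, `pred`), probability matrix `probs`, `confusion`,
#'   `metrics` ([metrics_from_confusion()]), per-class `auc`, `params`,
#'   `fold_centers` (per-fold training means, for leakage auditing).
#' @export
habitat_loocv <- function(x, y, classifier = "random_forest",
                          params = list(), seed = 1L, standardize = TRUE) {
  classifier <- match.arg(classifier, CLASSIFIERS)
  x <- as.matrix(x)
  y <- factor(y, levels = intersect(names(REGIONS), unique(as.character(y))))
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 samples for leave-one-out")
  lev <- levels(y)
  probs <- matrix(NA_real_, n, length(lev), dimnames = list(rownames(x), lev))
  centers <- matrix(NA_real_, n, ncol(x))
  for (i in seq_len(n)) {
    tr_x <- x[-i, , drop = FALSE]
    tr_y <- droplevels(y[-i])
    if (nlevels(tr_y) < nlevels(y))
      message("fold ", i, ": training set lacks class(es) ",
              paste(setdiff(lev, levels(tr_y)), collapse = ", "),
              "; scoring with remaining classes")
    te_x <- x[i, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(tr_x)
      sdv <- apply(tr_x, 2, stats::sd)
      sdv[!is.finite(sdv) | sdv == 0] <- 1
      tr_x <- sweep(sweep(tr_x, 2, mu), 2, sdv, "/")
      te_x <- sweep(sweep(te_x, 2, mu), 2, sdv, "/")
      centers[i, ] <- mu
    }
    fit <- fit_classifier(tr_x, tr_y, classifier, params,
                          seed = derive_seed(seed, i))
    probs[i, ] <- predict_probs(fit, te_x, all_levels = lev)
  }
  pred <- lev[max.col(probs, ties.method = "first")]
  cm <- confusion_matrix(y, pred, levels = lev)
  structure(list(
    classifier = classifier,
    params = utils::modifyList(default_params(classifier), params),
    seed = seed,
    predictions = data.frame(
      sample = if (is.null(rownames(x))) as.character(seq_len(n))
               else rownames(x),
      truth = as.character(y), pred = pred, stringsAsFactors = FALSE),
    probs = probs,
    confusion = cm,
    metrics = metrics_from_confusion(cm),
    auc = suppressWarnings(roc_auc(probs, as.character(y))),
    fold_centers = centers), class = "habitat_cv")
}

#' @export
print.habitat_cv <- function(x, ...) {
  cat("Leave-one-out cross-validation:", x$classifier, "on",
      nrow(x$probs), "samples\n")
  cat("Overall accuracy:", sprintf("%.3f", x$metrics$overall_accuracy), "\n")
  invisible(x)
}

#' @export
summary.habitat_cv <- function(object, ...) {
  print(object)
  cat("\nConfusion matrix (rows = truth):\n")
  print(object$confusion)
  cat("\nPer-class one-vs-rest metrics:\n")
  print(object$metrics)
  cat("\nPer-class AUC:\n")
  print(round(object$auc, 3))
  invisible(object)
}

#' Exhaustive grid search under LOOCV accuracy
#'
#' Evaluates every grid point with [habitat_loocv()] and returns the point
#' with the highest overall accuracy; ties are broken by the first point in
#' declared order. Random-forest `mtry` values above the feature count are
#' capped at the feature count.
#'
#' @param x,y,classifier,seed As in [habitat_loocv()].
#' @param grid Named list of parameter vectors (expanded in declared order,
#'   first parameter varying fastest) or a data frame of points.
#' @return List with `best` (chosen parameter list), `accuracy`, and
#'   `results` (one row per grid point with its LOOCV accuracy).
#' @export
grid_search <- function(x, y, classifier, grid, seed = 1L) {
  classifier <- match.arg(classifier, CLASSIFIERS)
  pts <- if (is.data.frame(grid)) grid
         else expand.grid(grid, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
  stopifnot(nrow(pts) >= 1L)
  if (classifier == "random_forest" && "mtry" %in% names(pts))
    pts$mtry <- pmin(pts$mtry, ncol(x))
  accs <- numeric(nrow(pts))
  for (g in seq_len(nrow(pts))) {
    params <- lapply(as.list(pts[g, , drop = FALSE]),
                     function(v) if (is.list(v)) v[[1L]] else v)
    names(params) <- names(pts)
    cv <- habitat_loocv(x, y, classifier, params, seed = seed)
    accs[g] <- cv$metrics$overall_accuracy
  }
  best <- which.max(accs)  # first maximum in declared order
  res <- cbind(pts, accuracy = accs)
  params <- lapply(as.list(pts[best, , drop = FALSE]),
                   function(v) if (is.list(v)) v[[1L]] else v)
  names(params) <- names(pts)
  list(best = params, accuracy = accs[best], results = res)
}
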