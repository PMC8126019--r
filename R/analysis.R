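# Random-forest feature importance ranking and correlation structure.

#' Rank features by random-forest importance
#'
#' Fits impurity-importance random forests with `n_seeds` different seeds on
#' the full (standardized) table, averages the per-feature mean decrease in
#' impurity, normalizes the scores to sum to 1, and ranks them in descending
#' order (ties broken by feature-registry/column order).
#'
#' @param x Numeric feature matrix (columns named).
#' @param y Region labels.
#' @param n_seeds Number of forests to average (default 10).
#' @param top_k Size of the selected feature list (default 20).
#' @param num_trees,mtry Random-forest parameters (defaults 500 and 8).
#' @param seed Base seed.
#' @return An `importance_ranking`: data frame `ranking` (`name`, `score`,
#'   `rank`) with scores summing to 1, and character vector `top_k`.
#' @export
rank_importance <- function(x, y, n_seeds = 10L, top_k = 20L,
                            num_trees = 500L, mtry = 8L, seed = 1L) {
  x <- as.matrix(x)
  y <- droplevels(factor(y))
  stopifnot(!is.null(colnames(x)), nlevels(y) >= 2L)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd); sdv[sdv == 0 | !is.finite(sdv)] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  imp <- numeric(ncol(x))
  for (s in seq_len(n_seeds)) {
    rf <- ranger::ranger(x = as.data.frame(xs), y = y,
                         num.trees = num_trees, mtry = min(mtry, ncol(x)),
                         importance = "impurity",
                         seed = derive_seed(seed, s), num.threads = 1L)
    imp <- imp + rf$variable.importance
  }
  imp <- pmax(imp / n_seeds, 0)
  score <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp),
                                                     length(imp))
  ord <- order(-score, seq_along(score))  # ties by column (registry) order
  ranking <- data.frame(name = colnames(x)[ord], score = score[ord],
                        rank = seq_along(ord), stringsAsFactors = FALSE)
  structure(list(ranking = ranking,
                 top_k = ranking$name[seq_len(min(top_k, nrow(ranking)))],
                 n_seeds = n_seeds),
            class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat("Random-forest importance ranking (", x$n_seeds, " seeds averaged)\n",
      sep = "")
  top <- utils::head(x$ranking, length(x$top_k))
  top$score <- signif(top$score, 4)
  print(top, row.names = FALSE)
  invisible(x)
}

#' Correlation matrix of selected features and the region label
#'
#' Pearson or Spearman correlations over the selected feature columns plus a
#' numeric `region` column encoding the label ordinally (necrosis = 1, solid
#' = 2, peritumoral = 3, edema = 4). Zero-variance columns get coefficient 0
#' against everything (unit diagonal kept) and are flagged.
#'
#' @param x Feature matrix or data frame (selected features as columns).
#' @param labels Region labels.
#' @param method `"pearson"` or `"spearman"`.
#' @return A `correlation_matrix`: symmetric matrix `r` with unit diagonal,
#'   `method`, and `flagged` (zero-variance column names).
#' @export
correlation_matrix <- function(x, labels, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 3L)
  lab <- REGIONS[as.character(labels)]
  stopifnot(!anyNA(lab))
  m <- cbind(x, region = as.numeric(lab))
  sdv <- apply(m, 2, stats::sd)
  flagged <- colnames(m)[sdv == 0]
  r <- suppressWarnings(stats::cor(m, method = method))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  structure(list(r = r, method = method, flagged = flagged),
            class = "correlation_matrix")
}

#' Correlation heatmap
#'
#' Pure rendering of an already-computed [correlation_matrix()] (no
#' re-computation). Uses `pheatmap` when installed, base `image()` otherwise.
#'
#' @param cm A `correlation_matrix`.
#' @param file Optional PNG path; when given, the plot is written there.
#' @param ... Passed to the plotting backend.
#' @return `cm`, invisibly.
#' @export
plot_correlation_heatmap <- function(cm, file = NULL, ...) {
  stopifnot(inherits(cm, "correlation_matrix"))
  draw <- function() {
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      pheatmap::pheatmap(cm$r, cluster_rows = FALSE, cluster_cols = FALSE,
                         breaks = seq(-1, 1, length.out = 101),
                         main = paste(cm$method, "correlation"), ...)
    } else {
      graphics::image(cm$r, zlim = c(-1, 1),
                      main = paste(cm$method, "correlation"), ...)
    }
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 800)
    on.exit(grDevices::dev.off())
    draw()
  } else draw()
  invisible(cm)
}
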