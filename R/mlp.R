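# Small multilayer perceptron: two hidden layers (default 128/64), ReLU,
# softmax output, Adam full-batch training, early stopping on the training
# cross-entropy plateau.  Deterministic given the seed.

mlp_fit <- function(x, y, hidden = c(128L, 64L), lr = 1e-3, max_epochs = 300L,
                    patience = 20L, tol = 1e-5, seed = 1L) {
  y <- droplevels(factor(y))
  lev <- levels(y)
  n <- nrow(x); p <- ncol(x); K <- length(lev)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), as.integer(y))] <- 1
  sizes <- c(p, hidden, K)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  nl <- length(W)
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(v) v * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best <- Inf; wait <- 0L
  for (ep in seq_len(max_epochs)) {
    A <- list(x)
    for (l in seq_len(nl)) {
      Z <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+")
      A[[l + 1L]] <- if (l < nl) pmax(Z, 0) else Z
    }
    Z <- A[[nl + 1L]]
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z); P <- P / rowSums(P)
    loss <- -mean(log(pmax(P[cbind(seq_len(n), as.integer(y))], 1e-12)))
    if (loss < best - tol) { best <- loss; wait <- 0L } else wait <- wait + 1L
    if (wait >= patience) break
    D <- (P - Y) / n
    for (l in nl:1) {
      gW <- crossprod(A[[l]], D)
      gb <- colSums(D)
      if (l > 1L) D <- (D %*% t(W[[l]])) * (A[[l]] > 0)
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      cb1 <- 1 - beta1^ep; cb2 <- 1 - beta2^ep
      W[[l]] <- W[[l]] - lr * (mW[[l]] / cb1) / (sqrt(vW[[l]] / cb2) + eps)
      b[[l]] <- b[[l]] - lr * (mb[[l]] / cb1) / (sqrt(vb[[l]] / cb2) + eps)
    }
  }
  list(W = W, b = b, levels = lev)
}

mlp_predict <- function(model, x) {
  A <- x
  nl <- length(model$W)
  for (l in seq_len(nl)) {
    A <- sweep(A %*% model$W[[l]], 2, model$b[[l]], "+")
    if (l < nl) A <- pmax(A, 0)
  }
  A <- A - apply(A, 1, max)
  P <- exp(A); P <- P / rowSums(P)
  colnames(P) <- model$levels
  P
}
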