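# Independent brute-force oracles, deliberately written as naive loops so they
# share no code with the package implementation.

# Symmetric co-occurrence matrix by explicit pair enumeration.
naive_glcm <- function(img, offset, n_levels) {
  C <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    r2 <- r + offset[1]; c2 <- c + offset[2]
    if (r2 < 1 || r2 > nrow(img) || c2 < 1 || c2 > ncol(img)) next
    a <- img[r, c]; b <- img[r2, c2]
    if (is.na(a) || is.na(b)) next
    C[a, b] <- C[a, b] + 1
    C[b, a] <- C[b, a] + 1
  }
  if (sum(C) > 0) C <- C / sum(C)
  C
}

# 22 co-occurrence statistics by direct summation loops over the matrix.
naive_glcm_features <- function(P) {
  L <- nrow(P)
  if (sum(P) == 0) P[1, 1] <- 1
  px <- numeric(L)
  for (i in 1:L) for (j in 1:L) px[i] <- px[i] + P[i, j]
  mu <- 0; for (i in 1:L) mu <- mu + i * px[i]
  s2 <- 0; for (i in 1:L) s2 <- s2 + (i - mu)^2 * px[i]
  ac <- ja <- cp <- cs <- ct <- con <- dis <- ene <- ent <- h1 <- h2 <- 0
  idmn <- idn <- iv <- mp <- 0
  pd <- numeric(L); ps <- numeric(2 * L)
  hxy1 <- hxy2 <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    ac <- ac + i * j * p
    cp <- cp + (i + j - 2 * mu)^4 * p
    cs <- cs + (i + j - 2 * mu)^3 * p
    ct <- ct + (i + j - 2 * mu)^2 * p
    con <- con + (i - j)^2 * p
    dis <- dis + abs(i - j) * p
    ene <- ene + p^2
    if (p > 0) ent <- ent - p * log2(p)
    h1 <- h1 + p / (1 + abs(i - j))
    h2 <- h2 + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + (i - j)^2 / L^2)
    idn <- idn + p / (1 + abs(i - j) / L)
    if (i != j) iv <- iv + p / (i - j)^2
    if (p > mp) mp <- p
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p
    ps[i + j] <- ps[i + j] + p
    if (px[i] * px[j] > 0) {
      hxy1 <- hxy1 - p * log2(px[i] * px[j])
      hxy2 <- hxy2 - px[i] * px[j] * log2(px[i] * px[j])
    }
  }
  da <- 0; for (k in 0:(L - 1)) da <- da + k * pd[k + 1]
  de <- 0; dv <- 0
  for (k in 0:(L - 1)) {
    if (pd[k + 1] > 0) de <- de - pd[k + 1] * log2(pd[k + 1])
    dv <- dv + (k - da)^2 * pd[k + 1]
  }
  se <- 0
  for (k in 2:(2 * L)) if (ps[k] > 0) se <- se - ps[k] * log2(ps[k])
  hx <- 0
  for (i in 1:L) if (px[i] > 0) hx <- hx - px[i] * log2(px[i])
  corr <- if (s2 > 0) (ac - mu^2) / s2 else 0
  imc1 <- if (hx > 0) (ent - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - 2^(-2 * (hxy2 - ent))))
  c(Autocorrelation = ac, JointAverage = mu, ClusterProminence = cp,
    ClusterShade = cs, ClusterTendency = ct, Contrast = con,
    Correlation = corr, DifferenceAverage = da, DifferenceEntropy = de,
    DifferenceVariance = dv, Dissimilarity = dis, Energy = ene,
    Entropy = ent, Homogeneity1 = h1, Homogeneity2 = h2, IMC1 = imc1,
    IMC2 = imc2, IDMN = idmn, IDN = idn, InverseVariance = iv,
    MaximumProbability = mp, SumEntropy = se)
}

# Run-length matrix by explicit scanning of each line in the direction.
naive_glrlm <- function(img, offset, n_levels, max_len) {
  R <- matrix(0, n_levels, max_len)
  visited <- matrix(FALSE, nrow(img), ncol(img))
  inb <- function(r, c) r >= 1 && r <= nrow(img) && c >= 1 && c <= ncol(img)
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    if (visited[r, c] || is.na(img[r, c])) next
    # only start a run at a line start: predecessor out of range or NA
    pr <- r - offset[1]; pc <- c - offset[2]
    if (inb(pr, pc) && !is.na(img[pr, pc]) && img[pr, pc] == img[r, c]) next
    len <- 0; rr <- r; cc <- c
    while (inb(rr, cc) && !is.na(img[rr, cc]) && img[rr, cc] == img[r, c]) {
      visited[rr, cc] <- TRUE
      len <- len + 1
      rr <- rr + offset[1]; cc <- cc + offset[2]
    }
    R[img[r, c], min(len, max_len)] <- R[img[r, c], min(len, max_len)] + 1
  }
  R
}

naive_glrlm_features <- function(R, n_voxels) {
  Nr <- sum(R)
  sre <- lre <- lgl <- hgl <- srl <- srh <- lrl <- lrh <- 0
  for (g in seq_len(nrow(R))) for (l in seq_len(ncol(R))) {
    x <- R[g, l]
    sre <- sre + x / l^2; lre <- lre + x * l^2
    lgl <- lgl + x / g^2; hgl <- hgl + x * g^2
    srl <- srl + x / (g^2 * l^2); srh <- srh + x * g^2 / l^2
    lrl <- lrl + x * l^2 / g^2; lrh <- lrh + x * g^2 * l^2
  }
  gln <- sum(rowSums(R)^2); rln <- sum(colSums(R)^2)
  c(SRE = sre / Nr, LRE = lre / Nr, GLN = gln / Nr, RLN = rln / Nr,
    RP = Nr / n_voxels, LGLRE = lgl / Nr, HGLRE = hgl / Nr,
    SRLGLE = srl / Nr, SRHGLE = srh / Nr, LRLGLE = lrl / Nr,
    LRHGLE = lrh / Nr)
}

# riu2 LBP code of one pixel by hand: circular neighbour order E, NE, N, NW,
# W, SW, S, SE.
naive_lbp_code <- function(img, r, c) {
  nb <- c(img[r, c + 1], img[r - 1, c + 1], img[r - 1, c], img[r - 1, c - 1],
          img[r, c - 1], img[r + 1, c - 1], img[r + 1, c], img[r + 1, c + 1])
  if (any(is.na(nb)) || is.na(img[r, c])) return(NA_integer_)
  bits <- as.integer(nb >= img[r, c])
  trans <- sum(bits != bits[c(2:8, 1)])
  if (trans <= 2) sum(bits) else 9L
}

# AUC by exhaustive concordant-pair counting (ties count 1/2).
naive_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Pearson correlation from raw sums.
naive_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}
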