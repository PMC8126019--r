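# 2-D SIFT keypoints and descriptors, aggregated over ROI slices.
#
# A compact SIFT: difference-of-Gaussian scale-space extrema (3 scales per
# octave, sigma0 = 1.6), contrast and edge-response rejection, one dominant
# gradient orientation per keypoint, and the standard 4x4-cell x 8-bin
# gradient-orientation descriptor (128 values, L2-normalised, 0.2-clipped,
# renormalised).  Simplifications relative to the original detector: no
# sub-pixel refinement, single orientation per keypoint, nearest-bin
# descriptor accumulation.  Fully deterministic.

.bilinear <- function(M, r, c) {
  nr <- nrow(M); nc <- ncol(M)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  M[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    M[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    M[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    M[cbind(r0 + 1, c0 + 1)] * fr * fc
}

.gradients <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gy[2:(nr - 1), ] <- (M[3:nr, ] - M[1:(nr - 2), ]) / 2
  gx[, 2:(nc - 1)] <- (M[, 3:nc] - M[, 1:(nc - 2)]) / 2
  list(gx = gx, gy = gy)
}

# Keypoints + descriptors of one 2-D image (values any range; internally
# normalised).  `mask` (logical, same shape) restricts keypoint locations.
sift_slice <- function(img, mask = NULL, max_keypoints = 40L,
                       contrast_thr = 0.03, edge_r = 10) {
  nr0 <- nrow(img); nc0 <- ncol(img)
  if (min(nr0, nc0) < 8L) return(NULL)
  rng <- range(img)
  if (diff(rng) == 0) return(NULL)
  img <- (img - rng[1]) / diff(rng)
  sigma0 <- 1.6; k <- 2^(1 / 3)
  n_oct <- max(1L, min(3L, floor(log2(min(nr0, nc0) / 8)) + 1L))

  kps <- list()
  base <- smooth_gaussian2d(img, sqrt(sigma0^2 - 0.5^2))
  for (oct in seq_len(n_oct)) {
    if (min(dim(base)) < 8L) break
    G <- vector("list", 6L); G[[1L]] <- base
    sig <- sigma0 * k^(0:5)
    for (i in 2:6)
      G[[i]] <- smooth_gaussian2d(G[[i - 1L]], sqrt(sig[i]^2 - sig[i - 1]^2))
    D <- lapply(1:5, function(i) G[[i + 1L]] - G[[i]])
    nr <- nrow(base); nc <- ncol(base)
    for (lvl in 2:4) {
      Dc <- D[[lvl]]
      if (nr < 3L || nc < 3L) next
      ctr <- Dc[2:(nr - 1), 2:(nc - 1), drop = FALSE]
      ismax <- array(TRUE, dim(ctr)); ismin <- array(TRUE, dim(ctr))
      for (dl in -1:1) for (dr in -1:1) for (dc2 in -1:1) {
        if (dl == 0 && dr == 0 && dc2 == 0) next
        nb <- D[[lvl + dl]][(2:(nr - 1)) + dr, (2:(nc - 1)) + dc2,
                            drop = FALSE]
        ismax <- ismax & (ctr > nb)
        ismin <- ismin & (ctr < nb)
      }
      ext <- (ismax | ismin) & abs(ctr) > contrast_thr
      if (!any(ext)) next
      pos <- which(ext, arr.ind = TRUE)
      pr <- pos[, 1] + 1L; pc <- pos[, 2] + 1L
      # edge response from the 2x2 DoG Hessian
      dxx <- Dc[cbind(pr, pc + 1L)] + Dc[cbind(pr, pc - 1L)] -
        2 * Dc[cbind(pr, pc)]
      dyy <- Dc[cbind(pr + 1L, pc)] + Dc[cbind(pr - 1L, pc)] -
        2 * Dc[cbind(pr, pc)]
      dxy <- (Dc[cbind(pr + 1L, pc + 1L)] + Dc[cbind(pr - 1L, pc - 1L)] -
                Dc[cbind(pr + 1L, pc - 1L)] - Dc[cbind(pr - 1L, pc + 1L)]) / 4
      tr <- dxx + dyy; det <- dxx * dyy - dxy^2
      ok <- det > 0 & tr^2 / det < (edge_r + 1)^2 / edge_r
      if (!any(ok)) next
      pr <- pr[ok]; pc <- pc[ok]
      scale_fac <- 2^(oct - 1L)
      r_full <- (pr - 1) * scale_fac + 1
      c_full <- (pc - 1) * scale_fac + 1
      if (!is.null(mask)) {
        mok <- mask[cbind(pmin(pmax(round(r_full), 1L), nr0),
                          pmin(pmax(round(c_full), 1L), nc0))]
        if (!any(mok)) next
        pr <- pr[mok]; pc <- pc[mok]
        r_full <- r_full[mok]; c_full <- c_full[mok]
      }
      for (q in seq_along(pr)) {
        kps[[length(kps) + 1L]] <- list(
          oct = oct, lvl = lvl, r = pr[q], c = pc[q],
          r_full = r_full[q], c_full = c_full[q],
          resp = abs(Dc[pr[q], pc[q]]), G = G[[lvl]])
      }
    }
    base <- G[[4L]][seq(1L, nrow(base), by = 2L),
                    seq(1L, ncol(base), by = 2L), drop = FALSE]
  }
  if (!length(kps)) return(NULL)
  ord <- order(vapply(kps, `[[`, 0, "resp"), decreasing = TRUE)
  kps <- kps[ord[seq_len(min(max_keypoints, length(kps)))]]

  desc <- matrix(0, length(kps), 128L)
  keep <- logical(length(kps))
  for (q in seq_along(kps)) {
    kp <- kps[[q]]
    L <- kp$G
    gr <- .gradients(L)
    sig_rel <- sigma0 * k^(kp$lvl - 1)
    # dominant orientation from a 36-bin weighted histogram
    rad <- max(2L, round(4.5 * sig_rel))
    rr <- (kp$r - rad):(kp$r + rad); cc <- (kp$c - rad):(kp$c + rad)
    rr <- rr[rr >= 1 & rr <= nrow(L)]; cc <- cc[cc >= 1 & cc <= ncol(L)]
    gxw <- gr$gx[rr, cc, drop = FALSE]; gyw <- gr$gy[rr, cc, drop = FALSE]
    magw <- sqrt(gxw^2 + gyw^2)
    d2 <- outer((rr - kp$r)^2, (cc - kp$c)^2, "+")
    w <- magw * exp(-d2 / (2 * (1.5 * sig_rel)^2))
    ang <- atan2(gyw, gxw) %% (2 * pi)
    hb <- pmin(floor(ang / (2 * pi) * 36) + 1L, 36L)
    hist36 <- vapply(1:36, function(b) sum(w[hb == b]), 0)
    theta <- (which.max(hist36) - 0.5) * 2 * pi / 36
    ct <- cos(theta); st <- sin(theta)
    # 16x16 sample grid, spacing 0.75 * sigma, rotated by theta
    sp <- 0.75 * sig_rel
    u <- (seq_len(16) - 8.5) * sp
    uu <- matrix(u, 16, 16); vv <- t(uu)
    rs <- kp$r + (uu * st + vv * ct)   # row offset: y
    cs <- kp$c + (uu * ct - vv * st)
    gxs <- .bilinear(gr$gx, as.vector(rs), as.vector(cs))
    gys <- .bilinear(gr$gy, as.vector(rs), as.vector(cs))
    mag <- sqrt(gxs^2 + gys^2)
    wts <- mag * exp(-(as.vector(uu)^2 + as.vector(vv)^2) / (2 * (8 * sp)^2))
    ang2 <- (atan2(gys, gxs) - theta) %% (2 * pi)
    obin <- pmin(floor(ang2 / (pi / 4)) + 1L, 8L)
    cell_r <- rep(rep(1:4, each = 4), 16)        # row cells over uu rows
    cell_c <- rep(1:4, each = 64)
    idx <- (cell_r - 1L) * 32L + (cell_c - 1L) * 8L + obin
    v <- vapply(1:128, function(b) sum(wts[idx == b]), 0)
    nv <- sqrt(sum(v^2))
    if (nv == 0) next
    v <- pmin(v / nv, 0.2)
    v <- v / sqrt(sum(v^2))
    desc[q, ] <- v
    keep[q] <- TRUE
  }
  if (!any(keep)) return(NULL)
  desc[keep, , drop = FALSE]
}

#' Aggregated SIFT features of an ROI's slices
#'
#' Detects SIFT keypoints on every slice (restricted to the ROI), collects the
#' 128-dimensional descriptors across slices, and returns the element-wise
#' mean concatenated with the element-wise (population) standard deviation —
#' 256 deterministic values per modality.  A flat ROI with no keypoint yields
#' 256 zeros with a warning.
#'
#' @param slices List of 2-D matrices with `NA` outside the ROI.
#' @param max_keypoints Strongest keypoints kept per slice (default 40).
#' @return Named numeric vector of length 256 (`SIFT_Mean_*`, `SIFT_SD_*`).
#' @export
sift_features <- function(slices, max_keypoints = 40L) {
  descs <- list()
  for (s in slices) {
    msk <- !is.na(s)
    if (!any(msk)) next
    img <- s
    img[!msk] <- mean(s[msk])
    d <- sift_slice(img, mask = msk, max_keypoints = max_keypoints)
    if (!is.null(d)) descs[[length(descs) + 1L]] <- d
  }
  nm <- c(sprintf("SIFT_Mean_%03d", 1:128), sprintf("SIFT_SD_%03d", 1:128))
  if (!length(descs)) {
    warning("no SIFT keypoint found in any slice; returning zeros")
    return(stats::setNames(numeric(256), nm))
  }
  D <- do.call(rbind, descs)
  mu <- colMeans(D)
  sdv <- sqrt(colMeans(sweep(D, 2, mu)^2))
  stats::setNames(c(mu, sdv), nm)
}
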