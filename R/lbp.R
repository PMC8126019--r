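# Local binary pattern (P = 8, R = 1, rotation-invariant uniform) histogram
# features on axial slices.

# riu2 code map of one 2-D patch (NA outside ROI).  A pixel gets a code only
# when it and its 8 grid neighbours are inside the ROI.  Uniform patterns
# (<= 2 circular 0/1 transitions) map to their number of set bits (0..8),
# non-uniform patterns to code 9.
lbp_code_map <- function(slice) {
  nr <- nrow(slice); nc <- ncol(slice)
  if (nr < 3L || nc < 3L) return(matrix(NA_integer_, 0, 0))
  # circular neighbour order: E, NE, N, NW, W, SW, S, SE
  off <- cbind(c(0, -1, -1, -1, 0, 1, 1, 1), c(1, 1, 0, -1, -1, -1, 0, 1))
  ctr <- slice[2:(nr - 1), 2:(nc - 1), drop = FALSE]
  bits <- vector("list", 8L)
  valid <- !is.na(ctr)
  for (k in 1:8) {
    nb <- slice[(2:(nr - 1)) + off[k, 1], (2:(nc - 1)) + off[k, 2],
                drop = FALSE]
    valid <- valid & !is.na(nb)
    bits[[k]] <- nb >= ctr
  }
  trans <- matrix(0L, nrow(ctr), ncol(ctr))
  ones <- matrix(0L, nrow(ctr), ncol(ctr))
  for (k in 1:8) {
    nxt <- if (k == 8L) 1L else k + 1L
    trans <- trans + (bits[[k]] != bits[[nxt]])
    ones <- ones + bits[[k]]
  }
  code <- ifelse(trans <= 2L, ones, 9L)
  code[!valid] <- NA_integer_
  code
}

#' LBP histogram features of an ROI's slices
#'
#' Computes the rotation-invariant uniform local binary pattern (P = 8 grid
#' neighbours, R = 1) code of every slice pixel whose full neighbourhood lies
#' inside the ROI, pools the codes over all slices, and returns the 16
#' first-order statistics of the pooled code distribution (entropy and
#' uniformity on the natural 10-bin code histogram), under names
#' `LBP_Mean` ... `LBP_P90`.
#'
#' @param slices List of 2-D numeric matrices with `NA` outside the ROI.
#' @return Named numeric vector of length 16.
#' @export
lbp_features <- function(slices) {
  codes <- unlist(lapply(slices, function(s) {
    m <- lbp_code_map(s)
    m[!is.na(m)]
  }))
  if (!length(codes))
    stop("no slice is large enough for LBP (need a 3x3 in-ROI neighbourhood)")
  probs <- tabulate(codes + 1L, nbins = 10L) / length(codes)
  out <- firstorder_stats(as.numeric(codes), hist_probs = probs)
  names(out) <- paste0("LBP_", FIRSTORDER_NAMES)
  out
}
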