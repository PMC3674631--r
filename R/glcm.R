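#' Grey-level co-occurrence matrix (GLCM) texture statistics
#'
#' Quantizes a grey-scale image to `levels` bins and accumulates a symmetric,
#' normalized co-occurrence matrix over the given pixel offsets, then returns
#' the classical Haralick summary statistics. Quantization is performed over
#' the observed intensity range of the included pixels by default, so the
#' statistics do not depend on the absolute brightness of the scene; a fixed
#' `range` can be supplied when comparability across images at a common scale
#' is wanted (e.g. per-cell texture at a brightness-normalized scale).
#'
#' @param x numeric matrix of grey values.
#' @param mask optional logical matrix of the same shape; only pixel pairs
#'   with both members inside the mask contribute.
#' @param levels number of quantization levels Q (default 64).
#' @param offsets list of integer offset vectors `c(dr, dc)`; the default
#'   `(0,1)` and `(1,0)` corresponds to 0 and 90 degree neighbours at
#'   distance 1, averaged.
#' @param range optional length-2 numeric giving the quantization range;
#'   default is the observed min/max of the included pixels.
#' @return list with elements `contrast`, `homogeneity`, `correlation`,
#'   `entropy`, and `n_pairs`. A constant (or empty) region yields contrast 0,
#'   homogeneity 1, correlation 0, entropy 0.
#' @export
glcm_stats <- function(x, mask = NULL, levels = 64L,
                       offsets = list(c(0L, 1L), c(1L, 0L)),
                       range = NULL) {
  stopifnot(is.matrix(x), length(dim(x)) == 2L)
  Q <- as.integer(levels)
  if (is.null(mask)) {
    inc <- NULL
    vals <- x
  } else {
    stopifnot(identical(dim(mask), dim(x)))
    inc <- mask
    vals <- x[mask]
  }
  empty <- list(contrast = 0, homogeneity = 1, correlation = 0,
                entropy = 0, n_pairs = 0L)
  if (length(vals) == 0L) return(empty)
  if (is.null(range)) {
    lo <- min(vals); hi <- max(vals)
  } else {
    lo <- range[1]; hi <- range[2]
  }
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) return(empty)
  # bin to 0..Q-1 over [lo, hi]
  q <- floor((x - lo) / (hi - lo) * Q)
  q[q < 0] <- 0; q[q > Q - 1] <- Q - 1
  storage.mode(q) <- "integer"

  nr <- nrow(x); nc <- ncol(x)
  counts <- numeric(Q * Q)
  npairs <- 0L
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- seq_len(nr - dr); c1 <- seq_len(nc - dc)
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    if (!is.null(inc)) {
      ok <- inc[r1, c1, drop = FALSE] & inc[r1 + dr, c1 + dc, drop = FALSE]
      a <- a[ok]; b <- b[ok]
    }
    if (length(a) == 0L) next
    idx <- a * Q + b + 1L
    tb <- tabulate(idx, nbins = Q * Q)
    counts <- counts + tb
    # symmetric accumulation: add the transposed pairs
    idx2 <- b * Q + a + 1L
    counts <- counts + tabulate(idx2, nbins = Q * Q)
    npairs <- npairs + length(a)
  }
  tot <- sum(counts)
  if (tot == 0) return(empty)
  p <- matrix(counts / tot, Q, Q, byrow = TRUE)  # p[i+1, j+1], i = first level
  i <- matrix(0:(Q - 1), Q, Q)
  j <- t(i)
  contrast <- sum(p * (i - j)^2)
  homogeneity <- sum(p / (1 + abs(i - j)))
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  sd_i <- sqrt(sum((i - mu_i)^2 * p)); sd_j <- sqrt(sum((j - mu_j)^2 * p))
  correlation <- if (sd_i > 0 && sd_j > 0)
    sum((i - mu_i) * (j - mu_j) * p) / (sd_i * sd_j) else 0
  pp <- p[p > 0]
  entropy <- -sum(pp * log2(pp))
  list(contrast = contrast, homogeneity = homogeneity,
       correlation = correlation, entropy = entropy, n_pairs = npairs)
}
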