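# internal fast Gaussian filtering helpers

# separable truncated-Gaussian convolution (kernel +-3 sigma, replicated
# edges); exact up to truncation, avoids full-image FFT cost
.sep_gauss <- function(m, sigma) {
  if (sigma <= 0) return(m)
  K <- ceiling(3 * sigma)
  k <- stats::dnorm(-K:K, sd = sigma); k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in -K:K) {
    src <- pmin(pmax(seq_len(nr) + i, 1L), nr)
    out <- out + k[i + K + 1L] * m[src, , drop = FALSE]
  }
  m2 <- out
  out <- matrix(0, nr, nc)
  for (i in -K:K) {
    src <- pmin(pmax(seq_len(nc) + i, 1L), nc)
    out <- out + k[i + K + 1L] * m2[, src, drop = FALSE]
  }
  out
}

# merge overlapping axis-aligned rectangles (matrix cols r0, r1, c0, c1)
.merge_rects <- function(rects) {
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nrow(rects)) {
      j <- i + 1L
      while (j <= nrow(rects)) {
        if (!(rects[i, 2] < rects[j, 1] || rects[j, 2] < rects[i, 1] ||
              rects[i, 4] < rects[j, 3] || rects[j, 4] < rects[i, 3])) {
          rects[i, ] <- c(min(rects[i, 1], rects[j, 1]),
                          max(rects[i, 2], rects[j, 2]),
                          min(rects[i, 3], rects[j, 3]),
                          max(rects[i, 4], rects[j, 4]))
          rects <- rects[-j, , drop = FALSE]
          merged <- TRUE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    if (!merged) break
  }
  rects
}

# Gaussian blur restricted to content rectangles: outside the (padded)
# rectangles the image is constant background, which blur leaves unchanged,
# so filtering only the dirty regions is exact away from a negligible
# truncation band
.blur_rects <- function(m, sigma, rects) {
  if (sigma <= 0 || nrow(rects) == 0L) return(m)
  pad <- ceiling(4 * sigma) + 1L
  rects[, 1] <- pmax(rects[, 1] - pad, 1L)
  rects[, 3] <- pmax(rects[, 3] - pad, 1L)
  rects[, 2] <- pmin(rects[, 2] + pad, nrow(m))
  rects[, 4] <- pmin(rects[, 4] + pad, ncol(m))
  rects <- .merge_rects(rects)
  for (i in seq_len(nrow(rects))) {
    rr <- rects[i, 1]:rects[i, 2]; cc <- rects[i, 3]:rects[i, 4]
    m[rr, cc] <- .sep_gauss(m[rr, cc, drop = FALSE], sigma)
  }
  m
}
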