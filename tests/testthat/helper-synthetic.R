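# shared helpers for synthetic-field tests

# small, fast field spec used across unit tests
tiny_spec <- function(..., image_shape = c(256L, 256L)) {
  field_spec(..., image_shape = image_shape)
}

# match kept segmentation objects to ground-truth cells by centroid distance
match_cells <- function(cells, truth, max_dist = 12) {
  if (length(cells) == 0L)
    return(data.frame(cell = integer(), truth = integer()))
  ctr <- t(vapply(cells, `[[`, numeric(2), "centroid"))
  out <- lapply(seq_len(nrow(ctr)), function(i) {
    d <- sqrt((truth$cells$row - ctr[i, 1])^2 +
                (truth$cells$col - ctr[i, 2])^2)
    j <- which.min(d)
    data.frame(cell = i, truth = if (d[j] <= max_dist) j else NA_integer_)
  })
  do.call(rbind, out)
}

# brute-force unweighted kappa: direct diagonal/margin summation
oracle_kappa_identity <- function(m) {
  n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  (po - pe) / (1 - pe)
}

# full hypergeometric enumeration of the two-sided Fisher p-value
oracle_fisher <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a) stats::dhyper(a, r1, r2, c1), numeric(1))
  p_obs <- stats::dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
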