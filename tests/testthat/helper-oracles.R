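# Independent brute-force oracles: plain loops over pixel pairs and matrix
# entries, sharing no code with the package kernels.

oracle_displacement <- function(angle, d) {
  switch(as.character(angle),
    "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d))
}

# Exhaustive enumeration of all in-bounds ordered pixel pairs.
oracle_glcm <- function(q, L, angle, d = 1, symmetric = FALSE) {
  disp <- oracle_displacement(angle, d)
  out <- matrix(0, L, L)
  for (r in seq_len(nrow(q))) {
    for (c in seq_len(ncol(q))) {
      rn <- r + disp[1]; cn <- c + disp[2]
      if (rn < 1 || rn > nrow(q) || cn < 1 || cn > ncol(q)) next
      i <- q[r, c] + 1; j <- q[rn, cn] + 1
      out[i, j] <- out[i, j] + 1
      if (symmetric) out[j, i] <- out[j, i] + 1
    }
  }
  out
}

# Direct double-loop evaluation of the five feature formulas.
oracle_haralick <- function(P) {
  L <- nrow(P)
  contrast <- energy <- homog <- entropy <- 0
  pi_ <- rowSums(P); pj_ <- colSums(P)
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    contrast <- contrast + (i - j)^2 * p
    energy <- energy + p^2
    homog <- homog + p / (1 + abs(i - j))
    if (p > 0) entropy <- entropy - p * log(p)
  }
  mui <- sum((0:(L - 1)) * pi_); muj <- sum((0:(L - 1)) * pj_)
  vi <- sum(((0:(L - 1)) - mui)^2 * pi_); vj <- sum(((0:(L - 1)) - muj)^2 * pj_)
  corr <- if (vi <= 0 || vj <= 0) NA_real_ else {
    s <- 0
    for (i in 1:L) for (j in 1:L)
      s <- s + ((i - 1) - mui) * ((j - 1) - muj) * P[i, j]
    s / sqrt(vi * vj)
  }
  c(contrast = contrast, correlation = corr, energy = energy,
    homogeneity = homog, entropy = entropy)
}

random_quantized <- function(H, W, L) {
  matrix(sample(0:(L - 1), H * W, replace = TRUE), H, W)
}

# Closed-form number of in-bounds ordered pairs for each offset.
expected_pair_count <- function(H, W, angle, d, symmetric = FALSE) {
  n <- switch(as.character(angle),
    "0" = H * max(W - d, 0),
    "90" = max(H - d, 0) * W,
    "45" = , "135" = max(H - d, 0) * max(W - d, 0))
  if (symmetric) 2 * n else n
}
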