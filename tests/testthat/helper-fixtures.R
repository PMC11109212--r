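# Shared fixtures and independent oracles, all built in code.

# small multimodal dataset for plumbing tests
tiny_dataset <- function(n_pos = 6, n_neg = 8, dims = c(a = 5L, b = 7L),
                         effect = 1, seed = 42) {
  generate_cohort(synthetic_spec(n_pos, n_neg, dims,
                                 n_shared_factors = 2, n_private_factors = 1,
                                 n_noise_factors = 1,
                                 effect_size = effect, seed = seed))
}

random_psd <- function(n, seed) {
  set.seed(seed)
  a <- matrix(rnorm(n * (n + 2)), n)
  tcrossprod(a) / (n + 2)
}

# brute-force ROC AUC: count all positive-negative pairs
brute_auc <- function(scores, labels) {
  pos <- scores[labels > 0]
  neg <- scores[labels < 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# all points of the step-0.01 probability simplex in k coordinates
simplex_grid <- function(k, step = 0.01) {
  m <- round(1 / step)
  if (k == 1) return(matrix(1, 1, 1))
  if (k == 2) {
    i <- 0:m
    return(cbind(i, m - i) / m)
  }
  if (k == 3) {
    out <- matrix(0, (m + 1) * (m + 2) / 2, 3)
    r <- 1L
    for (i in 0:m) for (j in 0:(m - i)) {
      out[r, ] <- c(i, j, m - i - j)
      r <- r + 1L
    }
    return(out / m)
  }
  stop("simplex_grid supports k <= 3")
}

# exhaustive minimum of the KOMD objective over the bi-simplex grid
grid_min_objective <- function(K, y, lambda, step = 0.01) {
  Q <- (1 - lambda) * (K * tcrossprod(y)) + diag(lambda, length(y))
  pos <- which(y > 0); neg <- which(y < 0)
  A <- simplex_grid(length(pos), step)
  B <- simplex_grid(length(neg), step)
  Qpp <- Q[pos, pos, drop = FALSE]
  Qnn <- Q[neg, neg, drop = FALSE]
  Qpn <- Q[pos, neg, drop = FALSE]
  qa <- rowSums((A %*% Qpp) * A)
  qb <- rowSums((B %*% Qnn) * B)
  best <- Inf
  for (i in seq_len(nrow(A))) {
    cross <- drop(B %*% (2 * crossprod(Qpn, A[i, ])))
    best <- min(best, qa[i] + min(qb + cross))
  }
  best
}

komd_objective <- function(K, y, lambda, gamma) {
  Q <- (1 - lambda) * (K * tcrossprod(y)) + diag(lambda, length(y))
  drop(crossprod(gamma, Q %*% gamma))
}
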