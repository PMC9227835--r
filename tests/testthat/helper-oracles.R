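# Independent reference implementations used as oracles in the tests.
# They deliberately use different algorithms/representations than the
# package code they check.

# Sample-space NIPALS PLS1 on pre-centered data.
nipalsPLS1 <- function(X, y, K) {
  E <- X; f <- y; M <- ncol(X)
  W <- P <- matrix(0, M, K); qv <- numeric(K)
  for (k in seq_len(K)) {
    w <- drop(crossprod(E, f))
    w <- w / sqrt(sum(w^2))
    t <- drop(E %*% w); tt <- sum(t^2)
    p <- drop(crossprod(E, t)) / tt
    q <- sum(f * t) / tt
    E <- E - tcrossprod(t, p)
    f <- f - t * q
    W[, k] <- w; P[, k] <- p; qv[k] <- q
  }
  R <- W %*% solve(crossprod(P, W))
  list(coef = drop(R %*% qv), proj = R)
}

# Literal Benjamini-Hochberg step-up rule.
stepUpBH <- function(p, q) {
  M <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= q * seq_len(M) / M)
  if (!length(ok)) return(integer(0))
  sort(o[seq_len(max(ok))])
}

softThreshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# N-by-M design whose columns are orthonormal after centering
# (crossprod(X) == I, colMeans == 0).
orthonormalDesign <- function(N, M) {
  stopifnot(N >= M + 1)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(N * M), N, M))))[, -1, drop = FALSE]
  Q
}

# Naive recount of confusion cells via explicit set membership.
naiveConfusion <- function(selected, truth, M) {
  inSel <- seq_len(M) %in% selected
  inTru <- seq_len(M) %in% truth
  c(tp = sum(inSel & inTru), fp = sum(inSel & !inTru),
    tn = sum(!inSel & !inTru), fn = sum(!inSel & inTru))
}

# Evaluate expr right after seeding the RNG, mirroring how the simulator
# consumes its config seed (the correlation matrix is its first draw).
.withSeedForTest <- function(seed, expr) {
  set.seed(seed)
  expr
}

colSkewness <- function(X) {
  apply(X, 2, function(v) mean((v - mean(v))^3) / sd(v)^3)
}

ksDistanceUniform <- function(p) {
  n <- length(p)
  s <- sort(p)
  max(abs(s - seq_len(n) / n), abs(s - (seq_len(n) - 1) / n))
}
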