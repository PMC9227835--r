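## Sparse partial least squares (regression and discriminant variants),
## written from scratch: soft-thresholded direction vectors, accumulated
## active set, dense PLS1 refits on the active set, score-space deflation.
##
## All path computations run in kernel (cross-product) form on S = X'X and
## s = X'y, so the cost of tuning is nearly independent of the number of
## subjects. The NIPALS recursion on (S, s) is algebraically identical to
## sample-space NIPALS PLS1.

# Kernel PLS1: S = X0'X0 and s = X0'y0 for centered X0, y0. Returns the
# regression coefficients (centered scale) and the projection matrix R
# mapping centered data to latent scores (T = X0 %*% R).
.pls1Kernel <- function(S, s, K) {
  M <- nrow(S)
  W <- P <- matrix(0, M, K)
  qv <- numeric(K)
  Sd <- S; sd <- s
  tol <- 1e-12 * max(1, abs(sum(diag(S))))
  k <- 0L
  for (i in seq_len(K)) {
    nw <- sqrt(sum(sd^2))
    if (nw^2 <= tol^2) break
    w <- sd / nw
    tt <- drop(crossprod(w, Sd %*% w))
    if (tt <= tol) break
    p <- drop(Sd %*% w) / tt
    q <- sum(sd * w) / tt
    sdNew <- sd - drop(Sd %*% w) * q
    sdNew <- sdNew - p * sum(w * sdNew)   # D' v = v - p (w'v)
    # Sd <- D' Sd D with D = I - w p', via two rank-1 updates:
    # Sd D = Sd - (Sd w) p'; then D' A = A - p (w' A).
    SdD <- Sd - tcrossprod(drop(Sd %*% w), p)
    Sd <- SdD - tcrossprod(p, drop(crossprod(SdD, w)))
    sd <- sdNew
    k <- i
    W[, i] <- w; P[, i] <- p; qv[i] <- q
  }
  if (k == 0L)
    return(list(coef = numeric(M), proj = matrix(0, M, 0), ncomp = 0L))
  W <- W[, seq_len(k), drop = FALSE]
  P <- P[, seq_len(k), drop = FALSE]
  R <- W %*% solve(crossprod(P, W))
  list(coef = drop(R %*% qv[seq_len(k)]), proj = R, ncomp = k)
}

# Sparse PLS path in kernel form. One entry per component count 1..K, each
# holding the accumulated active set A, the dense PLS1 refit coefficients
# on it (expanded to length M), and the active-set projection matrix.
# Components stop early when the thresholded direction is empty.
.splsSteps <- function(S, s, eta, K) {
  M <- nrow(S)
  A <- integer(0)
  steps <- vector("list", 0L)
  zTol <- 1e-12 * max(1, sqrt(max(diag(S))) * sqrt(sum(s^2)))
  proj <- NULL
  for (k in seq_len(K)) {
    if (is.null(proj)) {
      z <- s
    } else {
      # z = X_deflated' y_deflated = s - S[, A] R G R' s[A], the residual
      # covariance after projecting out the current latent scores.
      G <- solve(crossprod(proj, S[A, A, drop = FALSE] %*% proj))
      z <- s - drop(S[, A, drop = FALSE] %*%
                      (proj %*% (G %*% crossprod(proj, s[A]))))
    }
    zmax <- max(abs(z))
    if (zmax <= zTol) break
    w <- sign(z) * pmax(abs(z) - eta * zmax, 0)
    act <- which(w != 0)
    if (!length(act)) break
    A <- sort(union(A, act))
    pl <- .pls1Kernel(S[A, A, drop = FALSE], s[A], min(k, length(A)))
    if (pl$ncomp == 0L) break
    beta <- numeric(M)
    beta[A] <- pl$coef
    proj <- pl$proj
    steps[[k]] <- list(A = A, beta = beta, proj = proj, ncomp = pl$ncomp)
  }
  steps
}

# Convenience wrapper computing centering and cross-products from data.
.splsPath <- function(X, y, eta, K) {
  X0 <- scale(X, center = TRUE, scale = FALSE)
  y0 <- y - mean(y)
  list(steps = .splsSteps(crossprod(X0), drop(crossprod(X0, y0)), eta, K),
       xMeans = attr(X0, "scaled:center"), yMean = mean(y))
}

#' Sparse partial least squares regression
#'
#' Iterative sparse-direction algorithm for a continuous outcome: at each
#' component, the direction `z = X_deflated' y_deflated` is soft-thresholded
#' at `eta * max(|z|)` (so `eta = 0` recovers the dense first PLS direction
#' and `eta` near 1 keeps only the dominant metabolite), the surviving
#' metabolites join the accumulated active set, a dense PLS1 model with the
#' current number of components is refit on the active set, and the
#' covariance structure is deflated by the refit's latent scores. Final
#' scores are the absolute refit coefficients on the active set (0
#' elsewhere); the selected set is the active set.
#'
#' @param X numeric N-by-M matrix of standardized metabolite levels.
#' @param y continuous outcome vector.
#' @param eta sparsity parameter in \[0, 1).
#' @param nComponents number of latent components (>= 1).
#' @return a [MethodOutput-class] with `method = "spls"`.
#' @examples
#' X <- matrix(rnorm(600), 60, 10)
#' y <- X[, 1]
#' selectedSet(splsFit(X, y, eta = 0.9, nComponents = 1))
#' @export
splsFit <- function(X, y, eta = 0.5, nComponents = 2L) {
  if (eta < 0 || eta >= 1) stop("eta must lie in [0, 1)")
  if (nComponents < 1) stop("nComponents must be >= 1")
  X <- as.matrix(X)
  path <- .splsPath(X, y, eta, as.integer(nComponents))
  steps <- Filter(Negate(is.null), path$steps)
  if (!length(steps)) {
    warning("response is orthogonal to all metabolites; empty selection")
    return(MethodOutput("spls", scores = numeric(ncol(X)),
                        selected = integer(0),
                        tuning = list(eta = eta, n_components = 0L)))
  }
  last <- steps[[length(steps)]]
  MethodOutput("spls", scores = abs(last$beta),
               selected = which(last$beta != 0),
               tuning = list(eta = eta, n_components = last$ncomp))
}

#' Sparse partial least squares discriminant analysis
#'
#' Runs the sparse PLS machinery of [splsFit()] on the centered 0/1 class
#' indicator to obtain the active set and latent components, then fits a
#' logistic classifier on the component scores. Selection and importance
#' scores are inherited from the sparse directions; the classifier
#' coefficients are recorded in the tuning metadata.
#'
#' @param X numeric N-by-M matrix of standardized metabolite levels.
#' @param y binary outcome vector with values in `{0, 1}` (both present).
#' @param eta sparsity parameter in \[0, 1).
#' @param nComponents number of latent components (>= 1).
#' @return a [MethodOutput-class] with `method = "splsda"`.
#' @export
splsdaFit <- function(X, y, eta = 0.5, nComponents = 2L) {
  if (!all(y %in% c(0, 1))) stop("y must take values in {0, 1}")
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  if (eta < 0 || eta >= 1) stop("eta must lie in [0, 1)")
  if (nComponents < 1) stop("nComponents must be >= 1")
  X <- as.matrix(X)
  path <- .splsPath(X, y, eta, as.integer(nComponents))
  steps <- Filter(Negate(is.null), path$steps)
  if (!length(steps)) {
    warning("class indicator is orthogonal to all metabolites; ",
            "empty selection")
    return(MethodOutput("splsda", scores = numeric(ncol(X)),
                        selected = integer(0),
                        tuning = list(eta = eta, n_components = 0L)))
  }
  last <- steps[[length(steps)]]
  X0 <- sweep(X[, last$A, drop = FALSE], 2L, path$xMeans[last$A])
  Tm <- X0 %*% last$proj
  cls <- suppressWarnings(
    stats::glm.fit(cbind(1, Tm), y, family = stats::binomial()))
  gamma <- cls$coefficients
  gamma[is.na(gamma)] <- 0
  MethodOutput("splsda", scores = abs(last$beta),
               selected = which(last$beta != 0),
               tuning = list(eta = eta, n_components = last$ncomp,
                             classifier_coefficients = gamma))
}
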