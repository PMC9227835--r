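## Cross-validated tuning for the sparse methods, with the
## sparsest-within-one-SE rule for flat CV curves.

# Pick a row of a CV table (columns: mean, se, nsel) that is ordered
# sparsest-preference-first. Rule: among all rows whose CV error is within
# one standard error of the minimum, take the one with the fewest selected
# metabolites; remaining ties fall to the earlier (sparser-preferred) row.
.chooseOneSe <- function(tab) {
  imin <- which.min(tab$mean)
  thr <- tab$mean[imin] + tab$se[imin]
  cand <- which(tab$mean <= thr)
  cand[which.min(tab$nsel[cand])]
}

# Snapshot of the SPLS path at exactly K components (or the deepest
# available when the path stopped early). NULL when no component was built.
.pathAt <- function(steps, K) {
  avail <- which(!vapply(steps, is.null, logical(1)))
  avail <- avail[avail <= K]
  if (!length(avail)) NULL else steps[[max(avail)]]
}

#' Cross-validated tuning with the sparsest-within-one-SE rule
#'
#' Evaluates K-fold cross-validated prediction error over a tuning grid
#' (mean squared error for continuous outcomes, misclassification for the
#' discriminant variant) and returns the chosen tuning values. Because CV
#' curves for sparse methods on metabolomics data are frequently flat —
#' several sparsity levels equally supported by the data — the rule is not
#' plain minimization: among all grid points whose CV error lies within one
#' standard error of the minimum, the one yielding the sparsest full-data
#' model (fewest selected metabolites) is chosen. A strictly dominating
#' point (all others more than one SE worse) is chosen outright, and a
#' singleton grid is returned without any cross-validation. Folds are
#' stratified for binary outcomes and re-drawn if a fold loses a class.
#'
#' @param X numeric N-by-M matrix of standardized metabolite levels.
#' @param y outcome vector.
#' @param method `"spls"`, `"splsda"`, or `"lasso"`.
#' @param outcomeType `"continuous"` or `"binary"` (forced binary for
#'   `"splsda"`).
#' @param etaGrid,KGrid grids for the sparse PLS methods (defaults
#'   `seq(0.1, 0.9, 0.1)` and `1:5`).
#' @param lambdaGrid optional penalty grid for `"lasso"`; `NULL` uses 100
#'   log-spaced values spanning four decades down from the largest
#'   data-derived penalty.
#' @param nFolds number of folds (default 5).
#' @param foldSeed seed for the fold assignment; results are deterministic
#'   given this seed.
#' @return named list of chosen values — `list(eta=, n_components=)` or
#'   `list(lambda=)` — with the CV table attached as attribute `"cv"`.
#' @export
tuneSparse <- function(X, y, method = c("spls", "splsda", "lasso"),
                       outcomeType = c("continuous", "binary"),
                       etaGrid = seq(0.1, 0.9, by = 0.1), KGrid = 1:5,
                       lambdaGrid = NULL, nFolds = 5L, foldSeed = 1L) {
  method <- match.arg(method)
  outcomeType <- match.arg(outcomeType)
  if (method == "splsda") outcomeType <- "binary"
  if (nFolds < 2) stop("nFolds must be >= 2")
  X <- as.matrix(X)
  N <- nrow(X)

  if (method == "lasso") {
    if (!is.null(lambdaGrid) && !length(lambdaGrid))
      stop("lambdaGrid must be non-empty")
    if (!is.null(lambdaGrid) && length(lambdaGrid) == 1L)
      return(list(lambda = as.numeric(lambdaGrid)))
    fam <- if (outcomeType == "binary") "binomial" else "gaussian"
    cv <- .withSeed(foldSeed, {
      foldid <- .makeFolds(y, nFolds, stratify = outcomeType == "binary")
      args <- list(x = X, y = y, family = fam, foldid = foldid,
                   standardize = FALSE, nlambda = 100,
                   lambda.min.ratio = 1e-4)
      if (!is.null(lambdaGrid))
        args$lambda <- sort(as.numeric(lambdaGrid), decreasing = TRUE)
      do.call(glmnet::cv.glmnet, args)
    })
    tab <- data.frame(lambda = cv$lambda, mean = cv$cvm, se = cv$cvsd,
                      nsel = as.integer(cv$nzero))
    tab <- tab[order(-tab$lambda), ]  # sparser (larger penalty) first
    pick <- .chooseOneSe(tab)
    out <- list(lambda = tab$lambda[pick])
    attr(out, "cv") <- tab
    return(out)
  }

  if (!length(etaGrid) || !length(KGrid))
    stop("etaGrid and KGrid must be non-empty")
  if (any(etaGrid < 0 | etaGrid >= 1)) stop("etaGrid must lie in [0, 1)")
  KGrid <- sort(unique(as.integer(KGrid)))
  if (length(etaGrid) == 1L && length(KGrid) == 1L)
    return(list(eta = as.numeric(etaGrid), n_components = KGrid))

  Kmax <- max(KGrid)
  .withSeed(foldSeed, {
    fold <- .makeFolds(y, nFolds, stratify = outcomeType == "binary")
    err <- array(NA_real_, c(length(etaGrid), length(KGrid), nFolds))
    for (f in seq_len(nFolds)) {
      te <- fold == f
      Xtr <- X[!te, , drop = FALSE]; ytr <- y[!te]
      Xte <- X[te, , drop = FALSE]; yte <- y[te]
      # Per-fold cross-products, shared by the whole eta grid.
      Xtr0 <- scale(Xtr, center = TRUE, scale = FALSE)
      xm <- attr(Xtr0, "scaled:center")
      ym <- mean(ytr)
      S <- crossprod(Xtr0)
      s <- drop(crossprod(Xtr0, ytr - ym))
      Xte0 <- sweep(Xte, 2L, xm)
      for (ei in seq_along(etaGrid)) {
        steps <- .splsSteps(S, s, etaGrid[ei], Kmax)
        for (ki in seq_along(KGrid)) {
          st <- .pathAt(steps, KGrid[ki])
          if (is.null(st)) { err[ei, ki, f] <- stats::var(yte); next }
          if (method == "spls") {
            pred <- ym + drop(Xte0 %*% st$beta)
            err[ei, ki, f] <- mean((yte - pred)^2)
          } else {
            Ttr <- Xtr0[, st$A, drop = FALSE] %*% st$proj
            cls <- suppressWarnings(
              stats::glm.fit(cbind(1, Ttr), ytr,
                             family = stats::binomial()))
            g <- cls$coefficients; g[is.na(g)] <- 0
            Tte <- Xte0[, st$A, drop = FALSE] %*% st$proj
            phat <- stats::plogis(drop(cbind(1, Tte) %*% g))
            err[ei, ki, f] <- mean((phat > 0.5) != yte)
          }
        }
      }
    }
    # Full-data support size per grid point (the sparsity yardstick).
    X0 <- scale(X, center = TRUE, scale = FALSE)
    Sfull <- crossprod(X0)
    sfull <- drop(crossprod(X0, y - mean(y)))
    nsel <- matrix(NA_integer_, length(etaGrid), length(KGrid))
    for (ei in seq_along(etaGrid)) {
      steps <- .splsSteps(Sfull, sfull, etaGrid[ei], Kmax)
      for (ki in seq_along(KGrid)) {
        st <- .pathAt(steps, KGrid[ki])
        nsel[ei, ki] <- if (is.null(st)) 0L else length(st$A)
      }
    }
    tab <- expand.grid(ki = seq_along(KGrid), ei = seq_along(etaGrid))
    tab <- data.frame(
      eta = etaGrid[tab$ei], K = KGrid[tab$ki],
      mean = mapply(function(e, k) mean(err[e, k, ]), tab$ei, tab$ki),
      se = mapply(function(e, k) stats::sd(err[e, k, ]) / sqrt(nFolds),
                  tab$ei, tab$ki),
      nsel = mapply(function(e, k) nsel[e, k], tab$ei, tab$ki))
    tab <- tab[order(-tab$eta, tab$K), ]  # sparser-preferred first
    pick <- .chooseOneSe(tab)
    out <- list(eta = tab$eta[pick], n_components = tab$K[pick])
    attr(out, "cv") <- tab
    out
  })
}
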