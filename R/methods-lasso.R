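## L1-penalized regression via glmnet, with the sparsest-within-one-SE
## cross-validation rule.

# Stratified fold assignment; plain random folds for continuous outcomes.
.makeFolds <- function(y, nFolds, stratify = FALSE) {
  N <- length(y)
  if (nFolds < 2 || nFolds > N) stop("nFolds must lie in [2, N]")
  fold <- integer(N)
  if (stratify) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
    }
    # Refold degenerate assignments (a fold missing a class entirely).
    for (try in 1:20) {
      tab <- table(factor(fold, levels = seq_len(nFolds)), y)
      if (all(tab > 0)) break
      for (cls in unique(y)) {
        idx <- which(y == cls)
        fold[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
      }
    }
  } else {
    fold <- sample(rep_len(seq_len(nFolds), N))
  }
  fold
}

#' LASSO fit with cross-validated penalty
#'
#' Fits the L1-penalized regression
#' `(1 / 2N) * sum(residual^2) + lambda * sum(|beta_j|)` for continuous
#' outcomes, or the correspondingly penalized logistic negative
#' log-likelihood for binary outcomes, through \pkg{glmnet}. When `lambda`
#' is not supplied it is chosen by `nFolds`-fold cross-validation with the
#' sparsest-within-one-standard-error rule (the largest penalty whose CV
#' error is within one SE of the minimum). Adjustment covariates, when
#' supplied, enter the model unpenalized. Metabolites are selected when
#' their coefficient is nonzero; scores are absolute coefficients.
#'
#' @param X numeric N-by-M matrix of standardized metabolite levels.
#' @param y outcome vector.
#' @param outcomeType `"continuous"` or `"binary"`.
#' @param lambda optional nonnegative penalty; chosen by CV when `NULL`.
#' @param covariates optional unpenalized adjustment covariates.
#' @param nFolds CV folds (default 5, stratified for binary outcomes).
#' @param foldSeed seed for the CV fold assignment.
#' @return a [MethodOutput-class] with `method = "lasso"`.
#' @export
lassoFit <- function(X, y, outcomeType = c("continuous", "binary"),
                     lambda = NULL, covariates = NULL, nFolds = 5L,
                     foldSeed = 1L) {
  outcomeType <- match.arg(outcomeType)
  if (!is.null(lambda) && lambda < 0) stop("lambda must be nonnegative")
  X <- as.matrix(X)
  M <- ncol(X)
  fam <- if (outcomeType == "binary") "binomial" else "gaussian"
  Xall <- X
  pf <- rep(1, M)
  if (!is.null(covariates)) {
    covariates <- as.matrix(stats::model.matrix(~ ., data =
      as.data.frame(covariates)))[, -1, drop = FALSE]
    Xall <- cbind(X, covariates)
    pf <- c(pf, rep(0, ncol(covariates)))
  }

  if (is.null(lambda)) {
    cv <- .withSeed(foldSeed, {
      foldid <- .makeFolds(y, nFolds, stratify = outcomeType == "binary")
      glmnet::cv.glmnet(Xall, y, family = fam, foldid = foldid,
                        penalty.factor = pf, standardize = FALSE)
    })
    lambda <- cv$lambda.1se
    beta <- drop(as.matrix(stats::coef(cv, s = lambda)))[-1][seq_len(M)]
  } else {
    # Fit along a decreasing path ending at the requested lambda so the
    # coordinate-descent warm starts stay reliable.
    fit0 <- glmnet::glmnet(Xall, y, family = fam, penalty.factor = pf,
                           standardize = FALSE)
    path <- fit0$lambda
    lams <- sort(unique(c(path[path > lambda], lambda)),
                 decreasing = TRUE)
    fit <- glmnet::glmnet(Xall, y, family = fam, lambda = lams,
                          penalty.factor = pf, standardize = FALSE,
                          thresh = 1e-10)
    beta <- drop(as.matrix(stats::coef(fit, s = lambda,
                                       exact = FALSE)))[-1][seq_len(M)]
  }
  MethodOutput("lasso", scores = abs(beta), selected = which(beta != 0),
               tuning = list(lambda = as.numeric(lambda)))
}
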