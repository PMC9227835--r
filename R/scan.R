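## Univariate association scan and multiplicity corrections.

#' Per-metabolite univariate association scan
#'
#' Fits one single-metabolite model per column of `X`: ordinary least
#' squares with a Wald t-test for continuous outcomes, logistic maximum
#' likelihood with a Wald z-test for binary outcomes (or, optionally, a
#' linear-probability model). Adjustment covariates, when supplied, enter
#' every model. Degenerate fits are handled conservatively: a constant
#' metabolite column gets p = 1, and a logistic fit showing perfect or
#' quasi-perfect separation gets p = 1 with a warning.
#'
#' @param X numeric N-by-M matrix of (standardized) metabolite levels.
#' @param y outcome vector of length N.
#' @param outcomeType `"continuous"` or `"binary"`.
#' @param covariates optional numeric matrix or data.frame of adjustment
#'   covariates (e.g. a batch indicator), included in every model.
#' @param binaryModel `"logistic"` (default) or `"linear"` — the latter
#'   scans a binary outcome with the linear-probability model.
#' @return list with `pvalues` and `coefficients`, each of length M.
#' @examples
#' X <- matrix(rnorm(400), 100, 4)
#' y <- X[, 2] + rnorm(100)
#' univariateScan(X, y, "continuous")$pvalues
#' @export
univariateScan <- function(X, y, outcomeType = c("continuous", "binary"),
                           covariates = NULL,
                           binaryModel = c("logistic", "linear")) {
  outcomeType <- match.arg(outcomeType)
  binaryModel <- match.arg(binaryModel)
  X <- as.matrix(X)
  N <- nrow(X); M <- ncol(X)
  stopifnot(length(y) == N)
  D <- cbind(`(Intercept)` = rep(1, N))
  if (!is.null(covariates)) {
    covariates <- as.matrix(stats::model.matrix(~ ., data =
      as.data.frame(covariates)))[, -1, drop = FALSE]
    D <- cbind(D, covariates)
  }

  if (outcomeType == "continuous" ||
      (outcomeType == "binary" && binaryModel == "linear")) {
    # Residualize y and X on the nuisance design (Frisch-Waugh-Lovell),
    # then test each slope with the correct residual df.
    qrD <- qr(D)
    yr <- stats::residuals(stats::lm.fit(D, y))
    Xr <- X - qr.fitted(qrD, X)
    df <- N - qrD$rank - 1L
    if (df < 1L) stop("not enough residual degrees of freedom")
    sxx <- colSums(Xr^2)
    sxy <- drop(crossprod(Xr, yr))
    syy <- sum(yr^2)
    ok <- sxx > 1e-12 * max(sxx, 1)
    coefs <- ifelse(ok, sxy / sxx, 0)
    rss <- pmax(syy - coefs * sxy, 0)
    se <- sqrt(rss / df / pmax(sxx, .Machine$double.xmin))
    tstat <- ifelse(se > 0, coefs / se, ifelse(coefs != 0, Inf, 0))
    p <- 2 * stats::pt(-abs(tstat), df)
    p[!ok] <- 1
    coefs[!ok] <- 0
    return(list(pvalues = pmin(pmax(p, 0), 1), coefficients = coefs))
  }

  # Binary logistic scan.
  if (!all(y %in% c(0, 1))) stop("binary outcome must take values in {0, 1}")
  p <- numeric(M); coefs <- numeric(M)
  nSep <- 0L
  for (j in seq_len(M)) {
    xj <- X[, j]
    if (stats::var(xj) < 1e-12) { p[j] <- 1; coefs[j] <- 0; next }
    sep <- FALSE
    fit <- withCallingHandlers(
      suppressWarnings(stats::glm.fit(cbind(D, xj), y,
                                      family = stats::binomial())),
      warning = function(w) invokeRestart("muffleWarning"))
    mu <- fit$fitted.values
    if (!fit$converged || any(mu < 1e-8) || any(mu > 1 - 1e-8)) sep <- TRUE
    k <- ncol(D) + 1L
    est <- fit$coefficients[k]
    if (sep || is.na(est)) {
      p[j] <- 1; coefs[j] <- if (is.na(est)) 0 else est
      nSep <- nSep + 1L
      next
    }
    covU <- chol2inv(fit$qr$qr[seq_len(k), seq_len(k), drop = FALSE])
    z <- est / sqrt(covU[k, k])
    p[j] <- 2 * stats::pnorm(-abs(z))
    coefs[j] <- est
  }
  if (nSep > 0)
    warning(nSep, " logistic fit(s) showed separation or non-convergence; ",
            "their p-values were set to 1")
  list(pvalues = p, coefficients = coefs)
}

#' Bonferroni selection
#'
#' Selects metabolites with `p <= alpha / M`, controlling the family-wise
#' error rate at `alpha` over the M tests.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @param alpha family-wise level (default 0.05).
#' @return sorted integer vector of selected indices.
#' @export
bonferroniSelect <- function(pvalues, alpha = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1), alpha > 0, alpha < 1)
  which(pvalues <= alpha / length(pvalues))
}

#' Benjamini-Hochberg selection
#'
#' Standard step-up rule at false-discovery level `q`: order the p-values
#' ascending, find the largest k with `p_(k) <= q * k / M`, and select those
#' k hypotheses (none when no such k exists). Implemented through
#' [stats::p.adjust()], which is equivalent to the step-up rule.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @param q false-discovery level (default 0.1).
#' @return sorted integer vector of selected indices.
#' @export
bhSelect <- function(pvalues, q = 0.1) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1), q > 0, q < 1)
  which(stats::p.adjust(pvalues, method = "BH") <= q)
}
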