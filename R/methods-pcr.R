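## Principal component regression with coefficient reallocation.

#' Principal component regression importance
#'
#' Computes the principal components of (column-centered) `X`, regresses the
#' outcome on the leading `nComponents` component scores (linear or logistic
#' according to the outcome type), and reallocates the fitted component
#' coefficients back to the metabolites: the importance of metabolite j is
#' `|sum_k V[j, k] * gamma[k]|`, where `V[j, k]` is its loading on component
#' k and `gamma[k]` the component's regression coefficient. PCR ranks
#' metabolites but performs no variable selection, so the returned
#' [MethodOutput-class] carries scores only.
#'
#' When all components are used on a full-rank design, the reallocated
#' importances coincide with the absolute ordinary least-squares
#' coefficients.
#'
#' @param X numeric N-by-M matrix of standardized metabolite levels.
#' @param y outcome vector.
#' @param outcomeType `"continuous"` or `"binary"`.
#' @param nComponents number of leading components, in
#'   `[1, min(N - 1, M)]`; defaults to the maximum.
#' @return a [MethodOutput-class] with `method = "pcr"`.
#' @export
pcrImportance <- function(X, y, outcomeType = c("continuous", "binary"),
                          nComponents = NULL) {
  outcomeType <- match.arg(outcomeType)
  X <- as.matrix(X)
  N <- nrow(X); M <- ncol(X)
  kmax <- min(N - 1L, M)
  if (is.null(nComponents)) nComponents <- kmax
  if (nComponents < 1 || nComponents > kmax)
    stop("nComponents must lie in [1, ", kmax, "]")
  K <- as.integer(nComponents)

  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  K <- min(K, ncol(pc$rotation))
  S <- pc$x[, seq_len(K), drop = FALSE]
  V <- pc$rotation[, seq_len(K), drop = FALSE]
  if (outcomeType == "continuous") {
    fit <- stats::lm.fit(cbind(1, S), y)
  } else {
    if (!all(y %in% c(0, 1))) stop("binary outcome must be 0/1")
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, S), y, family = stats::binomial()))
  }
  gamma <- fit$coefficients[-1]
  gamma[is.na(gamma)] <- 0
  importance <- abs(drop(V %*% gamma))
  MethodOutput("pcr", scores = importance,
               tuning = list(n_components = K))
}
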