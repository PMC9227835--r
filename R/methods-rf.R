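## Random forest variable importance.

#' Random forest importance
#'
#' Grows a regression forest (continuous outcome) or classification forest
#' (binary outcome) and returns permutation variable importance as the
#' per-metabolite score. Permutation importance is used because it is
#' robust to the scale of correlated predictors. The forest ranks
#' metabolites but offers no principled selection cutoff, so no selected set
#' is reported. Pure-noise predictors can draw slightly negative permutation
#' importances; these are truncated at zero to keep scores on the common
#' nonnegative importance scale. Results are reproducible for a given seed
#' (single-threaded growth).
#'
#' @param X numeric N-by-M matrix of standardized metabolite levels.
#' @param y outcome vector.
#' @param outcomeType `"continuous"` or `"binary"`.
#' @param nTrees number of trees (default 500).
#' @param seed integer seed.
#' @return a [MethodOutput-class] with `method = "random_forest"`.
#' @export
rfImportance <- function(X, y, outcomeType = c("continuous", "binary"),
                         nTrees = 500L, seed = 1L) {
  outcomeType <- match.arg(outcomeType)
  if (nTrees < 1) stop("nTrees must be >= 1")
  X <- as.matrix(X)
  yy <- if (outcomeType == "binary") {
    if (!all(y %in% c(0, 1))) stop("binary outcome must be 0/1")
    factor(y, levels = c(0, 1))
  } else y
  fit <- ranger::ranger(x = as.data.frame(X), y = yy,
                        num.trees = as.integer(nTrees),
                        importance = "permutation",
                        seed = as.integer(seed), num.threads = 1L)
  MethodOutput("random_forest", scores = pmax(fit$variable.importance, 0),
               tuning = list(n_trees = as.integer(nTrees)))
}
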