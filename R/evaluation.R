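## Operating characteristics against the planted truth.

#' Top-k metabolite ranking
#'
#' Indices of the `k` largest scores, in descending score order, with ties
#' broken deterministically by ascending metabolite index.
#'
#' @param scores numeric importance vector.
#' @param k number of metabolites to return (`k <= length(scores)`).
#' @return ordered integer vector of length `k`.
#' @export
topK <- function(scores, k) {
  if (k > length(scores)) stop("k must not exceed the number of scores")
  order(-scores, seq_along(scores))[seq_len(k)]
}

#' Confusion summary of a selected set against the planted truth
#'
#' A true positive is a selected metabolite that was planted as directly
#' associated with the outcome; a false positive is any other selected
#' metabolite — including metabolites whose marginal association is genuine
#' but induced purely by correlation with a planted metabolite. Sensitivity,
#' specificity, PPV and NPV follow the standard formulas; a rate whose
#' denominator is zero (PPV under an empty selection, NPV under a full
#' selection) is reported as `NA`, never as 0.
#'
#' @param selected integer indices selected by a method.
#' @param truth integer indices of planted true positives.
#' @param M total number of metabolites.
#' @return a [ConfusionSummary-class].
#' @examples
#' confusion(1:10, 1:10, 200)   # perfect selection
#' confusion(integer(0), 1:10, 200)  # PPV undefined
#' @export
confusion <- function(selected, truth, M) {
  selected <- unique(as.integer(selected))
  truth <- unique(as.integer(truth))
  if (length(selected) && (min(selected) < 1 || max(selected) > M))
    stop("selected indices out of range [1, M]")
  if (length(truth) && (min(truth) < 1 || max(truth) > M))
    stop("truth indices out of range [1, M]")
  tp <- length(intersect(selected, truth))
  fp <- length(setdiff(selected, truth))
  fn <- length(setdiff(truth, selected))
  tn <- M - tp - fp - fn
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  new("ConfusionSummary",
      tp = tp, fp = fp, tn = as.integer(tn), fn = fn,
      sensitivity = rate(tp, tp + fn),
      specificity = rate(tn, tn + fp),
      ppv = rate(tp, tp + fp),
      npv = rate(tn, tn + fn),
      M = as.integer(M))
}

#' Fraction of false positives sharing a cluster with a true metabolite
#'
#' Companion tabulation to [confusion()]: false positives under the
#' planted-truth definition often carry genuine correlation-induced marginal
#' associations; this reports the fraction of them that sit in the same
#' correlation cluster as some planted metabolite.
#'
#' @param selected,truth integer index sets.
#' @param spec the [CorrelationSpec-class] that generated the data.
#' @return fraction in \[0, 1\], or `NA` when there are no false positives.
#' @export
fpClusterShare <- function(selected, truth, spec) {
  cl <- .clusterIndex(spec@nMetabolites, spec@nClusters)
  fp <- setdiff(as.integer(selected), as.integer(truth))
  if (!length(fp)) return(NA_real_)
  mean(cl[fp] %in% cl[as.integer(truth)])
}

#' Per-metabolite top-10 identification probability
#'
#' For each planted metabolite, the fraction of replicates in which it
#' appears among the first `k` (default 10) ranked indices.
#'
#' @param rankings list of ordered index vectors (one per replicate), each
#'   of length >= `k`.
#' @param truth integer indices of planted true positives.
#' @param k ranking depth (default 10).
#' @return named numeric vector, one probability per true metabolite.
#' @export
top10HitRate <- function(rankings, truth, k = 10L) {
  if (!length(rankings)) stop("at least one replicate ranking is required")
  if (any(vapply(rankings, length, 1L) < k))
    stop("every ranking must have length >= ", k)
  truth <- as.integer(truth)
  hits <- vapply(truth, function(j)
    mean(vapply(rankings, function(r) j %in% r[seq_len(k)], logical(1))),
    numeric(1))
  names(hits) <- as.character(truth)
  hits
}

#' Detection rate by planted effect size
#'
#' For each metabolite with a nonzero planted effect, the fraction of
#' replicates in which a method's selected set contained it, tabulated
#' against the absolute effect size (the empirical power curve over the
#' planted effect grid). Zero-effect metabolites are excluded.
#'
#' @param selections list of integer index sets (one per replicate).
#' @param beta length-M planted effect vector.
#' @return data.frame with columns `metabolite`, `effect_size`,
#'   `detection_rate`, sorted by `|effect_size|`.
#' @export
powerByEffectSize <- function(selections, beta) {
  truth <- which(beta != 0)
  if (!length(truth)) stop("beta must contain at least one nonzero entry")
  rate <- vapply(truth, function(j)
    mean(vapply(selections, function(s) j %in% s, logical(1))), numeric(1))
  out <- data.frame(metabolite = truth, effect_size = beta[truth],
                    detection_rate = rate)
  out[order(abs(out$effect_size)), , drop = FALSE]
}

#' Aggregate confusion summaries over replicates
#'
#' Per-metric mean with Monte-Carlo standard error over replicates.
#' Undefined (NA) rates are excluded from their metric's average rather than
#' imputed — imputing 0 or 1 would bias sparse methods' PPV at small sample
#' sizes — and the count of contributing replicates is always reported. A
#' metric undefined in every replicate is reported as `NA` with count 0.
#'
#' @param summaries list of [ConfusionSummary-class] objects.
#' @return data.frame with columns `metric`, `mean`, `se`, `n`.
#' @export
aggregateSummaries <- function(summaries) {
  if (!length(summaries)) stop("at least one replicate summary is required")
  pull <- list(
    sensitivity = function(s) s@sensitivity,
    specificity = function(s) s@specificity,
    ppv = function(s) s@ppv,
    npv = function(s) s@npv,
    fp = function(s) as.numeric(s@fp))
  rows <- lapply(names(pull), function(m) {
    v <- vapply(summaries, pull[[m]], numeric(1))
    v <- v[!is.na(v)]
    n <- length(v)
    data.frame(metric = m,
               mean = if (n) mean(v) else NA_real_,
               se = if (n > 1) stats::sd(v) / sqrt(n) else
                 if (n == 1) 0 else NA_real_,
               n = n)
  })
  do.call(rbind, rows)
}
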