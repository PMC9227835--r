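#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Between-metabolite correlation specification
#'
#' Describes the population correlation matrix of simulated metabolite
#' levels: a block (cluster) compound-symmetry backbone with Gaussian jitter
#' on the off-diagonal entries, optional negatively-correlated cluster pairs,
#' and optional planted pairs of highly intercorrelated metabolites.
#'
#' The default layout mirrors targeted metabolomics panels in which large
#' groups of metabolites are highly correlated: metabolites are split into
#' `nClusters` contiguous clusters of (near-)equal size, within-cluster
#' correlations centre on `withinClusterRho`, and cross-cluster correlations
#' centre on `betweenClusterRho`. When `betweenClusterRho` is `NA` it is
#' solved in closed form so that the mean of all off-diagonal entries equals
#' `targetMeanRho` (default +0.40).
#'
#' @slot nMetabolites number of metabolites M.
#' @slot nClusters number of correlation clusters.
#' @slot withinClusterRho within-cluster correlation, in \[0, 1).
#' @slot betweenClusterRho cross-cluster correlation in (-1, 1), or `NA_real_`
#'   to solve it from `targetMeanRho`.
#' @slot targetMeanRho target mean of the off-diagonal entries.
#' @slot jitterSd standard deviation of symmetric Gaussian jitter added to
#'   every off-diagonal entry (followed by nearest-PSD repair).
#' @slot negativeBlockFraction fraction of cross-cluster block pairs whose
#'   correlation sign is flipped (secondary-simulation option).
#' @slot pairedHighRho correlation planted on one adjacent metabolite pair
#'   per cluster, or `NA_real_` for none.
#' @export
setClass("CorrelationSpec",
  representation(
    nMetabolites = "integer",
    nClusters = "integer",
    withinClusterRho = "numeric",
    betweenClusterRho = "numeric",
    targetMeanRho = "numeric",
    jitterSd = "numeric",
    negativeBlockFraction = "numeric",
    pairedHighRho = "numeric"
  )
)

setValidity("CorrelationSpec", function(object) {
  msg <- character()
  if (length(object@nMetabolites) != 1L || object@nMetabolites < 2L)
    msg <- c(msg, "nMetabolites must be a single integer >= 2")
  if (length(object@nClusters) != 1L || object@nClusters < 1L ||
      object@nClusters > object@nMetabolites)
    msg <- c(msg, "nClusters must be in [1, nMetabolites]")
  if (object@withinClusterRho < 0 || object@withinClusterRho >= 1)
    msg <- c(msg, "withinClusterRho must lie in [0, 1)")
  if (!is.na(object@betweenClusterRho) &&
      (object@betweenClusterRho <= -1 || object@betweenClusterRho >= 1))
    msg <- c(msg, "betweenClusterRho must lie in (-1, 1)")
  if (object@jitterSd < 0)
    msg <- c(msg, "jitterSd must be nonnegative")
  if (object@negativeBlockFraction < 0 || object@negativeBlockFraction > 1)
    msg <- c(msg, "negativeBlockFraction must lie in [0, 1]")
  if (!is.na(object@pairedHighRho) &&
      (object@pairedHighRho <= 0 || object@pairedHighRho >= 1))
    msg <- c(msg, "pairedHighRho must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a CorrelationSpec
#'
#' @param nMetabolites number of metabolites M.
#' @param nClusters number of equal-size correlation clusters (default 10).
#' @param withinClusterRho within-cluster correlation (default 0.7).
#' @param betweenClusterRho cross-cluster correlation; `NA` (default) solves
#'   it so the off-diagonal mean equals `targetMeanRho`.
#' @param targetMeanRho target mean off-diagonal correlation (default +0.40).
#' @param jitterSd sd of Gaussian jitter on off-diagonal entries
#'   (default 0.05).
#' @param negativeBlockFraction fraction of cross-cluster blocks given
#'   negative sign (default 0).
#' @param pairedHighRho optional correlation for one planted
#'   high-correlation pair per cluster (default none).
#' @return a [CorrelationSpec-class] object.
#' @examples
#' spec <- CorrelationSpec(200)
#' R <- buildCorrelationMatrix(spec, seed = 1)
#' mean(R[upper.tri(R)])
#' @export
CorrelationSpec <- function(nMetabolites, nClusters = 10L,
                            withinClusterRho = 0.7,
                            betweenClusterRho = NA_real_,
                            targetMeanRho = 0.40, jitterSd = 0.05,
                            negativeBlockFraction = 0,
                            pairedHighRho = NA_real_) {
  new("CorrelationSpec",
    nMetabolites = as.integer(nMetabolites),
    nClusters = as.integer(nClusters),
    withinClusterRho = as.numeric(withinClusterRho),
    betweenClusterRho = as.numeric(betweenClusterRho),
    targetMeanRho = as.numeric(targetMeanRho),
    jitterSd = as.numeric(jitterSd),
    negativeBlockFraction = as.numeric(negativeBlockFraction),
    pairedHighRho = as.numeric(pairedHighRho))
}

#' Full specification of one simulated metabolomics study
#'
#' @slot nSubjects number of subjects N.
#' @slot correlation a [CorrelationSpec-class].
#' @slot outcomeType `"continuous"` or `"binary"`.
#' @slot prevalence expected outcome frequency (binary outcomes only).
#' @slot nTrue number of planted true-positive metabolites (default 10).
#' @slot effectSizes nonzero effects in outcome-SD per metabolite-SD units,
#'   one per true metabolite.
#' @slot noiseSd residual sd of the continuous outcome.
#' @slot caseControl if `TRUE`, subsample a binary study to an exact 1:1
#'   case/control ratio after generation.
#' @slot truthPlacement `"spread"` (one true metabolite per cluster, the
#'   default) or `"same_cluster"`.
#' @slot seed integer seed; regeneration under the same config is
#'   bit-identical.
#' @export
setClass("ScenarioConfig",
  representation(
    nSubjects = "integer",
    correlation = "CorrelationSpec",
    outcomeType = "character",
    prevalence = "numeric",
    nTrue = "integer",
    effectSizes = "numeric",
    noiseSd = "numeric",
    caseControl = "logical",
    truthPlacement = "character",
    seed = "integer"
  )
)

setValidity("ScenarioConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 2L)
    msg <- c(msg, "nSubjects must be >= 2")
  if (!object@outcomeType %in% c("continuous", "binary"))
    msg <- c(msg, "outcomeType must be 'continuous' or 'binary'")
  if (object@outcomeType == "binary") {
    if (is.na(object@prevalence) || object@prevalence <= 0 ||
        object@prevalence >= 1)
      msg <- c(msg, "prevalence in (0,1) is required for binary outcomes")
  } else if (!is.na(object@prevalence)) {
    msg <- c(msg, "prevalence must be NA for continuous outcomes")
  }
  if (object@nTrue < 1L || object@nTrue > object@correlation@nMetabolites)
    msg <- c(msg, "nTrue must lie in [1, nMetabolites]")
  if (length(object@effectSizes) != object@nTrue)
    msg <- c(msg, "effectSizes must have length nTrue")
  if (any(object@effectSizes == 0) || any(!is.finite(object@effectSizes)))
    msg <- c(msg, "effectSizes must be finite and nonzero")
  if (object@outcomeType == "continuous" && object@noiseSd <= 0)
    msg <- c(msg, "noiseSd must be positive for continuous outcomes")
  if (!object@truthPlacement %in% c("spread", "same_cluster"))
    msg <- c(msg, "truthPlacement must be 'spread' or 'same_cluster'")
  if (length(msg)) msg else TRUE
})

#' Default planted effect sizes
#'
#' Geometric grid of `n` effects spanning 0.05 to 0.5 outcome-SD per
#' metabolite-SD, covering the "varying effect sizes" range over which power
#' is profiled.
#'
#' @param n number of true-positive metabolites.
#' @return numeric vector of length `n`.
#' @export
defaultEffectSizes <- function(n = 10L) {
  exp(seq(log(0.05), log(0.5), length.out = n))
}

#' Construct a ScenarioConfig
#'
#' @param nSubjects number of subjects N.
#' @param correlation a [CorrelationSpec-class]; defaults to the standard
#'   layout at `nMetabolites`.
#' @param nMetabolites shorthand used when `correlation` is not supplied.
#' @param outcomeType `"continuous"` (default) or `"binary"`.
#' @param prevalence binary outcome frequency in (0,1); required iff binary.
#' @param nTrue number of planted true positives (default 10).
#' @param effectSizes nonzero effect sizes, length `nTrue`
#'   (default [defaultEffectSizes()]).
#' @param noiseSd residual sd of the continuous outcome (default 1).
#' @param caseControl subsample binary studies to exact 1:1 (default FALSE).
#' @param truthPlacement `"spread"` or `"same_cluster"`.
#' @param seed integer seed (default 1).
#' @return a [ScenarioConfig-class] object.
#' @examples
#' cfg <- ScenarioConfig(200, nMetabolites = 200, seed = 7)
#' ds <- simulateDataset(cfg)
#' @export
ScenarioConfig <- function(nSubjects, correlation = NULL, nMetabolites = 200L,
                           outcomeType = c("continuous", "binary"),
                           prevalence = NA_real_, nTrue = 10L,
                           effectSizes = defaultEffectSizes(nTrue),
                           noiseSd = 1, caseControl = FALSE,
                           truthPlacement = "spread", seed = 1L) {
  outcomeType <- match.arg(outcomeType)
  if (is.null(correlation)) correlation <- CorrelationSpec(nMetabolites)
  new("ScenarioConfig",
    nSubjects = as.integer(nSubjects), correlation = correlation,
    outcomeType = outcomeType, prevalence = as.numeric(prevalence),
    nTrue = as.integer(nTrue), effectSizes = as.numeric(effectSizes),
    noiseSd = as.numeric(noiseSd), caseControl = as.logical(caseControl),
    truthPlacement = truthPlacement, seed = as.integer(seed))
}

#' Simulated metabolomics dataset
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' holding one simulated study: the `"levels"` assay stores metabolite levels
#' (metabolites as rows, subjects as columns, standardized population scale),
#' `rowData` carries the planted effect vector `beta` and truth indicator,
#' and `colData$outcome` holds the continuous or 0/1 outcome. The generating
#' [ScenarioConfig-class] is kept in the `config` slot.
#'
#' @slot config the generating [ScenarioConfig-class].
#' @seealso [simulateDataset()], [metabMatrix()], [outcome()], [truthSet()]
#' @export
setClass("SimulatedDataset",
  contains = "SummarizedExperiment",
  representation(config = "ScenarioConfig")
)

setValidity("SimulatedDataset", function(object) {
  msg <- character()
  if (!"levels" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'levels' is required")
  if (is.null(rowData(object)$beta) || is.null(rowData(object)$isTrue))
    msg <- c(msg, "rowData must contain 'beta' and 'isTrue'")
  else if (sum(rowData(object)$isTrue) != object@config@nTrue)
    msg <- c(msg, "number of planted truths must equal config nTrue")
  y <- colData(object)$outcome
  if (is.null(y))
    msg <- c(msg, "colData must contain 'outcome'")
  else if (object@config@outcomeType == "binary" && !all(y %in% c(0, 1)))
    msg <- c(msg, "binary outcome must take values in {0, 1} only")
  if (length(msg)) msg else TRUE
})

#' Cohort-style raw feature table
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with a strictly positive, right-skewed `"intensity"` assay (metabolites as
#' rows, samples as columns) and per-sample covariates `age` (years), `sex`
#' (0/1) and `batch` (factor) in `colData`. No missing values are permitted:
#' the table models panels in which a non-missing value is recorded for every
#' participant.
#'
#' @seealso [generateCohortTable()], [preprocessTable()],
#'   [writeFeatureTable()]
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  else {
    x <- assay(object, "intensity")
    if (anyNA(x)) msg <- c(msg, "intensities must have no missing values")
    else if (any(x <= 0)) msg <- c(msg, "intensities must be strictly positive")
  }
  cd <- colData(object)
  need <- setdiff(c("age", "sex", "batch"), colnames(cd))
  if (length(need))
    msg <- c(msg, paste("colData lacks covariate(s):",
                        paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

.selectionMethods <- c("bonferroni", "fdr", "lasso", "spls", "splsda")
.allMethods <- c("bonferroni", "fdr", "pcr", "lasso", "spls", "splsda",
                 "random_forest")

#' Result of one association method on one dataset
#'
#' @slot method one of `"bonferroni"`, `"fdr"`, `"pcr"`, `"lasso"`,
#'   `"spls"`, `"splsda"`, `"random_forest"`.
#' @slot scores length-M nonnegative importance vector (absolute regression
#'   coefficients for regression-type methods, permutation importance for
#'   random forest).
#' @slot selected selected metabolite indices; present for methods that
#'   perform variable selection (`NULL` for PCR and random forest, which only
#'   rank).
#' @slot tuning named list of chosen tuning-parameter values.
#' @slot pvalues per-metabolite two-sided p-values (univariate methods only).
#' @export
setClass("MethodOutput",
  representation(
    method = "character",
    scores = "numeric",
    selected = "integerOrNULL",
    tuning = "list",
    pvalues = "numericOrNULL"
  )
)

setValidity("MethodOutput", function(object) {
  msg <- character()
  M <- length(object@scores)
  if (!object@method %in% .allMethods)
    msg <- c(msg, paste("unknown method:", object@method))
  if (any(object@scores < 0) || anyNA(object@scores))
    msg <- c(msg, "scores must be nonnegative and non-missing")
  sel <- object@selected
  if (object@method %in% .selectionMethods) {
    if (is.null(sel))
      msg <- c(msg, "selection-capable methods must report a selected set")
    else {
      if (length(sel) && (min(sel) < 1L || max(sel) > M))
        msg <- c(msg, "selected indices out of range")
      if (object@method %in% c("lasso", "spls", "splsda") &&
          length(sel) && any(object@scores[sel] <= 0))
        msg <- c(msg, "sparse-method selected indices must have positive scores")
    }
  } else if (!is.null(sel)) {
    msg <- c(msg, "ranking-only methods must not report a selected set")
  }
  if (!is.null(object@pvalues) &&
      (length(object@pvalues) != M || any(object@pvalues < 0) ||
       any(object@pvalues > 1)))
    msg <- c(msg, "pvalues must be length M and lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

MethodOutput <- function(method, scores, selected = NULL, tuning = list(),
                         pvalues = NULL) {
  new("MethodOutput", method = method, scores = as.numeric(scores),
      selected = if (is.null(selected)) NULL else
        sort(unique(as.integer(selected))),
      tuning = tuning, pvalues = pvalues)
}

#' Confusion counts and operating characteristics of one selection
#'
#' Counts are taken against the planted truth: a false positive is a
#' metabolite selected by the method but not planted as directly associated
#' with the outcome, even when it carries a genuine correlation-induced
#' marginal association. Rates that are undefined (PPV with an empty
#' selection, NPV with a full selection) are stored as `NA`, never as 0.
#'
#' @slot tp,fp,tn,fn confusion counts.
#' @slot sensitivity,specificity,ppv,npv derived rates in \[0,1\] or `NA`.
#' @slot M total number of metabolites.
#' @export
setClass("ConfusionSummary",
  representation(
    tp = "integer", fp = "integer", tn = "integer", fn = "integer",
    sensitivity = "numeric", specificity = "numeric",
    ppv = "numeric", npv = "numeric", M = "integer"
  )
)

setValidity("ConfusionSummary", function(object) {
  if (object@tp + object@fp + object@tn + object@fn != object@M)
    return("confusion counts must sum to M")
  rates <- c(object@sensitivity, object@specificity, object@ppv, object@npv)
  if (any(!is.na(rates) & (rates < 0 | rates > 1)))
    return("rates must lie in [0, 1] or be NA")
  TRUE
})

#' Thresholded Spearman correlation network
#'
#' @slot edges data.frame with columns `from`, `to`, `rho`; one row per
#'   unordered metabolite pair with `rho` above the threshold; no self-edges.
#' @slot nodes character vector of all metabolite ids in the source matrix.
#' @slot threshold the signed Spearman threshold applied.
#' @slot nodeAnnotations named list mapping metabolite id to the character
#'   vector of methods that selected it.
#' @export
setClass("NetworkEdges",
  representation(
    edges = "data.frame",
    nodes = "character",
    threshold = "numeric",
    nodeAnnotations = "list"
  )
)

setValidity("NetworkEdges", function(object) {
  e <- object@edges
  if (!all(c("from", "to", "rho") %in% colnames(e)))
    return("edges must have columns from, to, rho")
  if (nrow(e)) {
    if (any(e$from == e$to)) return("self-edges are not allowed")
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    if (anyDuplicated(key)) return("duplicate edges are not allowed")
    if (any(abs(e$rho) < object@threshold))
      return("all stored |rho| must meet the threshold")
  }
  TRUE
})

setMethod("show", "CorrelationSpec", function(object) {
  b <- if (is.na(object@betweenClusterRho)) "solved from target mean"
       else format(object@betweenClusterRho, digits = 3)
  cat("CorrelationSpec: M =", object@nMetabolites,
      "in", object@nClusters, "clusters\n",
      " within-cluster rho", object@withinClusterRho,
      "| between", b,
      "| target mean", object@targetMeanRho,
      "| jitter sd", object@jitterSd, "\n")
})

setMethod("show", "ScenarioConfig", function(object) {
  cat("ScenarioConfig: N =", object@nSubjects,
      ", M =", object@correlation@nMetabolites,
      ", outcome", object@outcomeType)
  if (object@outcomeType == "binary")
    cat(" (prevalence ", object@prevalence, ")", sep = "")
  cat(",", object@nTrue, "true effects, seed", object@seed, "\n")
})

setMethod("show", "MethodOutput", function(object) {
  cat("MethodOutput:", object@method, "on", length(object@scores),
      "metabolites")
  if (!is.null(object@selected))
    cat(";", length(object@selected), "selected")
  if (length(object@tuning))
    cat("; tuning:", paste(names(object@tuning),
        vapply(object@tuning, function(v) format(v[1], digits = 3), ""),
        sep = "=", collapse = ", "))
  cat("\n")
})

setMethod("show", "ConfusionSummary", function(object) {
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))
  cat("ConfusionSummary: TP", object@tp, "FP", object@fp,
      "TN", object@tn, "FN", object@fn, "\n",
      " sens", fmt(object@sensitivity), "spec", fmt(object@specificity),
      "PPV", fmt(object@ppv), "NPV", fmt(object@npv), "\n")
})

setMethod("show", "NetworkEdges", function(object) {
  cat("NetworkEdges:", nrow(object@edges), "edges over",
      length(object@nodes), "metabolites (threshold",
      object@threshold, ")\n")
})
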