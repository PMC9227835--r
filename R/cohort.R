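## Cohort-style analysis stage: preprocessing, method application with an
## optional batch covariate, set overlap, Spearman correlation network.

#' Log-transform and standardize a raw feature table
#'
#' Applies the standard cohort preprocessing for right-skewed intensity
#' data: natural log transform followed by per-metabolite z-scoring, so that
#' every column has sample mean 0 and sample standard deviation 1.
#'
#' @param table a [FeatureTable-class] with strictly positive intensities.
#' @return numeric samples-by-metabolites matrix of standardized
#'   log-intensities.
#' @examples
#' ft <- generateCohortTable(50, 10, seed = 1)
#' Z <- preprocessTable(ft)
#' max(abs(colMeans(Z)))  # ~ 0 to machine precision
#' @export
preprocessTable <- function(table) {
  stopifnot(is(table, "FeatureTable"))
  X <- intensityMatrix(table)
  if (any(X <= 0)) {
    bad <- which(X <= 0, arr.ind = TRUE)[1, ]
    stop("nonpositive intensity for sample '", rownames(X)[bad[1]],
         "', metabolite '", colnames(X)[bad[2]], "'")
  }
  L <- log(X)
  s <- apply(L, 2L, stats::sd)
  if (any(s < 1e-12)) {
    bad <- colnames(L)[which(s < 1e-12)[1]]
    stop("metabolite '", bad, "' has zero variance and cannot be ",
         "standardized")
  }
  scale(L, center = TRUE, scale = s)
}

#' Run the cohort analysis methods on a standardized matrix
#'
#' Applies the univariate scan with Bonferroni and Benjamini-Hochberg
#' selection, the LASSO, and sparse PLS (continuous outcome) or sparse
#' PLS-DA (binary outcome) with cross-validated tuning under the
#' sparsest-within-one-SE rule. A batch covariate, when supplied, enters the
#' univariate models and the LASSO unpenalized, and is residualized out of
#' the metabolite matrix (and a continuous outcome) before the sparse PLS
#' step.
#'
#' @param Z standardized samples-by-metabolites matrix (see
#'   [preprocessTable()]).
#' @param outcome outcome vector (e.g. age or a 0/1 sex indicator).
#' @param outcomeType `"continuous"` or `"binary"`.
#' @param batch optional batch factor/covariate.
#' @param alpha Bonferroni family-wise level (default 0.05).
#' @param q false-discovery level (default 0.1).
#' @param etaGrid,KGrid tuning grids for the sparse PLS step.
#' @param foldSeed seed for all CV fold assignments.
#' @return named list of [MethodOutput-class] objects
#'   (`bonferroni`, `fdr`, `lasso`, and `spls` or `splsda`).
#' @export
runCohortMethods <- function(Z, outcome,
                             outcomeType = c("continuous", "binary"),
                             batch = NULL, alpha = 0.05, q = 0.1,
                             etaGrid = seq(0.1, 0.9, by = 0.1),
                             KGrid = 1:5, foldSeed = 1L) {
  outcomeType <- match.arg(outcomeType)
  Z <- as.matrix(Z)
  if (length(outcome) != nrow(Z))
    stop("outcome length must match the number of samples")
  covar <- if (is.null(batch)) NULL else data.frame(batch = batch)

  scan <- suppressWarnings(univariateScan(Z, outcome, outcomeType,
                                          covariates = covar))
  out <- list(
    bonferroni = MethodOutput("bonferroni",
      scores = abs(scan$coefficients),
      selected = bonferroniSelect(scan$pvalues, alpha),
      pvalues = scan$pvalues, tuning = list(alpha = alpha)),
    fdr = MethodOutput("fdr", scores = abs(scan$coefficients),
      selected = bhSelect(scan$pvalues, q),
      pvalues = scan$pvalues, tuning = list(q = q)),
    lasso = lassoFit(Z, outcome, outcomeType, covariates = covar,
                     foldSeed = foldSeed))

  Zs <- Z
  ys <- outcome
  if (!is.null(batch)) {
    D <- stats::model.matrix(~ ., data = data.frame(batch = batch))
    Zs <- Z - qr.fitted(qr(D), Z)
    if (outcomeType == "continuous")
      ys <- stats::residuals(stats::lm.fit(D, outcome))
  }
  if (outcomeType == "continuous") {
    tp <- tuneSparse(Zs, ys, "spls", etaGrid = etaGrid, KGrid = KGrid,
                     foldSeed = foldSeed)
    out$spls <- splsFit(Zs, ys, eta = tp$eta,
                        nComponents = tp$n_components)
  } else {
    tp <- tuneSparse(Zs, ys, "splsda", etaGrid = etaGrid, KGrid = KGrid,
                     foldSeed = foldSeed)
    out$splsda <- splsdaFit(Zs, ys, eta = tp$eta,
                            nComponents = tp$n_components)
  }
  out
}

#' Three-set Venn region counts
#'
#' Counts for the seven regions of the three-set Venn partition. The region
#' names are built from the set names (e.g. `"fdr_only"`,
#' `"fdr_lasso"`, `"fdr_lasso_spls"`); counts sum to the size of the union.
#'
#' @param sets named list of exactly three index/id sets.
#' @return named integer vector of length 7.
#' @examples
#' vennCounts(list(A = c(1, 2), B = c(2, 3), C = 2))
#' @export
vennCounts <- function(sets) {
  if (length(sets) != 3L || is.null(names(sets)) ||
      any(!nzchar(names(sets))))
    stop("exactly three named sets are required")
  n <- names(sets)
  a <- unique(sets[[1]]); b <- unique(sets[[2]]); d <- unique(sets[[3]])
  u <- union(union(a, b), d)
  inA <- u %in% a; inB <- u %in% b; inC <- u %in% d
  counts <- c(
    sum(inA & !inB & !inC), sum(!inA & inB & !inC),
    sum(!inA & !inB & inC), sum(inA & inB & !inC),
    sum(inA & !inB & inC), sum(!inA & inB & inC),
    sum(inA & inB & inC))
  names(counts) <- c(
    paste0(n[1], "_only"), paste0(n[2], "_only"), paste0(n[3], "_only"),
    paste(n[1], n[2], sep = "_"), paste(n[1], n[3], sep = "_"),
    paste(n[2], n[3], sep = "_"), paste(n[1], n[2], n[3], sep = "_"))
  counts
}

#' Thresholded Spearman correlation network
#'
#' Estimates Spearman rank correlations for all metabolite pairs and keeps
#' the pairs whose signed correlation exceeds the threshold (default +0.75).
#' Because Spearman correlation is rank-based, it is invariant to the
#' monotone log/z-score preprocessing, so the network is identical whether
#' computed on raw or standardized values. Node annotations (which methods
#' selected each metabolite) can be attached for downstream visualization.
#'
#' @param Z samples-by-metabolites matrix (at least 3 samples).
#' @param threshold signed correlation threshold in (0, 1); default +0.75
#'   (a looser conventional choice is 0.65).
#' @param annotations optional named list or named list of
#'   [MethodOutput-class]s mapping metabolite id to selecting methods; when
#'   a list of MethodOutputs is given, annotations are derived from their
#'   selected sets.
#' @return a [NetworkEdges-class].
#' @export
spearmanNetwork <- function(Z, threshold = 0.75, annotations = NULL) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 3L)
    stop("at least 3 samples are required for rank correlation")
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  ids <- colnames(Z)
  if (is.null(ids)) ids <- sprintf("met_%04d", seq_len(ncol(Z)))
  rho <- stats::cor(Z, method = "spearman")
  keep <- which(upper.tri(rho) & rho > threshold, arr.ind = TRUE)
  edges <- data.frame(from = ids[keep[, 1]], to = ids[keep[, 2]],
                      rho = rho[keep], stringsAsFactors = FALSE)

  ann <- list()
  if (!is.null(annotations)) {
    if (length(annotations) && is(annotations[[1]], "MethodOutput")) {
      for (m in names(annotations)) {
        sel <- selectedSet(annotations[[m]])
        for (j in sel) {
          id <- ids[j]
          ann[[id]] <- c(ann[[id]], m)
        }
      }
    } else ann <- annotations
  }
  new("NetworkEdges", edges = edges, nodes = ids, threshold = threshold,
      nodeAnnotations = ann)
}

#' Export a correlation network as JSON and GraphML
#'
#' Writes (a) a JSON document `{nodes: [{id, methods: [...]}], links:
#' [{source, target, rho}]}` suitable for force-layout visualization
#' frameworks, and (b) a GraphML file with `rho` as an edge attribute and
#' per-method selection flags as node attributes.
#'
#' @param net a [NetworkEdges-class].
#' @param jsonPath output path for the JSON document (`NULL` to skip).
#' @param graphmlPath output path for the GraphML file (`NULL` to skip).
#' @return invisibly, the paths written.
#' @export
exportNetwork <- function(net, jsonPath = NULL, graphmlPath = NULL) {
  stopifnot(is(net, "NetworkEdges"))
  written <- character()
  methodsOf <- function(id) {
    m <- net@nodeAnnotations[[id]]
    if (is.null(m)) character(0) else as.character(m)
  }
  if (!is.null(jsonPath)) {
    doc <- list(
      nodes = lapply(net@nodes, function(id)
        list(id = id, methods = I(methodsOf(id)))),
      links = if (nrow(net@edges))
        lapply(seq_len(nrow(net@edges)), function(i)
          list(source = net@edges$from[i], target = net@edges$to[i],
               rho = net@edges$rho[i]))
      else list())
    jsonlite::write_json(doc, jsonPath, auto_unbox = TRUE, digits = NA)
    written <- c(written, jsonPath)
  }
  if (!is.null(graphmlPath)) {
    g <- igraph::graph_from_data_frame(
      net@edges, directed = FALSE,
      vertices = data.frame(name = net@nodes, stringsAsFactors = FALSE))
    methodNames <- sort(unique(unlist(net@nodeAnnotations)))
    annStr <- vapply(net@nodes, function(id)
      paste(methodsOf(id), collapse = ","), "")
    g <- igraph::set_vertex_attr(g, "methods", value = annStr)
    for (m in methodNames) {
      flag <- vapply(net@nodes, function(id) m %in% methodsOf(id),
                     logical(1))
      g <- igraph::set_vertex_attr(g, paste0("selected_", m),
                                   value = as.integer(flag))
    }
    igraph::write_graph(g, graphmlPath, format = "graphml")
    written <- c(written, graphmlPath)
  }
  invisible(written)
}
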