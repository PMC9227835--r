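## Serialization: scenario configs to/from YAML and JSON, feature tables
## to/from TSV, method outputs to JSON.

.configToList <- function(cfg) {
  sp <- cfg@correlation
  list(
    n_subjects = cfg@nSubjects,
    correlation = list(
      n_metabolites = sp@nMetabolites,
      n_clusters = sp@nClusters,
      within_cluster_rho = sp@withinClusterRho,
      between_cluster_rho = sp@betweenClusterRho,
      target_mean_rho = sp@targetMeanRho,
      jitter_sd = sp@jitterSd,
      negative_block_fraction = sp@negativeBlockFraction,
      paired_high_rho = sp@pairedHighRho),
    outcome_type = cfg@outcomeType,
    prevalence = cfg@prevalence,
    n_true = cfg@nTrue,
    effect_sizes = cfg@effectSizes,
    noise_sd = cfg@noiseSd,
    case_control = cfg@caseControl,
    truth_placement = cfg@truthPlacement,
    seed = cfg@seed)
}

.listToConfig <- function(x) {
  nullNA <- function(v, default = NA_real_) if (is.null(v) ||
    (length(v) == 1 && is.na(v))) default else v
  co <- x$correlation
  spec <- CorrelationSpec(
    nMetabolites = co$n_metabolites,
    nClusters = nullNA(co$n_clusters, 10L),
    withinClusterRho = nullNA(co$within_cluster_rho, 0.7),
    betweenClusterRho = nullNA(co$between_cluster_rho),
    targetMeanRho = nullNA(co$target_mean_rho, 0.40),
    jitterSd = nullNA(co$jitter_sd, 0.05),
    negativeBlockFraction = nullNA(co$negative_block_fraction, 0),
    pairedHighRho = nullNA(co$paired_high_rho))
  nTrue <- as.integer(nullNA(x$n_true, 10L))
  ScenarioConfig(
    nSubjects = x$n_subjects, correlation = spec,
    outcomeType = x$outcome_type,
    prevalence = as.numeric(nullNA(x$prevalence)),
    nTrue = nTrue,
    effectSizes = unlist(nullNA(x$effect_sizes,
                                defaultEffectSizes(nTrue))),
    noiseSd = nullNA(x$noise_sd, 1),
    caseControl = isTRUE(x$case_control),
    truthPlacement = nullNA(x$truth_placement, "spread"),
    seed = as.integer(nullNA(x$seed, 1L)))
}

#' Read and write scenario configurations
#'
#' Scenario configurations serialize to YAML or JSON (chosen from the file
#' extension) with snake_case keys mirroring the configuration fields:
#' `n_subjects`, `correlation` (with `n_metabolites`, `n_clusters`,
#' `within_cluster_rho`, `between_cluster_rho`, `target_mean_rho`,
#' `jitter_sd`, `negative_block_fraction`, `paired_high_rho`),
#' `outcome_type`, `prevalence`, `n_true`, `effect_sizes`, `noise_sd`,
#' `case_control`, `truth_placement`, `seed`.
#'
#' @param config a [ScenarioConfig-class].
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return `writeScenarioConfig` invisibly returns `path`;
#'   `readScenarioConfig` returns a [ScenarioConfig-class].
#' @export
writeScenarioConfig <- function(config, path) {
  stopifnot(is(config, "ScenarioConfig"))
  x <- .configToList(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path, precision = 15L)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else stop("path must end in .yaml, .yml, or .json")
  invisible(path)
}

#' @rdname writeScenarioConfig
#' @export
readScenarioConfig <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("path must end in .yaml, .yml, or .json")
  .listToConfig(x)
}

#' Read and write cohort feature tables as TSV
#'
#' The TSV dialect has one row per sample: a `sample_id` column, the
#' covariate columns `age`, `sex`, `batch`, then one column per metabolite
#' id. UTF-8 encoding, '.' decimal separator.
#'
#' @param table a [FeatureTable-class].
#' @param path TSV file path.
#' @return `writeFeatureTable` invisibly returns `path`;
#'   `readFeatureTable` returns a [FeatureTable-class].
#' @export
writeFeatureTable <- function(table, path) {
  stopifnot(is(table, "FeatureTable"))
  X <- intensityMatrix(table)
  cd <- covariateData(table)
  df <- data.frame(sample_id = rownames(X), age = cd$age, sex = cd$sex,
                   batch = as.character(cd$batch), X,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("sample_id", "age", "sex", "batch")
  if (!all(need %in% colnames(df)))
    stop("feature table TSV must contain columns: ",
         paste(need, collapse = ", "))
  metCols <- setdiff(colnames(df), need)
  X <- as.matrix(df[, metCols, drop = FALSE])
  rownames(X) <- df$sample_id
  se <- SummarizedExperiment(
    assays = list(intensity = t(X)),
    colData = DataFrame(age = df$age, sex = df$sex,
                        batch = factor(df$batch),
                        row.names = df$sample_id))
  new("FeatureTable", se)
}

#' Serialize a method output to JSON
#'
#' Uniform JSON form `{method, tuning, selected: [...], scores: [...]}`
#' shared by all methods.
#'
#' @param x a [MethodOutput-class].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to a file).
#' @export
methodOutputToJSON <- function(x, path = NULL) {
  stopifnot(is(x, "MethodOutput"))
  doc <- list(method = x@method,
              tuning = lapply(x@tuning, function(v)
                if (length(v) == 1) unname(v) else unname(as.vector(v))),
              selected = if (is.null(x@selected)) NULL else
                I(x@selected),
              scores = x@scores)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}
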