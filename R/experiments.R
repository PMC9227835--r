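## Scenario orchestration: replicate loops, seeding, aggregation, the
## full study-design grid.

#' Grid of simulation scenarios
#'
#' @slot scenarios list of [ScenarioConfig-class] objects.
#' @slot nReplicates replicates per scenario.
#' @slot methods subset of the available methods.
#' @slot masterSeed master seed; per-scenario and per-replicate seeds are
#'   derived from it so any replicate is reproducible in isolation.
#' @export
setClass("GridSpec",
  representation(scenarios = "list", nReplicates = "integer",
                 methods = "character", masterSeed = "integer"))

setValidity("GridSpec", function(object) {
  msg <- character()
  if (!length(object@scenarios))
    msg <- c(msg, "scenario list must be non-empty")
  if (!length(object@methods))
    msg <- c(msg, "methods must be non-empty")
  bad <- setdiff(object@methods, .allMethods)
  if (length(bad))
    msg <- c(msg, paste("unknown method(s):", paste(bad, collapse = ", ")))
  if (object@nReplicates < 1L)
    msg <- c(msg, "nReplicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname GridSpec-class
#' @param scenarios list of [ScenarioConfig-class] objects
#'   (default [tableOneGrid()]).
#' @param nReplicates replicates per scenario (default 100; the full study
#'   design uses 1000).
#' @param methods methods to run (default all six procedures, with the two
#'   univariate corrections counted separately).
#' @param masterSeed integer master seed.
#' @export
GridSpec <- function(scenarios = tableOneGrid(), nReplicates = 100L,
                     methods = .allMethods, masterSeed = 1L) {
  new("GridSpec", scenarios = scenarios,
      nReplicates = as.integer(nReplicates),
      methods = methods, masterSeed = as.integer(masterSeed))
}

# Counter-based derived seed: exact in double arithmetic, below 2^31.
.deriveSeed <- function(master, counter) {
  s <- (abs(as.double(master)) %% 2147483647) + 1
  as.integer((s * 48271 + as.double(counter) * 16807) %% 2147483647)
}

#' The default scenario grid
#'
#' The twelve primary study designs — all combinations of M in {200, 2000}
#' metabolites and N in {200, 1000, 5000} subjects for a continuous outcome
#' and for a binary outcome (20% frequency at N = 200, mimicking larger
#' observational cohorts' case fraction at small N per the tabulated
#' designs; 50% at N = 1000 and 5000, the 1:1 case-control reading) — plus
#' optional small-sample variants at N in {50, 100} with M = 200.
#'
#' @param includeSmallN add the N = 50 and N = 100 secondary variants
#'   (default TRUE).
#' @param masterSeed seed base from which each scenario's seed is derived.
#' @return named list of [ScenarioConfig-class] objects.
#' @export
tableOneGrid <- function(includeSmallN = TRUE, masterSeed = 1L) {
  rows <- list(
    list(outcome = "continuous", M = 200L, N = 200L, prev = NA),
    list(outcome = "continuous", M = 200L, N = 1000L, prev = NA),
    list(outcome = "continuous", M = 200L, N = 5000L, prev = NA),
    list(outcome = "continuous", M = 2000L, N = 200L, prev = NA),
    list(outcome = "continuous", M = 2000L, N = 1000L, prev = NA),
    list(outcome = "continuous", M = 2000L, N = 5000L, prev = NA),
    list(outcome = "binary", M = 200L, N = 200L, prev = 0.2),
    list(outcome = "binary", M = 200L, N = 1000L, prev = 0.5),
    list(outcome = "binary", M = 200L, N = 5000L, prev = 0.5),
    list(outcome = "binary", M = 2000L, N = 200L, prev = 0.2),
    list(outcome = "binary", M = 2000L, N = 1000L, prev = 0.5),
    list(outcome = "binary", M = 2000L, N = 5000L, prev = 0.5))
  if (includeSmallN)
    rows <- c(rows, list(
      list(outcome = "continuous", M = 200L, N = 50L, prev = NA),
      list(outcome = "continuous", M = 200L, N = 100L, prev = NA),
      list(outcome = "binary", M = 200L, N = 50L, prev = 0.2),
      list(outcome = "binary", M = 200L, N = 100L, prev = 0.2)))
  out <- lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    ScenarioConfig(r$N, nMetabolites = r$M, outcomeType = r$outcome,
                   prevalence = if (is.na(r$prev)) NA_real_ else r$prev,
                   seed = .deriveSeed(masterSeed, i * 1000L))
  })
  names(out) <- vapply(rows, function(r)
    sprintf("%s_M%d_N%d", substr(r$outcome, 1, 4), r$M, r$N), "")
  out
}

# Run one method on one standardized dataset; returns a MethodOutput.
.runMethod <- function(method, Z, y, outcomeType, scan, repSeed, opts) {
  switch(method,
    bonferroni = {
      sel <- bonferroniSelect(scan$pvalues,
                              opts$alpha %||% 0.05)
      MethodOutput("bonferroni", scores = abs(scan$coefficients),
                   selected = sel, pvalues = scan$pvalues,
                   tuning = list(alpha = opts$alpha %||% 0.05))
    },
    fdr = {
      sel <- bhSelect(scan$pvalues, opts$q %||% 0.1)
      MethodOutput("fdr", scores = abs(scan$coefficients),
                   selected = sel, pvalues = scan$pvalues,
                   tuning = list(q = opts$q %||% 0.1))
    },
    pcr = pcrImportance(Z, y, outcomeType,
                        nComponents = opts$nComponents),
    lasso = lassoFit(Z, y, outcomeType, foldSeed = repSeed,
                     nFolds = opts$nFolds %||% 5L),
    spls = {
      tp <- tuneSparse(Z, y, "spls", outcomeType,
                       etaGrid = opts$etaGrid %||% seq(0.1, 0.9, 0.1),
                       KGrid = opts$KGrid %||% 1:5,
                       nFolds = opts$nFolds %||% 5L, foldSeed = repSeed)
      splsFit(Z, y, eta = tp$eta, nComponents = tp$n_components)
    },
    splsda = {
      tp <- tuneSparse(Z, y, "splsda",
                       etaGrid = opts$etaGrid %||% seq(0.1, 0.9, 0.1),
                       KGrid = opts$KGrid %||% 1:5,
                       nFolds = opts$nFolds %||% 5L, foldSeed = repSeed)
      splsdaFit(Z, y, eta = tp$eta, nComponents = tp$n_components)
    },
    random_forest = rfImportance(Z, y, outcomeType,
                                 nTrees = opts$nTrees %||% 500L,
                                 seed = repSeed),
    stop("unknown method: ", method))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Standardize columns to sample mean 0 / sd 1; constant columns become 0.
.standardize <- function(X) {
  s <- apply(X, 2L, stats::sd)
  s[s < 1e-12] <- 1
  scale(X, center = TRUE, scale = s)
}

#' Run one scenario over replicates
#'
#' For each replicate: simulate a dataset (replicate seeds derived from the
#' master seed so each replicate is independently reproducible), standardize
#' the metabolite columns, run every requested method, score the selection
#' methods against the planted truth with [confusion()], and record every
#' method's top-10 ranking. A method failing on one replicate is recorded as
#' missing for that replicate (with its error message) and the run
#' continues. Per-replicate rows are written to `outDir` (append-only CSV)
#' before aggregation when an output directory is given.
#'
#' The binary-outcome univariate scan can be switched to the
#' linear-probability model through `methodOptions$scan$binaryModel`.
#'
#' @param config a [ScenarioConfig-class].
#' @param nReplicates number of replicates.
#' @param methods character vector of methods to run.
#' @param masterSeed integer master seed.
#' @param outDir optional directory for per-replicate CSV persistence.
#' @param methodOptions named list of per-method option lists (e.g.
#'   `list(spls = list(etaGrid = c(0.5, 0.9)))`).
#' @param label scenario label used in outputs.
#' @return list with `perReplicate` (one row per replicate and method),
#'   `aggregated` (scenario, method, metric, mean, se, n_reps), `selections`
#'   and `rankings` (per-method, per-replicate index sets / score orders),
#'   and `betas` (per-replicate planted effect vectors, for
#'   power-by-effect-size analyses).
#' @export
runScenario <- function(config, nReplicates, methods = .allMethods,
                        masterSeed = 1L, outDir = NULL,
                        methodOptions = list(),
                        label = sprintf("%s_M%d_N%d",
                                        substr(config@outcomeType, 1, 4),
                                        config@correlation@nMetabolites,
                                        config@nSubjects)) {
  if (!length(methods)) stop("methods must be non-empty")
  bad <- setdiff(methods, .allMethods)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  if (config@outcomeType == "continuous" &&
      any(c("splsda") %in% methods))
    stop("splsda requires a binary outcome")
  if (config@outcomeType == "binary" && "spls" %in% methods)
    stop("spls requires a continuous outcome; use splsda")

  M <- config@correlation@nMetabolites
  csvPath <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    csvPath <- file.path(outDir, paste0(label, "_replicates.csv"))
  }

  rows <- vector("list", nReplicates * length(methods))
  summaries <- lapply(methods, function(m) list())
  names(summaries) <- methods
  rankings <- lapply(methods, function(m) list())
  names(rankings) <- methods
  hitFracs <- lapply(methods, function(m) numeric(0))
  names(hitFracs) <- methods
  selections <- lapply(methods, function(m) list())
  names(selections) <- methods
  betas <- vector("list", nReplicates)
  ri <- 0L

  for (r in seq_len(nReplicates)) {
    repSeed <- .deriveSeed(masterSeed, r)
    cfg <- config
    cfg@seed <- repSeed
    ds <- simulateDataset(cfg)
    Z <- .standardize(metabMatrix(ds))
    y <- outcome(ds)
    truth <- truthSet(ds)
    betas[[r]] <- effectVector(ds)
    scanOpts <- methodOptions$scan %||% list()
    scan <- NULL
    if (any(c("bonferroni", "fdr") %in% methods))
      scan <- suppressWarnings(univariateScan(
        Z, y, config@outcomeType,
        binaryModel = scanOpts$binaryModel %||% "logistic"))

    for (m in methods) {
      ri <- ri + 1L
      res <- tryCatch(
        suppressWarnings(.runMethod(m, Z, y, config@outcomeType, scan,
                                    repSeed, methodOptions[[m]] %||% list())),
        error = function(e) e)
      if (inherits(res, "error")) {
        rows[[ri]] <- data.frame(
          scenario = label, rep = r, method = m, tp = NA, fp = NA, tn = NA,
          fn = NA, sensitivity = NA, specificity = NA, ppv = NA, npv = NA,
          n_selected = NA, top10_truth = NA,
          error = conditionMessage(res))
        next
      }
      rk <- topK(methodScores(res), min(10L, M))
      rankings[[m]][[length(rankings[[m]]) + 1L]] <- rk
      hitFracs[[m]] <- c(hitFracs[[m]], sum(rk %in% truth) / length(truth))
      sel <- selectedSet(res)
      cs <- NULL
      if (!is.null(sel)) {
        cs <- confusion(sel, truth, M)
        summaries[[m]][[length(summaries[[m]]) + 1L]] <- cs
        selections[[m]][[length(selections[[m]]) + 1L]] <- sel
      }
      rows[[ri]] <- data.frame(
        scenario = label, rep = r, method = m,
        tp = if (is.null(cs)) NA else cs@tp,
        fp = if (is.null(cs)) NA else cs@fp,
        tn = if (is.null(cs)) NA else cs@tn,
        fn = if (is.null(cs)) NA else cs@fn,
        sensitivity = if (is.null(cs)) NA else cs@sensitivity,
        specificity = if (is.null(cs)) NA else cs@specificity,
        ppv = if (is.null(cs)) NA else cs@ppv,
        npv = if (is.null(cs)) NA else cs@npv,
        n_selected = if (is.null(sel)) NA else length(sel),
        top10_truth = sum(rk %in% truth),
        error = NA_character_)
      if (!is.null(csvPath))
        utils::write.table(rows[[ri]], csvPath, sep = ",",
                           row.names = FALSE,
                           col.names = !file.exists(csvPath),
                           append = file.exists(csvPath))
    }
  }

  perRep <- do.call(rbind, rows)
  agg <- lapply(methods, function(m) {
    base <- data.frame(scenario = label, method = m)
    parts <- list()
    if (length(summaries[[m]])) {
      a <- aggregateSummaries(summaries[[m]])
      parts$conf <- cbind(base, a, row.names = NULL)
    }
    hf <- hitFracs[[m]]
    if (length(hf)) {
      # mean over replicates of (fraction of that replicate's truth set
      # ranked in the top 10); truth placement varies per replicate.
      parts$top10 <- cbind(base,
        data.frame(metric = "top10_hit_rate", mean = mean(hf),
                   se = if (length(hf) > 1)
                     stats::sd(hf) / sqrt(length(hf)) else 0,
                   n = length(hf)), row.names = NULL)
    }
    do.call(rbind, parts)
  })
  agg <- do.call(rbind, agg)
  names(agg)[names(agg) == "n"] <- "n_reps"
  rownames(agg) <- NULL
  list(perReplicate = perRep, aggregated = agg,
       selections = selections, rankings = rankings, betas = betas)
}

#' Run a full scenario grid
#'
#' Executes [runScenario()] for every scenario in the grid, concatenating
#' the aggregated results and recording a run manifest (per-scenario config
#' hash, master seed, package version, wall time). A scenario that fails is
#' isolated: its error is recorded in the manifest and the remaining
#' scenarios still run. Binary scenarios automatically swap `spls` for
#' `splsda` (and drop it the other way around).
#'
#' @param grid a [GridSpec-class].
#' @param outDir optional output directory; aggregated results are written
#'   as tidy CSV and the manifest as YAML.
#' @param methodOptions passed to [runScenario()].
#' @return list with `results` (tidy data.frame) and `manifest`.
#' @export
runGrid <- function(grid, outDir = NULL, methodOptions = list()) {
  validObject(grid)
  t0 <- Sys.time()
  results <- list()
  errors <- list()
  hashes <- character()
  for (i in seq_along(grid@scenarios)) {
    cfg <- grid@scenarios[[i]]
    label <- names(grid@scenarios)[i] %||%
      sprintf("scenario_%02d", i)
    if (is.null(label) || !nzchar(label)) label <- sprintf("scenario_%02d", i)
    meths <- grid@methods
    if (cfg@outcomeType == "binary")
      meths <- setdiff(unique(sub("^spls$", "splsda", meths)), "spls")
    else
      meths <- setdiff(unique(sub("^splsda$", "spls", meths)), "splsda")
    tmp <- tempfile(fileext = ".yaml")
    writeScenarioConfig(cfg, tmp)
    hashes[label] <- unname(tools::md5sum(tmp))
    unlink(tmp)
    res <- tryCatch(
      runScenario(cfg, grid@nReplicates, meths,
                  masterSeed = .deriveSeed(grid@masterSeed, i),
                  outDir = outDir, methodOptions = methodOptions,
                  label = label),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[label]] <- conditionMessage(res)
      message("scenario ", label, " failed: ", conditionMessage(res))
    } else {
      results[[label]] <- res$aggregated
    }
    message("completed scenario ", i, "/", length(grid@scenarios),
            ": ", label)
  }
  resTab <- do.call(rbind, results)
  rownames(resTab) <- NULL
  manifest <- list(
    master_seed = grid@masterSeed,
    n_replicates = grid@nReplicates,
    methods = grid@methods,
    scenario_hashes = as.list(hashes),
    package_version = as.character(utils::packageVersion("metaboBench")),
    wall_time_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    errors = errors)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(resTab, file.path(outDir, "grid_results.csv"),
                     row.names = FALSE)
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  }
  list(results = resTab, manifest = manifest)
}
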