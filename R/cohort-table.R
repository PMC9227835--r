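## Synthetic cohort-style raw feature table: right-skewed intensities with
## age/sex/batch covariates and planted associations, for exercising the
## cohort preprocessing and analysis stage. Entirely synthetic; no real
## cohort measurements are involved.

#' Generate a synthetic cohort-style raw feature table
#'
#' Emulates the raw output of a cohort metabolomics panel: strictly
#' positive, right-skewed intensities obtained as the exponential of a
#' correlated Gaussian field on the log scale, with covariate effects added
#' on the log scale. Age (years), sex (0/1) and specimen batch are generated
#' per sample; metabolites in `plantedAgeSet` receive a log-intensity shift
#' of `ageEffect` per SD of age, metabolites in `plantedSexSet` a shift of
#' `sexEffect` for sex = 1, and every metabolite receives an independent
#' batch offset with sd `batchSd`. Every intensity is positive and
#' non-missing, so the table is always log-transformable.
#'
#' @param nSamples number of samples.
#' @param nMetabolites number of metabolites.
#' @param plantedAgeSet metabolite indices truly associated with age.
#' @param plantedSexSet metabolite indices truly associated with sex.
#' @param nBatches number of specimen batches (default 3).
#' @param seed integer seed; generation is reproducible.
#' @param ageEffect log-intensity shift per SD of age on the planted age set
#'   (default 0.5).
#' @param sexEffect log-intensity shift for sex = 1 on the planted sex set
#'   (default 0.5).
#' @param batchSd sd of per-(batch, metabolite) log-intensity offsets
#'   (default 0.2).
#' @param biologicalSd sd of the correlated biological log-intensity field
#'   (default 0.5).
#' @return a [FeatureTable-class]; the planted sets are recorded in its
#'   metadata.
#' @examples
#' ft <- generateCohortTable(100, 40, plantedAgeSet = 1:5, seed = 2)
#' all(intensityMatrix(ft) > 0)
#' @export
generateCohortTable <- function(nSamples, nMetabolites,
                                plantedAgeSet = integer(0),
                                plantedSexSet = integer(0),
                                nBatches = 3L, seed = 1L,
                                ageEffect = 0.5, sexEffect = 0.5,
                                batchSd = 0.2, biologicalSd = 0.5) {
  stopifnot(nSamples >= 2, nMetabolites >= 2, nBatches >= 1)
  plantedAgeSet <- as.integer(plantedAgeSet)
  plantedSexSet <- as.integer(plantedSexSet)
  if (length(plantedAgeSet) && (min(plantedAgeSet) < 1 ||
      max(plantedAgeSet) > nMetabolites))
    stop("plantedAgeSet indices out of range")
  if (length(plantedSexSet) && (min(plantedSexSet) < 1 ||
      max(plantedSexSet) > nMetabolites))
    stop("plantedSexSet indices out of range")

  .withSeed(seed, {
    N <- as.integer(nSamples); M <- as.integer(nMetabolites)
    age <- stats::rnorm(N, 55, 10)
    sex <- stats::rbinom(N, 1L, 0.5)
    batch <- factor(sample(seq_len(nBatches), N, replace = TRUE))

    # Explicit between-cluster level (no target-mean solving) so the
    # field stays feasible for any metabolite count, including tiny
    # tables with a single cluster.
    spec <- CorrelationSpec(M, nClusters = max(1L, min(10L, M %/% 5L)),
                            withinClusterRho = 0.7,
                            betweenClusterRho = 0.25)
    S <- .matrixSqrt(buildCorrelationMatrix(spec))
    field <- (matrix(stats::rnorm(N * M), N, M) %*% S) * biologicalSd

    baseline <- stats::runif(M, log(1e4), log(1e6))
    logI <- sweep(field, 2L, baseline, "+")
    ageZ <- (age - mean(age)) / stats::sd(age)
    if (length(plantedAgeSet))
      logI[, plantedAgeSet] <- logI[, plantedAgeSet] + ageEffect * ageZ
    if (length(plantedSexSet))
      logI[, plantedSexSet] <- logI[, plantedSexSet] + sexEffect * sex
    batchShift <- matrix(stats::rnorm(nBatches * M, 0, batchSd), nBatches, M)
    logI <- logI + batchShift[as.integer(batch), , drop = FALSE]

    metIds <- sprintf("met_%04d", seq_len(M))
    sampleIds <- sprintf("S%05d", seq_len(N))
    intens <- t(exp(logI))
    dimnames(intens) <- list(metIds, sampleIds)
    se <- SummarizedExperiment(
      assays = list(intensity = intens),
      colData = DataFrame(age = age, sex = sex, batch = batch,
                          row.names = sampleIds))
    metadata(se)$plantedAgeSet <- plantedAgeSet
    metadata(se)$plantedSexSet <- plantedSexSet
    new("FeatureTable", se)
  })
}
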