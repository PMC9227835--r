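## Dataset simulation: multivariate-normal metabolite levels, planted
## effects, continuous or prevalence-calibrated binary outcomes.

#' Calibrate the logistic intercept for a target outcome prevalence
#'
#' Finds the intercept `c` such that the sample average of
#' `plogis(c + linearPredictor)` equals `targetPrevalence`. The mean fitted
#' probability is strictly increasing in `c`, so the root is unique;
#' bracketed root-finding is polished with Newton steps to an absolute
#' tolerance of 1e-12 on the prevalence scale.
#'
#' @param linearPredictor numeric vector of subject-level linear predictors.
#' @param targetPrevalence target expected outcome frequency, in (0, 1).
#' @return the calibrated intercept (scalar).
#' @examples
#' calibrateBinaryIntercept(rep(0, 100), 0.5)        # 0
#' calibrateBinaryIntercept(rep(0, 100), 0.2)        # log(0.25)
#' @export
calibrateBinaryIntercept <- function(linearPredictor, targetPrevalence) {
  if (any(!is.finite(linearPredictor)))
    stop("linearPredictor must be finite")
  if (targetPrevalence <= 0 || targetPrevalence >= 1)
    stop("targetPrevalence must lie in (0, 1)")
  f <- function(c) mean(stats::plogis(c + linearPredictor)) - targetPrevalence
  c0 <- stats::uniroot(f, c(-40, 40), extendInt = "upX",
                       tol = .Machine$double.eps^0.5)$root
  for (i in 1:5) {  # Newton polish; derivative = mean(p(1-p)) > 0
    p <- stats::plogis(c0 + linearPredictor)
    g <- mean(p) - targetPrevalence
    if (abs(g) <= 1e-13) break
    c0 <- c0 - g / mean(p * (1 - p))
  }
  c0
}

# Place the true-positive metabolites. "spread" puts them in distinct
# clusters (one random member per sampled cluster) so that
# correlation-induced false positives can be attributed per cluster;
# "same_cluster" concentrates them in one sufficiently large cluster.
.placeTruth <- function(spec, nTrue, placement) {
  M <- spec@nMetabolites
  C <- spec@nClusters
  cl <- .clusterIndex(M, C)
  if (placement == "spread") {
    cluster <- rep(seq_len(C), length.out = nTrue)
    if (nTrue <= C) cluster <- sample(C, nTrue)
    idx <- vapply(cluster, function(c) {
      members <- which(cl == c)
      members[sample.int(length(members), 1L)]
    }, integer(1))
    while (anyDuplicated(idx)) {  # only possible when nTrue > C
      dup <- which(duplicated(idx))
      for (d in dup) {
        members <- setdiff(which(cl == cl[idx[d]]), idx)
        if (length(members)) idx[d] <- members[sample.int(length(members), 1L)]
      }
    }
  } else {
    big <- which(tabulate(cl, C) >= nTrue)
    if (!length(big))
      stop("no cluster is large enough to hold all ", nTrue,
           " true metabolites")
    members <- which(cl == big[1])
    idx <- sort(sample(members, nTrue))
  }
  sort(idx)
}

#' Simulate one metabolomics study
#'
#' Draws metabolite levels from a multivariate normal distribution with mean
#' zero and the correlation matrix implied by the scenario's
#' [CorrelationSpec-class], plants `nTrue` nonzero effects (assigned in
#' order of increasing metabolite index), and generates the outcome:
#' continuous as `X %*% beta + rnorm(N, 0, noiseSd)`, binary from a logistic
#' model on `X %*% beta` with the intercept calibrated (see
#' [calibrateBinaryIntercept()]) so that the expected prevalence equals the
#' configured value. With `caseControl = TRUE` the binary study is
#' subsampled to an exact 1:1 case/control ratio.
#'
#' Generation is fully reproducible: the same config (including its seed)
#' returns bit-identical data.
#'
#' @param config a [ScenarioConfig-class].
#' @return a [SimulatedDataset-class].
#' @examples
#' ds <- simulateDataset(ScenarioConfig(100, nMetabolites = 50, seed = 3))
#' dim(metabMatrix(ds))
#' truthSet(ds)
#' @export
simulateDataset <- function(config) {
  validObject(config)
  .withSeed(config@seed, {
    spec <- config@correlation
    M <- spec@nMetabolites
    N <- config@nSubjects
    R <- buildCorrelationMatrix(spec)
    S <- .matrixSqrt(R)
    X <- matrix(stats::rnorm(N * M), N, M) %*% S

    truth <- .placeTruth(spec, config@nTrue, config@truthPlacement)
    beta <- numeric(M)
    beta[truth] <- config@effectSizes

    lp <- drop(X %*% beta)
    intercept <- NA_real_
    if (config@outcomeType == "continuous") {
      y <- lp + stats::rnorm(N, 0, config@noiseSd)
    } else {
      intercept <- calibrateBinaryIntercept(lp, config@prevalence)
      y <- stats::rbinom(N, 1L, stats::plogis(intercept + lp))
      if (config@caseControl) {
        cases <- which(y == 1); controls <- which(y == 0)
        k <- min(length(cases), length(controls))
        if (k < 1L) stop("degenerate binary outcome: a class is empty")
        keep <- sort(c(sample(cases, k), sample(controls, k)))
        X <- X[keep, , drop = FALSE]
        y <- y[keep]
        N <- length(keep)
      }
    }

    metIds <- sprintf("met_%04d", seq_len(M))
    dimnames(X) <- list(sprintf("S%05d", seq_len(N)), metIds)
    se <- SummarizedExperiment(
      assays = list(levels = t(X)),
      rowData = DataFrame(beta = beta, isTrue = beta != 0,
                          cluster = .clusterIndex(M, spec@nClusters),
                          row.names = metIds),
      colData = DataFrame(outcome = y, row.names = rownames(X)))
    metadata(se)$intercept <- intercept
    new("SimulatedDataset", se, config = config)
  })
}
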