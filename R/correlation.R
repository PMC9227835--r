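## Correlation-matrix construction: block compound symmetry + jitter + PSD repair.

# Evaluate expr with a temporary RNG state; restores the caller's stream.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

# Near-equal contiguous cluster sizes.
.clusterSizes <- function(M, C) {
  base <- M %/% C
  sizes <- rep(base, C)
  extra <- M - base * C
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

# Cluster index (1..C) of each metabolite.
.clusterIndex <- function(M, C) {
  rep(seq_len(C), times = .clusterSizes(M, C))
}

# Solve the cross-cluster correlation so the off-diagonal mean hits target.
.solveBetweenRho <- function(spec) {
  M <- spec@nMetabolites
  sizes <- .clusterSizes(M, spec@nClusters)
  nWithin <- sum(sizes * (sizes - 1))
  nTotal <- M * (M - 1)
  nCross <- nTotal - nWithin
  if (nCross == 0) {
    if (abs(spec@withinClusterRho - spec@targetMeanRho) > 1e-12)
      stop("infeasible correlation spec: a single cluster fixes the ",
           "off-diagonal mean at within_cluster_rho = ",
           spec@withinClusterRho, ", which differs from target_mean_rho = ",
           spec@targetMeanRho)
    return(0)
  }
  b <- (spec@targetMeanRho * nTotal - nWithin * spec@withinClusterRho) / nCross
  if (b <= -1 || b >= 1)
    stop("infeasible correlation spec: reaching target_mean_rho = ",
         spec@targetMeanRho, " with within_cluster_rho = ",
         spec@withinClusterRho, " requires between_cluster_rho = ",
         format(b, digits = 4), ", outside (-1, 1)")
  b
}

# Nearest-PSD repair: clip negative eigenvalues at 0, renormalize diagonal.
.nearestPSD <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= 0) return(R)
  v <- pmax(e$values, 0)
  R2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(pmax(diag(R2), .Machine$double.eps))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  (R2 + t(R2)) / 2
}

#' Build the population correlation matrix for simulated metabolite levels
#'
#' Constructs a symmetric, unit-diagonal, positive semi-definite M-by-M
#' correlation matrix with block (cluster) structure: within-cluster entries
#' centre on `withinClusterRho`, cross-cluster entries on
#' `betweenClusterRho` (solved from `targetMeanRho` when `NA`), with
#' independent Gaussian jitter of sd `jitterSd` added to every off-diagonal
#' entry so that pairwise correlations are randomly distributed around their
#' block means. Jitter can break positive semi-definiteness, so the matrix is
#' repaired by eigenvalue clipping at zero followed by re-normalization to a
#' unit diagonal.
#'
#' Optional features for secondary simulation designs: a fraction of
#' cross-cluster blocks can be given negative correlation
#' (`negativeBlockFraction`), and one adjacent metabolite pair per cluster
#' can be planted at a high correlation (`pairedHighRho`), emulating pairs of
#' highly intercorrelated metabolites from a shared pathway.
#'
#' @param spec a [CorrelationSpec-class].
#' @param seed optional integer seed for the jitter and block-sign draws;
#'   when `NULL` the current RNG stream is used.
#' @return M-by-M correlation matrix.
#' @examples
#' R <- buildCorrelationMatrix(CorrelationSpec(200), seed = 1)
#' mean(R[upper.tri(R)])  # close to +0.40
#' min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)  # >= 0
#' @export
buildCorrelationMatrix <- function(spec, seed = NULL) {
  validObject(spec)
  .withSeed(seed, {
    M <- spec@nMetabolites
    C <- spec@nClusters
    cl <- .clusterIndex(M, C)
    w <- spec@withinClusterRho
    solved <- is.na(spec@betweenClusterRho)
    b <- if (solved) .solveBetweenRho(spec) else spec@betweenClusterRho
    same <- outer(cl, cl, "==")

    # Fixed random ingredients, drawn once so the calibration loop below
    # reassembles the same matrix.
    signM <- matrix(1, M, M)
    if (spec@negativeBlockFraction > 0 && C > 1) {
      pairs <- utils::combn(C, 2)
      nFlip <- round(spec@negativeBlockFraction * ncol(pairs))
      if (nFlip > 0) {
        flip <- sample(ncol(pairs), nFlip)
        for (i in flip) {
          a <- cl == pairs[1, i]; d <- cl == pairs[2, i]
          signM[a, d] <- -1; signM[d, a] <- -1
        }
      }
    }
    J <- matrix(0, M, M)
    if (spec@jitterSd > 0) {
      ut <- upper.tri(J)
      J[ut] <- stats::rnorm(sum(ut), 0, spec@jitterSd)
      J <- J + t(J)
    }

    assemble <- function(bval) {
      R <- matrix(bval, M, M)
      R[same] <- w
      R <- R * signM
      if (!is.na(spec@pairedHighRho)) {
        first <- cumsum(c(1L, .clusterSizes(M, C)))[seq_len(C)]
        for (f in first[first + 1 <= M]) {
          if (cl[f] == cl[f + 1]) {
            R[f, f + 1] <- spec@pairedHighRho
            R[f + 1, f] <- spec@pairedHighRho
          }
        }
      }
      R <- R + J
      R[R > 0.99] <- 0.99
      R[R < -0.99] <- -0.99
      diag(R) <- 1
      .nearestPSD(R)
    }

    R <- assemble(b)
    if (solved) {
      # The nearest-PSD repair renormalizes the diagonal and thereby
      # shrinks off-diagonal entries, pulling the realized mean below the
      # solved target. Correct by a fixed-point adjustment of the
      # cross-cluster level, with the jitter held fixed.
      off <- !diag(TRUE, M)
      nCross <- sum(!same & off)
      if (nCross > 0) {
        for (it in 1:8) {
          gap <- spec@targetMeanRho - mean(R[off])
          if (abs(gap) < 0.003) break
          b <- b + gap * sum(off) / nCross
          if (b <= -1 || b >= 1)
            stop("infeasible correlation spec: cannot reach ",
                 "target_mean_rho = ", spec@targetMeanRho,
                 " after positive semi-definite repair")
          R <- assemble(b)
        }
      }
    }
    R
  })
}

# Symmetric square root of a PSD correlation matrix (for MVN sampling even
# when eigenvalue clipping has left the matrix singular).
.matrixSqrt <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}
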