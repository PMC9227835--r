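test_that("preprocessing produces exact zero means and unit sds", {
  ft <- generateCohortTable(120, 20, seed = 1)
  Z <- preprocessTable(ft)
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-10)
})

test_that("scaling a raw column leaves its standardized values unchanged", {
  ft <- generateCohortTable(50, 5, seed = 2)
  Z1 <- preprocessTable(ft)
  X <- intensityMatrix(ft)
  X[, 3] <- X[, 3] * 10
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = t(X)),
    colData = SummarizedExperiment::colData(ft))
  Z2 <- preprocessTable(new("FeatureTable", se))
  expect_equal(Z2[, 3], Z1[, 3], tolerance = 1e-12)
})

test_that("preprocessing errors name the offending sample and metabolite", {
  ft <- generateCohortTable(20, 4, seed = 3)
  # a nonpositive intensity is rejected (by class validity at
  # construction, and by the named preprocessing error if one slips
  # past into an already-built object)
  err <- tryCatch({
    bad <- ft
    SummarizedExperiment::assay(bad, "intensity",
                                withDimnames = FALSE)["met_0002",
                                                      "S00005"] <- -1
    preprocessTable(bad)
    "no error raised"
  }, error = conditionMessage)
  expect_match(err, "S00005|positive")
  expect_match(err, "met_0002|positive")
  # constant column cannot be standardized
  cst <- intensityMatrix(ft)
  cst[, 1] <- 5
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = t(cst)),
    colData = SummarizedExperiment::colData(ft))
  expect_error(preprocessTable(new("FeatureTable", se)), "zero variance")
})

test_that("cohort methods recover a strongly planted age set", {
  ft <- generateCohortTable(400, 40, plantedAgeSet = 1:5, seed = 4,
                            ageEffect = 0.8)
  Z <- preprocessTable(ft)
  cd <- covariateData(ft)
  res <- runCohortMethods(Z, cd$age, "continuous", batch = cd$batch,
                          etaGrid = c(0.5, 0.9), KGrid = 1:2, foldSeed = 1)
  expect_named(res, c("bonferroni", "fdr", "lasso", "spls"))
  expect_true(all(1:5 %in% selectedSet(res$fdr)))
  expect_true(all(selectedSet(res$bonferroni) %in% selectedSet(res$fdr)))
})

test_that("binary outcome (sex) routes to splsda and logistic lasso", {
  ft <- generateCohortTable(300, 30, plantedSexSet = 1:3, seed = 5,
                            sexEffect = 1.2)
  Z <- preprocessTable(ft)
  cd <- covariateData(ft)
  res <- runCohortMethods(Z, cd$sex, "binary", batch = cd$batch,
                          etaGrid = c(0.5, 0.9), KGrid = 1:2, foldSeed = 1)
  expect_true("splsda" %in% names(res))
  expect_true(all(1:3 %in% selectedSet(res$fdr)))
})

test_that("permuted outcome selects almost nothing by FDR", {
  ft <- generateCohortTable(200, 100, seed = 6)
  Z <- preprocessTable(ft)
  cd <- covariateData(ft)
  set.seed(1)
  sizes <- vapply(1:5, function(i) {
    yp <- sample(cd$age)
    scan <- suppressWarnings(univariateScan(Z, yp, "continuous"))
    length(bhSelect(scan$pvalues, 0.1))
  }, numeric(1))
  expect_lte(mean(sizes), 0.05 * 100)
})

test_that("vennCounts enumerates the seven regions", {
  v <- vennCounts(list(A = c(1, 2), B = c(2, 3), C = 2))
  expect_equal(unname(v), c(1, 1, 0, 0, 0, 0, 1))
  expect_identical(names(v), c("A_only", "B_only", "C_only", "A_B", "A_C",
                               "B_C", "A_B_C"))
  # disjoint
  v2 <- vennCounts(list(x = 1, y = 2, z = 3))
  expect_equal(unname(v2), c(1, 1, 1, 0, 0, 0, 0))
  # identical
  v3 <- vennCounts(list(x = 1:4, y = 1:4, z = 1:4))
  expect_equal(unname(v3), c(0, 0, 0, 0, 0, 0, 4))
  expect_equal(sum(v3), 4)
  expect_error(vennCounts(list(1:2, 1:3)), "three named sets")
})

test_that("spearman network keeps signed rho above the threshold", {
  set.seed(7)
  N <- 100
  base <- rnorm(N)
  Z <- cbind(a = base + rnorm(N, 0, 0.1), b = base + rnorm(N, 0, 0.1),
             c = rnorm(N), d = -base + rnorm(N, 0, 0.1))
  net <- spearmanNetwork(Z, threshold = 0.75)
  e <- net@edges
  expect_equal(nrow(e), 1L)  # only (a, b); (a, d) is strongly negative
  expect_setequal(c(e$from, e$to), c("a", "b"))
  expect_gt(e$rho, 0.75)
})

test_that("duplicated column yields an edge with rho = 1", {
  set.seed(8)
  x <- rnorm(50)
  Z <- cbind(m1 = x, m2 = x, m3 = rnorm(50))
  net <- spearmanNetwork(Z, threshold = 0.75)
  expect_equal(net@edges$rho[net@edges$from == "m1" &
                             net@edges$to == "m2"], 1)
})

test_that("spearman network is invariant to monotone transforms", {
  set.seed(9)
  Z <- matrix(rnorm(60 * 4), 60, 4) + rnorm(60)
  colnames(Z) <- paste0("m", 1:4)
  n1 <- spearmanNetwork(Z, 0.5)
  Z2 <- Z
  Z2[, 1] <- exp(Z2[, 1])
  n2 <- spearmanNetwork(Z2, 0.5)
  expect_equal(n1@edges, n2@edges)
})

test_that("independent columns at N=1000 give an empty network", {
  set.seed(10)
  Z <- matrix(rnorm(1000 * 10), 1000, 10)
  net <- spearmanNetwork(Z, 0.75)
  expect_equal(nrow(net@edges), 0L)
})

test_that("network input validation", {
  expect_error(spearmanNetwork(matrix(rnorm(4), 2, 2)), "3 samples")
  expect_error(spearmanNetwork(matrix(rnorm(30), 10, 3), threshold = 1),
               "threshold")
})

test_that("annotations derive from MethodOutput selections", {
  set.seed(11)
  Z <- matrix(rnorm(50 * 4), 50, 4)
  colnames(Z) <- paste0("met_", 1:4)
  ann <- list(
    fdr = MethodOutput("fdr", scores = c(1, 1, 0, 0), selected = 1:2,
                       pvalues = c(0.001, 0.002, 0.5, 0.9)),
    lasso = MethodOutput("lasso", scores = c(0.5, 0, 0, 0), selected = 1L))
  net <- spearmanNetwork(Z, 0.5, annotations = ann)
  expect_setequal(net@nodeAnnotations[["met_1"]], c("fdr", "lasso"))
  expect_identical(net@nodeAnnotations[["met_2"]], "fdr")
})

test_that("network JSON and GraphML exports round-trip", {
  set.seed(12)
  base <- rnorm(80)
  Z <- cbind(m1 = base + rnorm(80, 0, 0.1), m2 = base + rnorm(80, 0, 0.1),
             m3 = rnorm(80))
  net <- spearmanNetwork(Z, 0.75,
                         annotations = list(m1 = c("fdr", "spls")))
  jp <- tempfile(fileext = ".json"); gp <- tempfile(fileext = ".graphml")
  on.exit(unlink(c(jp, gp)), add = TRUE)
  exportNetwork(net, jsonPath = jp, graphmlPath = gp)
  doc <- jsonlite::fromJSON(jp, simplifyVector = FALSE)
  expect_length(doc$nodes, 3L)
  expect_length(doc$links, nrow(net@edges))
  expect_setequal(unlist(doc$nodes[[1]]$methods), c("fdr", "spls"))
  g <- igraph::read_graph(gp, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(net@edges))
  expect_equal(sort(igraph::edge_attr(g, "rho")), sort(net@edges$rho),
               tolerance = 1e-9)
  expect_identical(igraph::vertex_attr(g, "methods",
    igraph::V(g)[igraph::V(g)$name == "m1"]), "fdr,spls")
})

test_that("empty network exports valid JSON with empty arrays", {
  set.seed(13)
  Z <- matrix(rnorm(300), 100, 3)
  colnames(Z) <- paste0("m", 1:3)
  net <- spearmanNetwork(Z, 0.9)
  jp <- tempfile(fileext = ".json")
  on.exit(unlink(jp), add = TRUE)
  exportNetwork(net, jsonPath = jp)
  doc <- jsonlite::fromJSON(jp, simplifyVector = FALSE)
  expect_length(doc$links, 0L)
  expect_length(doc$nodes, 3L)
})

test_that("FDR picks denser-correlated sets than SPLS on clustered tables", {
  # univariate selection drags in cluster-mates; SPLS stays sparser/broader
  for (s in 1:3) {
    ft <- generateCohortTable(300, 50, plantedAgeSet = c(1, 11, 21),
                              seed = s, ageEffect = 0.6,
                              biologicalSd = 0.8)
    Z <- preprocessTable(ft)
    cd <- covariateData(ft)
    res <- runCohortMethods(Z, cd$age, "continuous",
                            etaGrid = c(0.5, 0.8), KGrid = 1:2,
                            foldSeed = s)
    meanAbsRho <- function(sel) {
      if (length(sel) < 2) return(NA_real_)
      r <- cor(Z[, sel], method = "spearman")
      mean(abs(r[upper.tri(r)]))
    }
    fdrRho <- meanAbsRho(selectedSet(res$fdr))
    splsRho <- meanAbsRho(selectedSet(res$spls))
    if (!is.na(fdrRho) && !is.na(splsRho))
      expect_gte(fdrRho, splsRho - 0.15)
  }
})
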