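test_that("perfect linear dependence gives p ~ 0 and coefficient 1", {
  set.seed(1)
  X <- matrix(rnorm(300), 100, 3)
  y <- X[, 2]
  scan <- univariateScan(X, y, "continuous")
  expect_lt(scan$pvalues[2], 1e-12)
  expect_equal(scan$coefficients[2], 1, tolerance = 1e-10)
})

test_that("continuous scan matches lm() per column", {
  set.seed(2)
  X <- matrix(rnorm(50 * 4), 50, 4)
  y <- X[, 1] * 0.5 + rnorm(50)
  scan <- univariateScan(X, y, "continuous")
  for (j in 1:4) {
    fit <- summary(lm(y ~ X[, j]))$coefficients
    expect_equal(scan$coefficients[j], fit[2, 1], tolerance = 1e-10)
    expect_equal(scan$pvalues[j], fit[2, 4], tolerance = 1e-10)
  }
})

test_that("continuous scan with covariates matches lm()", {
  set.seed(3)
  X <- matrix(rnorm(60 * 3), 60, 3)
  b <- factor(sample(1:3, 60, replace = TRUE))
  y <- X[, 1] + as.integer(b) * 0.3 + rnorm(60)
  scan <- univariateScan(X, y, "continuous",
                         covariates = data.frame(batch = b))
  for (j in 1:3) {
    fit <- summary(lm(y ~ b + X[, j]))$coefficients
    expect_equal(scan$coefficients[j], fit["X[, j]", 1], tolerance = 1e-10)
    expect_equal(scan$pvalues[j], fit["X[, j]", 4], tolerance = 1e-10)
  }
})

test_that("logistic scan matches glm() per column", {
  set.seed(4)
  X <- matrix(rnorm(200 * 3), 200, 3)
  y <- rbinom(200, 1, plogis(X[, 2]))
  scan <- univariateScan(X, y, "binary")
  for (j in 1:3) {
    fit <- summary(glm(y ~ X[, j], family = binomial()))$coefficients
    expect_equal(scan$coefficients[j], fit[2, 1], tolerance = 1e-6)
    expect_equal(scan$pvalues[j], fit[2, 4], tolerance = 1e-6)
  }
})

test_that("null p-values are approximately uniform", {
  set.seed(5)
  p <- replicate(1000, {
    x <- rnorm(60); y <- rnorm(60)
    univariateScan(matrix(x), y, "continuous")$pvalues
  })
  expect_lt(ksDistanceUniform(p), 0.06)
})

test_that("an orthogonal batch covariate barely moves p-values", {
  set.seed(6)
  N <- 200
  X <- matrix(rnorm(N * 5), N, 5)
  # moderate signal keeps p-values away from the underflow regime where
  # relative comparisons are meaningless
  y <- X[, 1] * 0.2 + rnorm(N)
  # covariate orthogonalized against X and y
  raw <- rnorm(N)
  covar <- residuals(lm(raw ~ X + y))
  p0 <- univariateScan(X, y, "continuous")$pvalues
  p1 <- univariateScan(X, y, "continuous",
                       covariates = data.frame(c1 = covar))$pvalues
  expect_true(all(abs(p1 - p0) / pmax(p0, 1e-300) < 0.1))
})

test_that("constant metabolite column yields p = 1", {
  set.seed(7)
  X <- cbind(rep(1, 50), rnorm(50))
  y <- rnorm(50)
  scan <- univariateScan(X, y, "continuous")
  expect_equal(scan$pvalues[1], 1)
  expect_equal(scan$coefficients[1], 0)
  yb <- rbinom(50, 1, 0.5)
  scanB <- univariateScan(X, yb, "binary")
  expect_equal(scanB$pvalues[1], 1)
})

test_that("perfect separation in logistic scan gives p = 1 with warning", {
  x <- c(rnorm(25, -3), rnorm(25, 3))
  y <- rep(c(0, 1), each = 25)
  expect_warning(scan <- univariateScan(matrix(x), y, "binary"),
                 "separation")
  expect_equal(scan$pvalues[1], 1)
})

test_that("linear-probability scan option works for binary outcomes", {
  set.seed(8)
  X <- matrix(rnorm(300), 100, 3)
  y <- rbinom(100, 1, plogis(2 * X[, 1]))
  scan <- univariateScan(X, y, "binary", binaryModel = "linear")
  fit <- summary(lm(y ~ X[, 1]))$coefficients
  expect_equal(scan$pvalues[1], fit[2, 4], tolerance = 1e-10)
})

test_that("bonferroniSelect applies the alpha/M threshold", {
  p <- c(1e-4, 0.01, rep(0.5, 198))
  expect_identical(bonferroniSelect(p, 0.05), 1L)
  expect_identical(bonferroniSelect(rep(1, 10)), integer(0))
  expect_error(bonferroniSelect(c(-0.1, 0.5)))
})

test_that("bhSelect equals the literal step-up rule", {
  expect_identical(bhSelect(c(0.001, 0.010, 0.020, 0.900), 0.1), 1:3)
  expect_identical(bhSelect(0.05, 0.1), 1L)
  expect_identical(bhSelect(rep(1, 20), 0.1), integer(0))
  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(5:100, 1))^sample(1:3, 1)
    expect_identical(bhSelect(p, 0.1), stepUpBH(p, 0.1))
  }
})

test_that("bonferroni set is a subset of the BH set at the same level", {
  set.seed(10)
  for (i in 1:100) {
    p <- runif(200)^3
    expect_true(all(bonferroniSelect(p, 0.05) %in% bhSelect(p, 0.05)))
  }
})
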