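test_that("autoscaling centres and unit-variance scales, and freezes params", {
  x <- cbind(a = c(1, 2, 3), b = c(2, 2, 5))
  sc <- autoscale(x)
  expect_equal(sc$x[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(colMeans(sc$x), c(a = 0, b = 0))
  expect_equal(apply(sc$x, 2, sd), c(a = 1, b = 1))
  # hand-computed z-scores for the 3x2 matrix
  expect_equal(sc$x[, "b"], (c(2, 2, 5) - 3) / sd(c(2, 2, 5)),
               ignore_attr = TRUE)
  # stored params applied to the training data reproduce fresh scaling
  again <- autoscale(x, params = sc)
  expect_equal(again$x, sc$x)
  # projection of new data uses the *training* parameters
  xnew <- cbind(a = 4, b = 3)  # a: (4 - 2) / 1 = 2 under training params
  expect_equal(autoscale(xnew, params = sc)$x[, "a"], 2, ignore_attr = TRUE)
})

test_that("zero-variance columns error by name, or drop with a warning", {
  x <- cbind(a = c(1, 2, 3), flat = c(7, 7, 7))
  expect_error(autoscale(x), "flat")
  expect_warning(sc <- autoscale(x, dropConstant = TRUE), "flat")
  expect_equal(colnames(sc$x), "a")
})

test_that("within-subject decomposition gives +/- half the paired difference", {
  x <- rbind(c(2, 4), c(4, 8))  # rest then post for one subject
  dec <- withinSubjectDecompose(x, c("s1", "s1"))
  expect_equal(dec$within, rbind(c(-1, -2), c(1, 2)), ignore_attr = TRUE)
  # rest == post -> within all zero
  x2 <- rbind(c(3, 5), c(3, 5), c(1, 9), c(1, 9))
  dec2 <- withinSubjectDecompose(x2, c("a", "a", "b", "b"))
  expect_equal(dec2$within, matrix(0, 4, 2), ignore_attr = TRUE)
  expect_error(withinSubjectDecompose(x2[1:3, ], c("a", "a", "b")),
               "unpaired.*b")
})

test_that("between + within + grand reconstructs any paired matrix exactly", {
  set.seed(9)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    x <- matrix(rnorm(2 * n * 4), 2 * n, 4)
    subj <- rep(paste0("s", seq_len(n)), each = 2)
    dec <- withinSubjectDecompose(x, subj)
    rec <- dec$within + dec$between +
      matrix(dec$grand, 2 * n, 4, byrow = TRUE)
    expect_equal(rec, x, tolerance = 1e-12)
  }
})

test_that("PCA explained fractions follow the variance structure", {
  # rank-1 matrix
  x1 <- outer(c(1, 2, 3, 4), c(1, -1))
  p1 <- fitPCA(x1, 1)
  expect_equal(p1@explainedVariance, 1)
  # two orthogonal directions with variances 4 and 1
  set.seed(2)
  a <- scale(rnorm(400), TRUE, TRUE) * 2
  b <- scale(rnorm(400), TRUE, TRUE)
  b <- scale(resid(lm(b ~ a)), FALSE, FALSE)
  b <- b / sd(b)
  x2 <- cbind(a, b)
  p2 <- fitPCA(x2, 2)
  expect_equal(p2@explainedVariance, c(0.8, 0.2), tolerance = 1e-8)
})

test_that("PCA agrees with a brute-force eigendecomposition", {
  set.seed(7)
  x <- matrix(rnorm(24), 6, 4)
  p <- fitPCA(x, 3)
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(cov(xc))
  expect_equal(p@explainedVariance, (ev$values / sum(ev$values))[1:3],
               tolerance = 1e-10)
  for (k in 1:3)  # loadings match up to sign
    expect_equal(abs(sum(p@loadings[, k] * ev$vectors[, k])), 1,
                 tolerance = 1e-8)
  expect_error(fitPCA(x, 6), "nComponents")
})

test_that("robust PC1 outliers flag the whole subject", {
  set.seed(5)
  x <- matrix(rnorm(40), 20, 2)
  subj <- rep(paste0("s", 1:10), each = 2)
  x[3, 1] <- x[3, 1] + 40  # one sample of subject s2 far out on PC1
  pca <- fitPCA(x, 2)
  expect_equal(flagOutliers(pca, subj), "s2")
  # all-equal scores flag nothing
  pcaFlat <- methods::new("PcaResult", scores = matrix(1, 10, 1),
                          loadings = matrix(1, 1, 1), explainedVariance = 1)
  expect_length(flagOutliers(pcaFlat, paste0("s", 1:10)), 0)
})

test_that("removing a flagged subject drops both of its samples", {
  sim <- tinyPairedDataset(5, c("Ala", "Gly", "Ser"))
  ds <- removeSubjects(sim$dataset, "S02")
  expect_equal(ncol(ds), 8L)
  expect_false("S02" %in% subjectIds(ds))
  expect_true(methods::validObject(ds))
})

test_that("NIPALS PLS-DA matches an independent minimal implementation", {
  set.seed(42)
  X <- matrix(rnorm(18), 6, 3)
  y <- c(0, 1, 0, 1, 0, 1)
  m <- fitPLSDA(X, y, nComponents = 2)
  o <- naiveNipals(X, y, 2)
  expect_equal(m@weights, o$W, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(m@scores, o$T, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(m@xLoadings, o$P, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(m@yLoadings, o$q, tolerance = 1e-10)
})

test_that("PLS score vectors are orthogonal and separate ordered classes", {
  set.seed(8)
  X <- matrix(rnorm(80), 20, 4)
  y <- rep(c(0, 1), 10)
  m <- fitPLSDA(X, y, nComponents = 2)
  expect_lt(abs(sum(m@scores[, 1] * m@scores[, 2])), 1e-8)
  # 1-D X perfectly ordered by class -> training AUROC 1
  x1 <- matrix(c(1, 2, 3, 11, 12, 13), ncol = 1)
  y1 <- c(0, 0, 0, 1, 1, 1)
  m1 <- fitPLSDA(x1, y1, nComponents = 1)
  pr <- predictScores(m1, x1)
  expect_equal(computeAUROC(pr$predicted, y1), 1)
})

test_that("component-1 weights agree with mixOmics up to sign", {
  skip_if_not_installed("mixOmics")
  set.seed(12)
  X <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, paste0("v", 1:6)))
  y <- rep(c(0, 1), 5)
  m <- fitPLSDA(X, y, nComponents = 2)
  mo <- mixOmics::plsda(X, factor(y), ncomp = 2, scale = TRUE)
  w1 <- mo$loadings$X[, 1]
  a <- m@weights[, 1] / sqrt(sum(m@weights[, 1]^2))
  b <- w1 / sqrt(sum(w1^2))
  expect_equal(abs(sum(a * b)), 1, tolerance = 1e-6)
})

test_that("prediction projects with frozen training parameters", {
  set.seed(4)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- rep(c(0, 1), 5)
  m <- fitPLSDA(X, y, nComponents = 2)
  pr <- predictScores(m, X)
  expect_equal(pr$scores, m@scores, ignore_attr = TRUE, tolerance = 1e-12)
  # a row at the training centre predicts the class prior
  centre <- matrix(m@center, 1, dimnames = list(NULL, paste0("v", 1:4)))
  expect_equal(predictScores(m, centre)$predicted, m@yMean)
  # hand projection on a 1-component model
  m1 <- fitPLSDA(X, y, nComponents = 1)
  xnew <- X[3, , drop = FALSE]
  z <- (xnew - m1@center) / m1@scale
  expect_equal(predictScores(m1, xnew)$predicted,
               m1@yMean + sum(z * m1@weights[, 1]) * m1@yLoadings[1])
  expect_error(predictScores(m, X[, 1:2, drop = FALSE]), "mismatch")
})

test_that("VIP is normalised and ranks an informative variable first", {
  # single-variable model -> VIP exactly 1
  x1 <- matrix(c(1, 2, 3, 11, 12, 13), ncol = 1,
               dimnames = list(NULL, "only"))
  expect_equal(unname(computeVIP(fitPLSDA(x1, c(0, 0, 0, 1, 1, 1), 1))), 1)
  # sum of squared VIPs equals p for random models
  set.seed(21)
  for (rep in 1:3) {
    X <- matrix(rnorm(200), 20, 10)
    m <- fitPLSDA(X, rep(c(0, 1), 10), nComponents = 2)
    expect_equal(sum(computeVIP(m)^2), 10, tolerance = 1e-8)
  }
  # one informative variable among 9 noise variables
  set.seed(33)
  y <- rep(c(0, 1), 20)
  X <- matrix(rnorm(400), 40, 10,
              dimnames = list(NULL, paste0("v", 1:10)))
  X[, 1] <- X[, 1] + 2 * y
  vip <- computeVIP(fitPLSDA(X, y, nComponents = 2))
  expect_equal(names(which.max(vip)), "v1")
  expect_gt(vip["v1"], 1)
})
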