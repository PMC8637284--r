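test_that("combination counts are exact", {
  expect_equal(countCombinations(30, 20), 30045015)
  expect_equal(countCombinations(4, 2), 6)
  expect_equal(countCombinations(7, 0), 1)
  expect_equal(countCombinations(0, 0), 1)
  expect_error(countCombinations(4, 5), "k must")
  for (n in 1:12) for (k in 0:n)
    expect_equal(countCombinations(n, k), length(lexCombinations(n, k)))
})

test_that("unranking reproduces the lexicographic enumeration", {
  expect_equal(unrankCombination(1, 4, 2), c(1L, 2L))
  expect_equal(unrankCombination(6, 4, 2), c(3L, 4L))
  expect_equal(unrankCombination(3, 4, 2), c(1L, 4L))
  expect_error(unrankCombination(7, 4, 2), "out of range")
  expect_error(unrankCombination(0, 4, 2), "out of range")
  for (n in c(5, 6, 8)) for (k in c(1, 3, n - 1)) {
    all <- lexCombinations(n, k)
    for (i in seq_along(all))
      expect_equal(unrankCombination(i, n, k), as.integer(all[[i]]))
  }
})

test_that("stride sampling yields the documented index counts", {
  expect_length(strideIndices(30045015, 1287), 23345)
  expect_equal(strideIndices(6, 2), c(1, 3, 5))
  expect_equal(strideIndices(5, 10), 1)
  set.seed(14)
  for (rep in 1:20) {
    total <- sample(1:5000, 1); stride <- sample(1:300, 1)
    expect_length(strideIndices(total, stride),
                  floor((total - 1) / stride) + 1)
  }
})

test_that("AUROC matches exhaustive pair counting and is label-symmetric", {
  expect_equal(computeAUROC(c(1, 2, 10, 11), c(0, 0, 1, 1)), 1)
  s <- c(1, 2, 3, 2, 3, 4); l <- c(0, 0, 0, 1, 1, 1)
  expect_equal(computeAUROC(s, l), pairCountAuroc(s, l))
  expect_equal(computeAUROC(s, 1 - l), 1 - computeAUROC(s, l))
  set.seed(6)
  for (rep in 1:10) {
    sc <- sample(1:5, 12, replace = TRUE)  # heavy ties
    lb <- rep(c(0, 1), 6)
    expect_equal(computeAUROC(sc, lb), pairCountAuroc(sc, lb))
  }
  expect_error(computeAUROC(1:4, rep(1, 4)), "both classes")
})

test_that("Mann-Whitney p is exact for complete separation and rank-invariant", {
  p <- aurocPvalue(c(1, 2, 3, 4, 5, 11, 12, 13, 14, 15),
                   c(rep(0, 5), rep(1, 5)))
  expect_equal(p, 2 / choose(10, 5), tolerance = 1e-12)
  set.seed(10)
  s <- rnorm(20); l <- rep(c(0, 1), 10)
  expect_equal(aurocPvalue(exp(s), l), aurocPvalue(s, l), tolerance = 1e-12)
  expect_error(aurocPvalue(1:4, rep(0, 4)), "both classes")
})

test_that("Mann-Whitney p-values are approximately uniform under the null", {
  set.seed(17)
  ps <- replicate(400, aurocPvalue(rnorm(20), rep(c(0, 1), 10)))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("split schemes allocate subjects, never single samples", {
  subj <- sprintf("S%02d", 1:15)
  sch <- makeSplitScheme(subj, testSize = 3, trainSize = 8, stride = 5,
                         seed = 2)
  expect_length(sch@testSubjects, 3)
  expect_length(sch@poolSubjects, 12)
  expect_length(intersect(sch@testSubjects, sch@poolSubjects), 0)
  sp <- exermet:::.modelSplit(sch, 4)
  expect_length(sp$train, 8)
  expect_length(sp$validation, 4)
  expect_setequal(c(sp$train, sp$validation), sch@poolSubjects)
  # same seed -> same scheme
  sch2 <- makeSplitScheme(subj, testSize = 3, trainSize = 8, stride = 5,
                          seed = 2)
  expect_identical(sch@testSubjects, sch2@testSubjects)
})

test_that("best-model selection filters by cutoff with a top-decile fallback", {
  evals <- data.frame(combination = 1:3, auroc = c(0.90, 0.95, 0.99),
                      p = c(0.1, 0.01, 0.001))
  expect_length(selectBestModels(evals, 0), 3)
  expect_equal(selectBestModels(evals, 0.95), c(2L, 3L))
  expect_warning(idx <- selectBestModels(evals, 1), "top decile")
  expect_equal(idx, 3L)
  expect_warning(none <- selectBestModels(evals, 1, fallbackTopDecile = FALSE),
                 "cutoff")
  expect_length(none, 0)
})

test_that("a strong paired effect passes the gate with high AUROC medians", {
  analytes <- c("Ala", "Gln", "Ser", "C2", "C12", "Gly", "His", "Met")
  eff <- stats::setNames(c(0.9, 0.9, -0.9, 0.9), c("Ala", "Gln", "Ser", "C2"))
  sim <- tinyPairedDataset(15, analytes, effects = eff, seed = 19)
  sch <- makeSplitScheme(unique(subjectIds(sim$dataset)), testSize = 3,
                         trainSize = 8, stride = 1, seed = 20)
  ens <- runEnsemble(sim$dataset, sch)
  expect_true(ens@gatePassed)
  expect_gte(ens@medianValidationAuroc, 0.9)
  expect_gte(ens@medianTestAuroc, 0.9)
  # volcano covers every metabolite, flags VIP >= 1, signs the direction
  v <- buildVolcanoTable(ens)
  expect_setequal(v$metabolite, analytes)
  expect_equal(v$discriminant, v$median_vip >= 1)
  expect_equal(v$median_loading["Ser" == v$metabolite] < 0, TRUE)
  expect_lt(ens@loadingMedian[["Ser"]], 0)
  expect_gt(ens@loadingMedian[["Ala"]], 0)
})

test_that("ensembles are deterministic under a fixed scheme", {
  sim <- tinyPairedDataset(10, c("Ala", "Gly", "Ser", "His"),
                           effects = c(Ala = 1), seed = 3)
  sch <- makeSplitScheme(unique(subjectIds(sim$dataset)), testSize = 2,
                         trainSize = 5, stride = 2, seed = 4)
  e1 <- suppressWarnings(runEnsemble(sim$dataset, sch))
  e2 <- suppressWarnings(runEnsemble(sim$dataset, sch))
  expect_identical(e1@evaluations, e2@evaluations)
  expect_identical(e1@vipMedian, e2@vipMedian)
})

test_that("a null cohort fails the gate and suppresses discriminant selection", {
  sim <- tinyPairedDataset(12, c("Ala", "Gly", "Ser", "His", "Met", "C2"),
                           seed = 23)
  sch <- makeSplitScheme(unique(subjectIds(sim$dataset)), testSize = 2,
                         trainSize = 6, stride = 1, seed = 24)
  expect_warning(ens <- runEnsemble(sim$dataset, sch), "gate")
  expect_false(ens@gatePassed)
  expect_length(ens@bestIndices, 0)
  expect_error(buildVolcanoTable(ens), "gate")
})
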