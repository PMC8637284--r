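flatRecording <- function(values, status = NULL) {
  t <- seq(0, 1020)
  P <- sapply(values, function(v) rep(v, length(t)))
  TcPO2Recording(t, P, c(rest_start = 0, exercise_start = 120,
                         exercise_end = 420, recovery_end = 1020),
                 probeStatus = status)
}

test_that("reference probe defaults to chest left and falls back to chest right", {
  rec <- flatRecording(c(chest_left = 65, chest_right = 64, calf_left = 60))
  expect_equal(selectReferenceProbe(rec), "chest_left")
  st <- c(chest_left = FALSE, chest_right = TRUE, calf_left = TRUE)
  rec2 <- flatRecording(c(chest_left = 65, chest_right = 64, calf_left = 60),
                        status = st)
  expect_equal(selectReferenceProbe(rec2), "chest_right")
  st2 <- c(chest_left = FALSE, chest_right = FALSE, calf_left = TRUE)
  rec3 <- flatRecording(c(chest_left = 65, chest_right = 64, calf_left = 60),
                        status = st2)
  expect_error(selectReferenceProbe(rec3), "reference")
})

test_that("DROP is the limb change minus the reference change", {
  restIdx <- 1:100
  limb <- rep(60, 200); ref <- rep(65, 200)
  expect_equal(computeDropSeries(limb, ref, restIdx), rep(0, 200))
  # limb falls 20 from rest, chest falls 5 -> DROP -15
  limb2 <- c(rep(60, 100), rep(40, 100))
  ref2 <- c(rep(65, 100), rep(60, 100))
  expect_equal(computeDropSeries(limb2, ref2, restIdx)[150], -15)
  # limb unchanged, chest rises 5 -> DROP -5
  ref3 <- c(rep(65, 100), rep(70, 100))
  expect_equal(computeDropSeries(limb, ref3, restIdx)[150], -5)
  expect_error(computeDropSeries(limb, ref[1:10], restIdx), "time base")
  expect_error(computeDropSeries(limb, ref, integer(0)), "rest window")
})

test_that("DROP invariances hold", {
  set.seed(3)
  ref <- 65 + stats::rnorm(300)
  restIdx <- 1:120
  expect_equal(computeDropSeries(ref, ref, restIdx), rep(0, 300))
  limb <- 60 + stats::rnorm(300)
  expect_equal(computeDropSeries(limb + 7, ref + 7, restIdx),
               computeDropSeries(limb, ref, restIdx))
})

test_that("minimal DROP is the window minimum", {
  expect_equal(minimalDrop(seq(0, -22, length.out = 50)), -22)
  v <- c(seq(0, -30, length.out = 30), seq(-30, -5, length.out = 30))
  expect_equal(minimalDrop(v), -30)
  expect_equal(minimalDrop(c(5, 2, 8)), 2)
  expect_error(minimalDrop(v, integer(0)), "empty")
})

test_that("ischemia and hypoxemia thresholds are strict", {
  expect_true(classifyLimbIschemia(-20))
  expect_false(classifyLimbIschemia(-15))
  expect_true(classifyLimbIschemia(-15 - 1e-9))
  expect_false(classifyLimbIschemia(0))
  restIdx <- 1:10
  mk <- function(drop) c(rep(65, 10), rep(65 - drop, 10))
  expect_true(detectExerciseHypoxemia(mk(6), restIdx, 11:20)$hypoxemia)
  expect_false(detectExerciseHypoxemia(mk(5), restIdx, 11:20)$hypoxemia)
  rises <- detectExerciseHypoxemia(c(rep(65, 10), rep(70, 10)), restIdx, 11:20)
  expect_true(rises$decrease <= 0)
  expect_false(rises$hypoxemia)
})

test_that("severity index sums limb DROP magnitudes, clipping positive minima", {
  expect_equal(severityIndex(rep(-20, 6)), 120)
  expect_equal(severityIndex(rep(0, 6)), 0)
  expect_equal(severityIndex(c(-30, -25, -20, -15, -10, -3)), 103)
  expect_equal(severityIndex(c(-30, -25, -20, -15, -10, +4)), 100)
  expect_error(severityIndex(c(-30, -25)), "six")
  expect_error(severityIndex(c(-30, -25, -20, -15, -10, NA)), "missing")
  expect_equal(as.numeric(severityIndex(c(-30, -25, NA, -15, -10, -3),
                                        allowPartial = TRUE)), 83)
})

test_that("severity index is monotone as any limb minimum deepens", {
  base <- c(-10, -20, -5, -15, -25, -8)
  s0 <- severityIndex(base)
  for (i in 1:6) {
    deeper <- base; deeper[i] <- deeper[i] - 7
    expect_gt(severityIndex(deeper), s0)
  }
})

test_that("treadmill distance integrates the speed ramp and caps at 15 min", {
  expect_equal(computeMWD(0), 0)
  expect_equal(computeMWD(60), 35)
  expect_equal(computeMWD(900), 35 + 840 * 3.2 / 3.6, tolerance = 1e-12)
  expect_equal(computeMWD(1200), computeMWD(900))
  expect_error(computeMWD(-5), "negative")
  # within the ramp: quadratic in t
  expect_equal(computeMWD(30), 30 / 3.6 + 2.2 / 3.6 * 900 / 120,
               tolerance = 1e-12)
})

test_that("recording-level summary recovers simulated targets", {
  targets <- c(-25, -18, -10, 0, -30, -5)
  rec <- targetRecording(targets, chest = 2, seed = 41)
  ds <- dropSummary(rec)
  expect_true(all(abs(ds@minimalDrops[limbSiteNames] - targets) <= 1))
  expect_equal(unname(ds@ischemia[limbSiteNames]),
               ds@minimalDrops[limbSiteNames] < -15, ignore_attr = TRUE)
  expect_false(ds@hypoxemia)
  expect_equal(ds@referenceProbe, "chest_left")
})

test_that("eligibility screen fires the documented exclusion reasons", {
  rec <- targetRecording(c(-25, -18, -10, 0, -30, -5), chest = 2, seed = 7)
  ds <- dropSummary(rec)
  ok <- screenEligibility(welch = 30, walk10mTime = 8, treadmillTime = 600,
                          drops = ds, limbSymptoms = TRUE)
  expect_true(ok$include)
  expect_equal(
    screenEligibility(30, 8, 16 * 60, ds, TRUE)$reasons, "no_limitation")
  recHyp <- targetRecording(c(-25, -18, -10, 0, -30, -5), chest = 7, seed = 7)
  expect_equal(
    screenEligibility(30, 8, 600, dropSummary(recHyp), TRUE)$reasons,
    "exercise_hypoxemia")
  recMild <- targetRecording(c(-10, -8, -5, 0, -12, -5), seed = 7)
  expect_equal(
    screenEligibility(30, 8, 600, dropSummary(recMild), TRUE)$reasons,
    "no_limb_ischemia")
  expect_error(screenEligibility(NA, 8, 600, ds, TRUE), "welch")
})

test_that("recordings round-trip through the TSV + JSON sidecar interface", {
  rec <- targetRecording(c(-25, -18, -10, 0, -30, -5), chest = 2, seed = 5)
  traces <- tempfile(fileext = ".tsv"); side <- tempfile(fileext = ".json")
  df <- data.frame(time_s = rec@time, rec@pressures, check.names = FALSE)
  utils::write.table(df, traces, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(phases = as.list(rec@phases),
                            probe_status = as.list(rec@probeStatus)),
                       side, auto_unbox = TRUE, digits = NA)
  rec2 <- readTcPO2Recording(traces, side)
  expect_equal(rec2@pressures, rec@pressures, ignore_attr = TRUE)
  expect_equal(dropSummary(rec2)@severityIndex, dropSummary(rec)@severityIndex)
})
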