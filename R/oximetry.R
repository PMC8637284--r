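#' Construct a TcPO2 recording
#'
#' @param time Numeric vector of timestamps (s), strictly increasing.
#' @param pressures Numeric matrix (time x probe, mmHg) with canonical site
#'   column names (`chest_left`, `chest_right`, `buttock_left/right`,
#'   `thigh_left/right`, `calf_left/right`).
#' @param phases Named numeric vector: `rest_start`, `exercise_start`,
#'   `exercise_end`, `recovery_end` (s).
#' @param probeStatus Named logical, `TRUE` for valid probes (defaults to all
#'   valid).
#' @return A [TcPO2Recording-class].
#' @export
TcPO2Recording <- function(time, pressures, phases, probeStatus = NULL) {
  if (is.null(probeStatus)) {
    probeStatus <- rep(TRUE, ncol(pressures))
    names(probeStatus) <- colnames(pressures)
  }
  methods::new("TcPO2Recording", time = as.numeric(time),
               pressures = pressures, phases = phases,
               probeStatus = probeStatus)
}

#' Read a TcPO2 recording from a trace TSV and a phase/status JSON sidecar
#'
#' The trace file has a `time_s` column and one column per probe site; the
#' sidecar holds `phases` (the four phase marks, s) and optionally
#' `probe_status` (site -> logical).
#'
#' @param traceFile Path to the tab-separated trace file.
#' @param phaseFile Path to the JSON sidecar.
#' @return A [TcPO2Recording-class].
#' @export
readTcPO2Recording <- function(traceFile, phaseFile) {
  tr <- utils::read.delim(traceFile, check.names = FALSE, comment.char = "#")
  if (!"time_s" %in% colnames(tr)) stop("trace file must have a time_s column")
  side <- jsonlite::read_json(phaseFile, simplifyVector = TRUE)
  probes <- as.matrix(tr[, setdiff(colnames(tr), "time_s"), drop = FALSE])
  status <- NULL
  if (!is.null(side$probe_status))
    status <- unlist(side$probe_status)[colnames(probes)]
  TcPO2Recording(tr$time_s, probes, unlist(side$phases), status)
}

.phaseIdx <- function(recording, from, to) {
  ph <- recording@phases
  which(recording@time >= ph[from] & recording@time <= ph[to])
}

#' Select the chest reference probe
#'
#' The left thoracic probe is the default reference; on failure the right
#' thoracic probe is used. Both failed (or absent) is unrecoverable.
#'
#' @param recording A [TcPO2Recording-class].
#' @return `"chest_left"` or `"chest_right"`.
#' @export
selectReferenceProbe <- function(recording) {
  st <- recording@probeStatus
  for (site in c("chest_left", "chest_right"))
    if (site %in% colnames(recording@pressures) && isTRUE(st[[site]]))
      return(site)
  stop("no valid chest reference probe available")
}

#' DROP series: limb change from rest minus reference change from rest
#'
#' `DROP(t) = (limb(t) - mean(limb | rest)) - (ref(t) - mean(ref | rest))`,
#' in mmHg. Negative values indicate limb-specific deoxygenation.
#'
#' @param limb,reference Numeric pressure series on a common time base.
#' @param restIdx Indices of the rest phase (baseline window).
#' @return Numeric DROP series, same length as the inputs.
#' @export
computeDropSeries <- function(limb, reference, restIdx) {
  if (length(limb) != length(reference))
    stop("limb and reference series are on different time bases")
  if (length(restIdx) == 0L) stop("empty rest window")
  (limb - mean(limb[restIdx])) - (reference - mean(reference[restIdx]))
}

#' Minimal DROP over an analysis window
#' @param dropSeries Numeric DROP series (mmHg).
#' @param windowIdx Indices of the analysis window (default: whole series).
#' @return The minimum DROP value (mmHg, signed).
#' @export
minimalDrop <- function(dropSeries, windowIdx = seq_along(dropSeries)) {
  if (length(windowIdx) == 0L) stop("empty analysis window")
  min(dropSeries[windowIdx])
}

#' Limb ischemia criterion: minimal DROP strictly below -15 mmHg
#' @param minDrop Minimal DROP (mmHg).
#' @return Logical.
#' @export
classifyLimbIschemia <- function(minDrop) minDrop < -15

#' Exercise-induced systemic hypoxemia on the chest reference probe
#'
#' The chest decrease is the rest-phase mean minus the exercise-phase
#' minimum of the reference series; hypoxemia is a decrease strictly above
#' 5 mmHg.
#'
#' @param reference Chest reference pressure series (mmHg).
#' @param restIdx,exerciseIdx Index windows.
#' @return List with `decrease` (mmHg) and `hypoxemia` (logical).
#' @export
detectExerciseHypoxemia <- function(reference, restIdx, exerciseIdx) {
  if (length(restIdx) == 0L || length(exerciseIdx) == 0L)
    stop("empty phase window")
  decrease <- mean(reference[restIdx]) - min(reference[exerciseIdx])
  list(decrease = decrease, hypoxemia = decrease > 5)
}

#' Ischemia severity index from the six limb minimal DROPs
#'
#' The summed magnitude of the six limb minimal DROPs, reported on a
#' positive scale. Positive minima (no deoxygenation) are clipped to zero
#' before summation so the index is non-negative and monotone in ischemia
#' depth.
#'
#' @param minimalDrops Named numeric of six limb minimal DROPs (mmHg).
#' @param allowPartial Allow fewer than six probes (result carries attribute
#'   `partial = TRUE`).
#' @return Non-negative severity index (mmHg).
#' @examples
#' severityIndex(c(-30, -25, -20, -15, -10, -3))  # 103
#' @export
severityIndex <- function(minimalDrops, allowPartial = FALSE) {
  if (anyNA(minimalDrops)) {
    if (!allowPartial) stop("missing limb probe minima")
    minimalDrops <- minimalDrops[!is.na(minimalDrops)]
  }
  if (length(minimalDrops) != 6L && !allowPartial)
    stop("six limb minima are required")
  idx <- -sum(pmin(minimalDrops, 0))
  if (length(minimalDrops) != 6L) attr(idx, "partial") <- TRUE
  idx
}

.movingAverage <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  h <- k %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)  # window shrinks at the edges
}

#' Summarise a TcPO2 recording into DROP indices
#'
#' Runs the full per-recording analysis: reference-probe selection, per-limb
#' DROP series, minimal DROPs over the analysis window (exercise start
#' through end of recovery by default), ischemia flags (DROP < -15 mmHg),
#' chest hypoxemia (decrease > 5 mmHg) and the severity index. Series are
#' smoothed with a centred moving average before extrema are taken, matching
#' the slow (tens of seconds) response of heated TcPO2 electrodes; the rest
#' baseline is the arithmetic mean of the rest phase.
#'
#' @param recording A [TcPO2Recording-class].
#' @param window `"exercise_to_recovery"` (default) or `"exercise_only"`.
#' @param smoothSeconds Width of the moving-average smoother (s); 0 disables.
#' @param allowPartial Tolerate failed limb probes (partial severity index).
#' @return A [DropSummary-class].
#' @export
dropSummary <- function(recording, window = c("exercise_to_recovery",
                                              "exercise_only"),
                        smoothSeconds = 30, allowPartial = FALSE) {
  window <- match.arg(window)
  ref_site <- selectReferenceProbe(recording)
  dt <- stats::median(diff(recording@time))
  k <- max(1L, round(smoothSeconds / dt))
  P <- apply(recording@pressures, 2, .movingAverage, k = k)
  restIdx <- .phaseIdx(recording, "rest_start", "exercise_start")
  exIdx <- .phaseIdx(recording, "exercise_start", "exercise_end")
  winIdx <- if (window == "exercise_only") exIdx else
    .phaseIdx(recording, "exercise_start", "recovery_end")
  ref <- P[, ref_site]
  limbs <- intersect(.LIMB_SITES, colnames(P))
  mins <- stats::setNames(rep(NA_real_, length(.LIMB_SITES)), .LIMB_SITES)
  for (site in limbs) {
    if (!isTRUE(recording@probeStatus[[site]])) next
    drops <- computeDropSeries(P[, site], ref, restIdx)
    mins[site] <- minimalDrop(drops, winIdx)
  }
  hyp <- detectExerciseHypoxemia(ref, restIdx, exIdx)
  methods::new("DropSummary",
               minimalDrops = mins,
               ischemia = vapply(mins, classifyLimbIschemia, TRUE),
               chestDecrease = hyp$decrease, hypoxemia = hyp$hypoxemia,
               severityIndex = as.numeric(
                 severityIndex(mins, allowPartial = allowPartial)),
               referenceProbe = ref_site)
}

#' Maximum walking distance from treadmill walking time
#'
#' The treadmill starts at 1 km/h, ramps linearly to 3.2 km/h over the first
#' minute and stays at 3.2 km/h until the test ends (at most 15 min).
#'
#' @param walkDuration Walking time (s), capped at 900 s.
#' @return Distance walked (m).
#' @examples
#' computeMWD(60)   # 35 m (mean ramp speed 2.1 km/h)
#' computeMWD(900)  # 781.7 m
#' @export
computeMWD <- function(walkDuration) {
  if (walkDuration < 0) stop("negative walking duration")
  t <- min(walkDuration, 900)
  v0 <- 1 / 3.6; v1 <- 3.2 / 3.6  # m/s
  if (t <= 60) t * v0 + (v1 - v0) * t^2 / (2 * 60)
  else 60 * (v0 + v1) / 2 + (t - 60) * v1
}

#' Eligibility screen against the study exclusion criteria
#'
#' A subject is included only if no exclusion criterion fires. Criteria (and
#' reason codes): no treadmill limitation, i.e. walking time > 15 min
#' (`no_limitation`); 10-m spontaneous walk time > 10 s (`slow_walking`);
#' WELCH score > 50, i.e. insufficient self-reported limitation
#' (`welch_above_50`); no lower-limb symptoms (`no_limb_symptoms`);
#' non-vascular limitation — myocardial ischemia or joint pain
#' (`nonvascular_limitation`); exercise-induced systemic hypoxemia, chest
#' decrease > 5 mmHg (`exercise_hypoxemia`); absence of significant ischemia
#' on all limb probes, i.e. no minimal DROP below -15 mmHg
#' (`no_limb_ischemia`).
#'
#' @param welch WELCH questionnaire score (0-100, lower = more limited).
#' @param walk10mTime Time to walk 10 m at spontaneous speed (s).
#' @param treadmillTime Treadmill walking time (s).
#' @param drops A [DropSummary-class] for the subject's recording.
#' @param limbSymptoms Logical: lower-limb symptoms reported during the test.
#' @param myocardialIschemia,jointPain Logical non-vascular limitation flags.
#' @return List with `include` (logical) and `reasons` (character codes).
#' @export
screenEligibility <- function(welch, walk10mTime, treadmillTime, drops,
                              limbSymptoms, myocardialIschemia = FALSE,
                              jointPain = FALSE) {
  args <- list(welch = welch, walk10mTime = walk10mTime,
               treadmillTime = treadmillTime, drops = drops,
               limbSymptoms = limbSymptoms)
  missing <- names(args)[vapply(args, function(a) is.null(a) ||
                                  (!methods::is(a, "DropSummary") && anyNA(a)),
                                TRUE)]
  if (length(missing))
    stop("missing mandatory field(s): ", paste(missing, collapse = ", "))
  reasons <- character()
  if (treadmillTime > 900) reasons <- c(reasons, "no_limitation")
  if (walk10mTime > 10) reasons <- c(reasons, "slow_walking")
  if (welch > 50) reasons <- c(reasons, "welch_above_50")
  if (!limbSymptoms) reasons <- c(reasons, "no_limb_symptoms")
  if (myocardialIschemia || jointPain)
    reasons <- c(reasons, "nonvascular_limitation")
  if (drops@hypoxemia) reasons <- c(reasons, "exercise_hypoxemia")
  if (!any(drops@ischemia, na.rm = TRUE))
    reasons <- c(reasons, "no_limb_ischemia")
  list(include = length(reasons) == 0L, reasons = reasons)
}

#' Write a DropSummary as JSON
#' @param summary A [DropSummary-class].
#' @param file Output path.
#' @export
writeDropSummary <- function(summary, file) {
  jsonlite::write_json(list(
    minimal_drops = as.list(summary@minimalDrops),
    ischemia = as.list(summary@ischemia),
    chest_decrease = summary@chestDecrease,
    hypoxemia = summary@hypoxemia,
    severity_index = summary@severityIndex,
    reference_probe = summary@referenceProbe),
    file, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(file)
}
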