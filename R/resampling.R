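#' Exact number of k-subsets of n elements
#'
#' Binomial coefficient computed exactly (all values used here are far below
#' 2^53, where double-precision integers are exact).
#'
#' @param n Pool size.
#' @param k Subset (training set) size.
#' @return The exact count as a numeric.
#' @examples
#' countCombinations(30, 20)  # 30045015
#' @export
countCombinations <- function(n, k) {
  stopifnot(n >= 0)
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n")
  out <- round(choose(n, k))
  if (out > 2^53) stop("count exceeds exact double-precision range")
  out
}

#' Unrank a lexicographic k-combination
#'
#' Returns the `index`-th k-subset of `{1..n}` in lexicographic order via
#' the combinatorial number system, so the full combination matrix is never
#' materialised — any column of the conceptual n-choose-k matrix C is
#' reconstructed on demand.
#'
#' @param index 1-based rank, `1 <= index <= choose(n, k)`.
#' @param n Pool size.
#' @param k Subset size.
#' @return Integer vector of length `k`, strictly increasing.
#' @examples
#' unrankCombination(3, 4, 2)  # c(1, 4)
#' @export
unrankCombination <- function(index, n, k) {
  total <- countCombinations(n, k)
  if (index < 1 || index > total)
    stop("index out of range 1..", format(total, scientific = FALSE))
  r <- index - 1
  out <- integer(k)
  v <- 1L
  for (i in seq_len(k)) {
    repeat {
      cnt <- countCombinations(n - v, k - i)
      if (r < cnt) break
      r <- r - cnt
      v <- v + 1L
    }
    out[i] <- v
    v <- v + 1L
  }
  out
}

#' Evenly strided 1-based indices
#'
#' `1, 1 + stride, 1 + 2 stride, ...` up to `total` — the column-sampling
#' rule that thins the full combination enumeration (neighbouring columns
#' are nearly identical, so a large stride decorrelates the sampled models).
#'
#' @param total Number of available indices.
#' @param stride Sampling stride.
#' @return Numeric vector of indices.
#' @examples
#' length(strideIndices(30045015, 1287))  # 23345
#' @export
strideIndices <- function(total, stride) {
  stopifnot(total >= 1, stride >= 1)
  seq(1, total, by = stride)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' `(concordant pairs + ties / 2) / (n0 * n1)` computed via mid-ranks.
#'
#' @param scores Numeric prediction scores (higher = more positive-like).
#' @param labels Binary labels (0/1, logical, or two-level factor with the
#'   positive class second).
#' @return AUROC in `[0, 1]`.
#' @export
computeAUROC <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Two-sided Mann-Whitney p-value for score separation
#'
#' The probability that a model with no discriminating ability separates the
#' two classes at least this well. Exact enumeration of the U distribution
#' when `n0 * n1 <= 400` and there are no ties, otherwise the tie-corrected
#' normal approximation.
#'
#' @inheritParams computeAUROC
#' @return p-value in `(0, 1]`.
#' @export
aurocPvalue <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.numeric(labels)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0)
    stop("both classes must be present")
  exact <- length(pos) * length(neg) <= 400 &&
    !any(duplicated(c(pos, neg)))
  p <- suppressWarnings(stats::wilcox.test(
    pos, neg, alternative = "two.sided", exact = exact,
    correct = !exact))$p.value
  min(max(p, .Machine$double.xmin), 1)
}

#' Build the subject allocation scheme for the combination ensemble
#'
#' Draws the held-out test subjects once with the given seed, leaves the
#' remaining subjects as the training-validation pool, and selects every
#' `stride`-th k-combination (lexicographic order) of the pool as the model
#' training sets. Defaults mirror the study design: 9 test subjects, a pool
#' of 30 split 20 training / 10 validation, and stride 1287 over the
#' 30,045,015 combinations, giving 23,345 models.
#'
#' @param subjects Character vector of subject ids.
#' @param testSize Number of test subjects.
#' @param trainSize Training subjects per model.
#' @param stride Combination sampling stride.
#' @param seed Integer seed for the test-set draw (required).
#' @return A [SplitScheme-class].
#' @export
makeSplitScheme <- function(subjects, testSize = 9, trainSize = 20,
                            stride = 1287, seed) {
  stopifnot(!missing(seed))
  subjects <- as.character(subjects)
  if (testSize >= length(subjects)) stop("testSize leaves no pool")
  test <- withSeed(seed, sample(subjects, testSize))
  pool <- setdiff(subjects, test)
  total <- countCombinations(length(pool), trainSize)
  methods::new("SplitScheme", subjects = subjects, testSubjects = test,
               poolSubjects = pool, trainSize = as.integer(trainSize),
               stride = as.integer(stride),
               combinationIndices = strideIndices(total, stride),
               seed = as.integer(seed))
}

# Evaluate RNG-dependent code under a local, restored seed.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.modelSplit <- function(scheme, i) {
  idx <- unrankCombination(scheme@combinationIndices[i],
                          length(scheme@poolSubjects), scheme@trainSize)
  list(train = scheme@poolSubjects[idx],
       validation = scheme@poolSubjects[-idx])
}

.fitEvalModel <- function(within, subject, condition, trainSubjects,
                          evalSubjects, nComponents) {
  tr <- subject %in% trainSubjects
  ev <- subject %in% evalSubjects
  model <- fitPLSDA(within[tr, , drop = FALSE],
                    as.numeric(condition[tr] == "post"),
                    nComponents = nComponents)
  pred <- predictScores(model, within[ev, , drop = FALSE])
  y <- as.numeric(condition[ev] == "post")
  list(model = model, predicted = pred$predicted, y = y,
       auroc = computeAUROC(pred$predicted, y),
       p = aurocPvalue(pred$predicted, y))
}

#' Run the combination-ensemble validation of the paired PLS-DA
#'
#' For every sampled training combination, fits a paired PLS-DA on the
#' training subjects' within-subject matrix, scores the validation subjects
#' and records the validation AUROC and its Mann-Whitney p-value. Global
#' performance is declared satisfactory only when the median validation
#' AUROC is at least `gateAuroc` (0.8) and the median p-value at most
#' `gateP` (0.05). If the gate passes, the best models (validation AUROC >=
#' `bestCutoff`, default 0.95) are applied to the held-out test subjects,
#' and per-metabolite VIPs and component-1 loadings, per-sample latent
#' scores, and test AUROC/p are aggregated across best models by the median.
#' Discriminant metabolites are those with median VIP >= 1; their direction
#' is the sign of the median loading (negative = decreased after exercise).
#'
#' @param dataset A QC-filtered, outlier-screened [PairedMetabolome-class].
#' @param scheme A [SplitScheme-class] over the dataset's subjects.
#' @param nComponents Latent variables per model (default 2).
#' @param bestCutoff Validation-AUROC cutoff for the best-model set.
#' @param gateAuroc,gateP Global-performance gate thresholds.
#' @return An [EnsembleResult-class].
#' @export
runEnsemble <- function(dataset, scheme, nComponents = 2,
                        bestCutoff = 0.95, gateAuroc = 0.8, gateP = 0.05) {
  stopifnot(methods::is(dataset, "PairedMetabolome"),
            methods::is(scheme, "SplitScheme"))
  if (!setequal(scheme@subjects, unique(subjectIds(dataset))))
    stop("scheme subjects do not match dataset subjects")
  dec <- pairedWithinMatrix(dataset)
  within <- dec$within; subject <- dec$subject; condition <- dec$condition
  m <- length(scheme@combinationIndices)
  auroc <- pval <- numeric(m)
  for (i in seq_len(m)) {
    sp <- .modelSplit(scheme, i)
    fit <- .fitEvalModel(within, subject, condition, sp$train, sp$validation,
                         nComponents)
    auroc[i] <- fit$auroc; pval[i] <- fit$p
  }
  evals <- data.frame(combination = scheme@combinationIndices,
                      auroc = auroc, p = pval)
  medAuroc <- stats::median(auroc)
  medP <- stats::median(pval)
  gate <- medAuroc >= gateAuroc && medP <= gateP

  nmet <- ncol(within)
  empty <- stats::setNames(rep(NA_real_, nmet), colnames(within))
  res <- methods::new("EnsembleResult", evaluations = evals,
                      medianValidationAuroc = medAuroc,
                      medianValidationP = medP, gatePassed = gate,
                      bestIndices = numeric(), bestCutoff = bestCutoff,
                      medianTestAuroc = NA_real_, medianTestP = NA_real_,
                      vipMedian = empty, loadingMedian = empty,
                      sampleScores = matrix(numeric(), 0, 2),
                      discriminants = data.frame())
  if (!gate) {
    warning("global-performance gate failed (median AUROC ",
            signif(medAuroc, 3), ", median p ", signif(medP, 3),
            "); discriminant selection suppressed")
    return(res)
  }

  best <- selectBestModels(evals, bestCutoff)
  nb <- length(best)
  vips <- loads <- matrix(NA_real_, nb, nmet, dimnames = list(NULL, colnames(within)))
  lv1 <- lv2 <- matrix(NA_real_, nb, nrow(within),
                       dimnames = list(NULL, rownames(within)))
  tAuroc <- tP <- numeric(nb)
  for (b in seq_len(nb)) {
    i <- best[b]
    sp <- .modelSplit(scheme, i)
    fit <- .fitEvalModel(within, subject, condition, sp$train,
                         scheme@testSubjects, nComponents)
    tAuroc[b] <- fit$auroc; tP[b] <- fit$p
    vips[b, ] <- computeVIP(fit$model)
    loads[b, ] <- fit$model@xLoadings[, 1]
    pr <- predictScores(fit$model, within)
    lv1[b, ] <- pr$scores[, 1]
    lv2[b, ] <- if (fit$model@nComponents >= 2) pr$scores[, 2] else NA_real_
  }
  res@bestIndices <- scheme@combinationIndices[best]
  res@medianTestAuroc <- stats::median(tAuroc)
  res@medianTestP <- stats::median(tP)
  res@vipMedian <- apply(vips, 2, stats::median)
  res@loadingMedian <- apply(loads, 2, stats::median)
  res@sampleScores <- cbind(LV1 = apply(lv1, 2, stats::median),
                            LV2 = apply(lv2, 2, stats::median))
  res@discriminants <- buildVolcanoTable(res)
  res
}

#' Select best models by validation AUROC cutoff
#'
#' Returns the positions (row indices of `evals`) of models with validation
#' AUROC at or above `cutoff`. When none qualifies, falls back to the top
#' decile with a warning.
#'
#' @param evals data.frame with an `auroc` column.
#' @param cutoff AUROC cutoff.
#' @param fallbackTopDecile Use the top decile when the cutoff selects
#'   nothing (default `TRUE`).
#' @return Integer positions into `evals`.
#' @export
selectBestModels <- function(evals, cutoff, fallbackTopDecile = TRUE) {
  stopifnot(nrow(evals) > 0)
  idx <- which(evals$auroc >= cutoff)
  if (length(idx) == 0L) {
    if (!fallbackTopDecile) {
      warning("no model reaches the AUROC cutoff ", cutoff)
      return(integer())
    }
    warning("no model reaches the AUROC cutoff ", cutoff,
            "; falling back to the top decile")
    k <- max(1L, ceiling(nrow(evals) / 10))
    idx <- order(evals$auroc, decreasing = TRUE)[seq_len(k)]
  }
  idx
}

#' Volcano table: median loading vs median VIP per metabolite
#'
#' One row per metabolite with its median component-1 loading and median VIP
#' across the best models, the discriminant flag (VIP >= 1) and the
#' direction of change (sign of the loading; negative = decreased after
#' exercise).
#'
#' @param ensemble An [EnsembleResult-class] whose gate passed.
#' @return data.frame with columns `metabolite`, `median_loading`,
#'   `median_vip`, `discriminant`, `direction`.
#' @export
buildVolcanoTable <- function(ensemble) {
  if (!ensemble@gatePassed)
    stop("global-performance gate failed; no discriminant selection")
  v <- ensemble@vipMedian
  l <- ensemble@loadingMedian
  data.frame(metabolite = names(v), median_loading = unname(l),
             median_vip = unname(v), discriminant = unname(v >= 1),
             direction = ifelse(l > 0, "increased",
                                ifelse(l < 0, "decreased", "unchanged")),
             row.names = NULL)
}
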