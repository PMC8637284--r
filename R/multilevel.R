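#' Centre and unit-variance scale a matrix (autoscaling)
#'
#' Columns are centred and divided by their sample standard deviation
#' (denominator n - 1). When `params` is supplied (a list with `center` and
#' `scale`, as returned by a previous call), those training parameters are
#' applied instead — the projection used for validation and test samples.
#'
#' @param x Numeric matrix (samples x variables).
#' @param params Optional scaling parameters from a training fit.
#' @param dropConstant Drop zero-variance columns with a warning instead of
#'   erroring.
#' @return List with `x` (scaled matrix), `center`, `scale`.
#' @export
autoscale <- function(x, params = NULL, dropConstant = FALSE) {
  stopifnot(is.matrix(x))
  if (is.null(params)) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    zero <- scl <= .Machine$double.eps * 10
    if (any(zero)) {
      bad <- colnames(x)[zero]
      if (is.null(bad)) bad <- which(zero)
      if (!dropConstant)
        stop("zero-variance column(s): ", paste(bad, collapse = ", "))
      warning("dropping zero-variance column(s): ", paste(bad, collapse = ", "))
      x <- x[, !zero, drop = FALSE]
      ctr <- ctr[!zero]; scl <- scl[!zero]
    }
  } else {
    if (!is.null(names(params$center)) && !is.null(colnames(x)))
      x <- x[, names(params$center), drop = FALSE]
    ctr <- params$center; scl <- params$scale
  }
  list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

#' Multilevel (within-subject) decomposition of a paired matrix
#'
#' Splits a paired samples x variables matrix into its between-subject part
#' (subject means, centred on the grand mean) and its within-subject part
#' (each row's deviation from its subject mean). For a rest/post pair with
#' difference `d = post - rest`, the within rows are `-d/2` and `+d/2`. The
#' decomposition is exact: `within + between + grand` reconstructs the
#' input. Paired multivariate analyses (pPCA, pPLS-DA) operate on the
#' within part, which isolates the exercise effect from between-subject
#' concentration differences.
#'
#' @param x Numeric matrix, samples x variables.
#' @param subject Subject id per row.
#' @return List with `within`, `between` (same shape as `x`) and `grand`
#'   (the grand mean row vector).
#' @export
withinSubjectDecompose <- function(x, subject) {
  stopifnot(is.matrix(x), length(subject) == nrow(x))
  tab <- table(subject)
  if (any(tab != 2L))
    stop("unpaired subject(s): ",
         paste(names(tab)[tab != 2L], collapse = ", "))
  subject <- as.character(subject)
  means <- rowsum(x, subject) / as.vector(tab[sort(unique(subject))])
  sm <- means[subject, , drop = FALSE]
  grand <- colMeans(x)
  within <- x - sm
  between <- sm - matrix(grand, nrow(x), ncol(x), byrow = TRUE)
  dimnames(within) <- dimnames(between) <- dimnames(x)
  list(within = within, between = between, grand = grand)
}

#' Extract the paired within-subject matrix of a PairedMetabolome
#'
#' Convenience wrapper: transposes to samples x metabolites and applies
#' [withinSubjectDecompose()].
#'
#' @param dataset A [PairedMetabolome-class].
#' @return List as in [withinSubjectDecompose()] plus `subject` and
#'   `condition` row annotations.
#' @export
pairedWithinMatrix <- function(dataset) {
  x <- t(concentrations(dataset))
  dec <- withinSubjectDecompose(x, subjectIds(dataset))
  dec$subject <- subjectIds(dataset)
  dec$condition <- sampleConditions(dataset)
  dec
}

#' Principal component analysis
#'
#' Thin wrapper around [stats::prcomp] returning scores, loadings and
#' explained-variance fractions. For paired PCA (pPCA) apply it to the
#' within-subject matrix of [pairedWithinMatrix()] after autoscaling.
#'
#' @param x Numeric matrix, samples x variables (centred internally).
#' @param nComponents Number of components to keep.
#' @return A [PcaResult-class].
#' @export
fitPCA <- function(x, nComponents = 2) {
  stopifnot(is.matrix(x))
  maxc <- min(nrow(x) - 1L, ncol(x))
  if (nComponents > maxc)
    stop("nComponents exceeds min(rows - 1, cols) = ", maxc)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  keep <- seq_len(nComponents)
  methods::new("PcaResult",
               scores = p$x[, keep, drop = FALSE],
               loadings = p$rotation[, keep, drop = FALSE],
               explainedVariance = ev[keep])
}

#' Robust PC1 outlier flagging
#'
#' A sample is flagged when its PC1 score deviates from the median by more
#' than `k` robust standard deviations (MAD with the normal consistency
#' constant). Flagging either sample of a subject flags the subject, whose
#' two samples should then both be excluded — use [removeSubjects()].
#'
#' @param pca A [PcaResult-class] fitted on the paired within matrix.
#' @param subject Subject id per score row.
#' @param k Deviation multiplier (default 5).
#' @return Character vector of flagged subject ids (possibly empty).
#' @export
flagOutliers <- function(pca, subject, k = 5) {
  s <- pca@scores[, 1]
  dev <- abs(s - stats::median(s))
  rsd <- stats::mad(s)
  flagged <- dev > k * rsd
  unique(as.character(subject[flagged]))
}

#' Drop all samples of the given subjects from a PairedMetabolome
#' @param dataset A [PairedMetabolome-class].
#' @param subjects Subject ids to remove.
#' @return The reduced [PairedMetabolome-class].
#' @export
removeSubjects <- function(dataset, subjects) {
  dataset[, !subjectIds(dataset) %in% subjects]
}

#' Fit a PLS-DA model by NIPALS (PLS1 on the class vector)
#'
#' The class vector is coded 0 (rest) / 1 (post) and centred; `x` is
#' autoscaled internally (training parameters stored in the model). Per
#' component: the weight vector is the normalised covariance `X'y`, scores
#' `t = Xw`, X-loadings `p = X't / t't`, Y-loading `q = y't / t't`, followed
#' by deflation of both `X` and `y`. Components are sign-fixed so that the
#' Y-loading is positive — a positive variable loading then means a higher
#' value in the post-exercise class.
#'
#' @param x Numeric matrix, samples x variables (raw scale; scaled inside).
#' @param y Binary class vector (0/1, logical, or a two-level factor whose
#'   second level codes "post").
#' @param nComponents Number of latent variables (default 2).
#' @param scale Autoscale `x` (default `TRUE`).
#' @return A [PlsdaModel-class].
#' @export
fitPLSDA <- function(x, y, nComponents = 2, scale = TRUE) {
  stopifnot(is.matrix(x))
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (nrow(x) < 2L) stop("at least two samples are required")
  if (scale) {
    sc <- autoscale(x)
    X <- sc$x; ctr <- sc$center; scl <- sc$scale
  } else {
    X <- x
    ctr <- stats::setNames(rep(0, ncol(x)), colnames(x))
    scl <- stats::setNames(rep(1, ncol(x)), colnames(x))
  }
  ymean <- mean(y)
  yc <- y - ymean
  p <- ncol(X); n <- nrow(X)
  W <- P <- matrix(0, p, nComponents,
                   dimnames = list(colnames(x), paste0("LV", seq_len(nComponents))))
  Tm <- matrix(0, n, nComponents,
               dimnames = list(rownames(x), paste0("LV", seq_len(nComponents))))
  q <- numeric(nComponents)
  A <- 0L
  for (a in seq_len(nComponents)) {
    w <- crossprod(X, yc)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # no residual covariance left
    w <- w / nw
    t <- X %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pl <- crossprod(X, t)[, 1] / tt
    qa <- sum(yc * t) / tt
    if (qa < 0) { w <- -w; t <- -t; pl <- -pl; qa <- -qa }
    X <- X - t %*% t(pl)
    yc <- yc - qa * t
    W[, a] <- w; Tm[, a] <- t; P[, a] <- pl; q[a] <- qa
    A <- a
  }
  if (A == 0L) stop("no PLS component could be extracted (X'y is zero)")
  methods::new("PlsdaModel",
               weights = W[, seq_len(A), drop = FALSE],
               scores = Tm[, seq_len(A), drop = FALSE],
               xLoadings = P[, seq_len(A), drop = FALSE],
               yLoadings = q[seq_len(A)],
               center = ctr, scale = scl, yMean = ymean,
               nComponents = A,
               columnIds = if (is.null(colnames(x))) character() else colnames(x))
}

#' Project new samples onto a fitted PLS-DA model
#'
#' Applies the training scaling parameters, computes latent-variable scores
#' by successive weight projection and loading deflation, and returns the
#' scalar predicted class score `yMean + sum_a t_a q_a` per sample (higher
#' means more post-exercise-like).
#'
#' @param model A [PlsdaModel-class].
#' @param xNew Numeric matrix, samples x variables, with the training
#'   columns.
#' @return List with `scores` (samples x components) and `predicted`.
#' @export
predictScores <- function(model, xNew) {
  stopifnot(is.matrix(xNew))
  if (length(model@columnIds)) {
    if (is.null(colnames(xNew))) {
      if (ncol(xNew) != length(model@columnIds))
        stop("column mismatch with training data")
    } else {
      if (!all(model@columnIds %in% colnames(xNew)))
        stop("column mismatch with training data: missing ",
             paste(setdiff(model@columnIds, colnames(xNew))[1:3], collapse = ", "))
      xNew <- xNew[, model@columnIds, drop = FALSE]
    }
  }
  X <- sweep(sweep(xNew, 2, model@center), 2, model@scale, "/")
  A <- model@nComponents
  Tn <- matrix(0, nrow(X), A,
               dimnames = list(rownames(xNew), paste0("LV", seq_len(A))))
  for (a in seq_len(A)) {
    t <- X %*% model@weights[, a]
    Tn[, a] <- t
    X <- X - t %*% t(model@xLoadings[, a])
  }
  list(scores = Tn,
       predicted = as.numeric(model@yMean + Tn %*% model@yLoadings))
}

#' Variable importance for the projection (VIP)
#'
#' `VIP_j = sqrt( p * sum_a SS_a w_{aj}^2 / sum_a SS_a )` with unit-norm
#' weight vectors and `SS_a = q_a^2 t_a' t_a`, the Y-variance explained by
#' component `a`. The squared VIPs average to 1, so VIP > 1 marks a variable
#' as more important than average for the discrimination.
#'
#' @param model A [PlsdaModel-class].
#' @return Named numeric VIP per variable.
#' @export
computeVIP <- function(model) {
  W <- model@weights
  ss <- model@yLoadings^2 * colSums(model@scores^2)
  p <- nrow(W)
  vip <- sqrt(p * as.numeric(W^2 %*% ss) / sum(ss))
  stats::setNames(vip, rownames(W))
}

#' Serialize a PLS-DA model to JSON (audit trail)
#' @param model A [PlsdaModel-class].
#' @param file Output path.
#' @export
writePlsdaModel <- function(model, file) {
  jsonlite::write_json(list(
    weights = model@weights, x_loadings = model@xLoadings,
    y_loadings = model@yLoadings, center = model@center,
    scale = model@scale, y_mean = model@yMean,
    n_components = model@nComponents, column_ids = model@columnIds),
    file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}
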