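# Independent oracles, deliberately minimal and written differently from the
# package implementations they check.

# NIPALS PLS1 with explicit loops; X autoscaled, y centred, q sign-fixed.
naiveNipals <- function(X, y, A) {
  n <- nrow(X); p <- ncol(X)
  ctr <- colMeans(X)
  scl <- sqrt(colSums((X - matrix(ctr, n, p, byrow = TRUE))^2) / (n - 1))
  Xd <- (X - matrix(ctr, n, p, byrow = TRUE)) /
    matrix(scl, n, p, byrow = TRUE)
  yc <- y - mean(y)
  W <- P <- matrix(0, p, A); Tm <- matrix(0, n, A); q <- numeric(A)
  for (a in seq_len(A)) {
    w <- numeric(p)
    for (j in seq_len(p)) w[j] <- sum(Xd[, j] * yc)
    w <- w / sqrt(sum(w * w))
    t <- numeric(n)
    for (i in seq_len(n)) t[i] <- sum(Xd[i, ] * w)
    tt <- sum(t * t)
    pl <- numeric(p)
    for (j in seq_len(p)) pl[j] <- sum(Xd[, j] * t) / tt
    qa <- sum(yc * t) / tt
    if (qa < 0) { w <- -w; t <- -t; pl <- -pl; qa <- -qa }
    Xd <- Xd - outer(t, pl)
    yc <- yc - qa * t
    W[, a] <- w; Tm[, a] <- t; P[, a] <- pl; q[a] <- qa
  }
  list(W = W, T = Tm, P = P, q = q)
}

# AUROC by exhaustive pair counting.
pairCountAuroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# Pearson chi-squared statistic on a 2x2 table from first principles.
chi2Oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# All k-subsets of 1..n in lexicographic order, as a list.
lexCombinations <- function(n, k) {
  if (k == 0) return(list(integer(0)))
  m <- utils::combn(n, k)
  lapply(seq_len(ncol(m)), function(i) m[, i])
}

limbSiteNames <- c("buttock_left", "buttock_right", "thigh_left",
                   "thigh_right", "calf_left", "calf_right")

# Tiny paired dataset on a panel subset, with a constant log-scale effect
# applied to chosen metabolites.
tinyPairedDataset <- function(nSubjects, analytes, effects = numeric(),
                              seed = 1) {
  panel <- subsetPanel(buildP180Panel(), analytes)
  cfg <- simConfig(nSubjects = nSubjects, panel = panel,
                   discriminantEffects = effects, seed = seed)
  simulatePairedMetabolome(cfg)
}

# A synthetic recording whose six limb probes target the given minimal DROPs.
targetRecording <- function(drops, chest = 0, seed = 1, noiseSd = 1) {
  simulateTcPO2(stats::setNames(drops, limbSiteNames),
                chestDecrease = chest, seed = seed, noiseSd = noiseSd)
}
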