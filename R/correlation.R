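#' Exercise-induced change per subject and metabolite
#'
#' The arithmetic post-minus-rest concentration difference per subject (a
#' log-ratio alternative is available via `logRatio = TRUE`). Indicator
#' ratios are computed per condition first and then differenced.
#'
#' @param dataset A [PairedMetabolome-class].
#' @param panel Optional [MetabolitePanel-class]; when given, the three
#'   indicator ratios ([computeIndicatorRatios()]) are appended as rows.
#' @param logRatio Use `log(post / rest)` instead of `post - rest`.
#' @return Matrix, (metabolites + ratios) x subjects.
#' @export
exerciseDelta <- function(dataset, panel = NULL, logRatio = FALSE) {
  stopifnot(methods::is(dataset, "PairedMetabolome"))
  conc <- concentrations(dataset)
  cond <- sampleConditions(dataset)
  subj <- subjectIds(dataset)
  rest <- conc[, cond == "rest", drop = FALSE]
  post <- conc[, cond == "post", drop = FALSE]
  post <- post[, match(subj[cond == "rest"], subj[cond == "post"]),
               drop = FALSE]
  if (!is.null(panel)) {
    r_rest <- computeIndicatorRatios(rest, panel)
    r_post <- computeIndicatorRatios(post, panel)
    rest <- rbind(rest, r_rest)
    post <- rbind(post, r_post)
  }
  d <- if (logRatio) log(post / rest) else post - rest
  colnames(d) <- subj[cond == "rest"]
  d
}

#' Pearson correlation with a two-sided t-based p-value
#'
#' Thin wrapper around [stats::cor.test] (t distribution, n - 2 degrees of
#' freedom) with pairwise-complete handling: rows with a missing value in
#' either argument are dropped. Zero variance in either argument yields an
#' undefined correlation (`NA`) rather than an error.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r`, `p` and `n` (pairs used).
#' @export
pearsonWithP <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlate exercise-induced changes with clinical severity scores
#'
#' Full grid of Pearson correlations (with unadjusted two-sided p-values)
#' between each retained metabolite's (or ratio's) exercise-induced change
#' and each severity score: ABI, the summed-DROP severity index, maximum
#' walking time and the WELCH score. No multiple-testing adjustment is
#' applied; the `significant` flag simply marks p < 0.05.
#'
#' @param deltas Matrix from [exerciseDelta()], variables x subjects.
#' @param scores data.frame with `subject_id` and score columns `ABI`,
#'   `DROPs`, `MWT`, `WELCH` (missing columns are skipped).
#' @return data.frame, one row per variable, with `r_<score>`, `p_<score>`
#'   columns and a `significant` flag (any p < 0.05).
#' @export
correlationTable <- function(deltas, scores) {
  stopifnot(is.matrix(deltas), "subject_id" %in% colnames(scores))
  missing <- setdiff(colnames(deltas), scores$subject_id)
  if (length(missing))
    stop("subjects without severity scores: ", paste(missing, collapse = ", "))
  scores <- scores[match(colnames(deltas), scores$subject_id), ]
  cols <- intersect(c("ABI", "DROPs", "MWT", "WELCH"), colnames(scores))
  out <- data.frame(variable = rownames(deltas), row.names = NULL)
  anySig <- rep(FALSE, nrow(deltas))
  for (sc in cols) {
    res <- apply(deltas, 1, pearsonWithP, y = scores[[sc]])
    out[[paste0("r_", sc)]] <- vapply(res, `[[`, numeric(1), "r")
    out[[paste0("p_", sc)]] <- vapply(res, `[[`, numeric(1), "p")
    anySig <- anySig | (!is.na(out[[paste0("p_", sc)]]) &
                          out[[paste0("p_", sc)]] < 0.05)
  }
  out$significant <- anySig
  out
}

#' Write a correlation grid (and its significant rows) as TSV
#' @param table data.frame from [correlationTable()].
#' @param file Output path for the full grid.
#' @param significantFile Optional path for the significant-rows subset.
#' @export
writeCorrelationTable <- function(table, file, significantFile = NULL) {
  con <- file(file, "w")
  writeLines("# Pearson correlations, two-sided p, no multiplicity adjustment",
             con)
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(significantFile)) {
    con <- file(significantFile, "w")
    writeLines("# rows with at least one unadjusted p < 0.05", con)
    utils::write.table(table[table$significant, , drop = FALSE], con,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(file)
}
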