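#' Quantitation-range quality-control filter
#'
#' Removes metabolites with more than 20% of their values outside the
#' quantitation range (below LLOQ or above ULOQ). For metabolites with more
#' than 20% but less than 40% out of range, a 2x2 chi-squared test of
#' independence between in/out-of-range status and the rest/post condition
#' is computed and recorded before removal; a p-value below 0.05 indicates
#' condition-dependent missingness and triggers a warning (such metabolites
#' can be kept with `retainIfDependent = TRUE`). Out-of-range values in
#' retained metabolites are replaced, by default with the violated limit,
#' alternatively with LLOQ/2 for values below range
#' (`substitute = "half_lloq"`).
#'
#' The filter is idempotent: substituted values lie inside the quantitation
#' range, so re-filtering a filtered dataset changes nothing.
#'
#' @param dataset A [PairedMetabolome-class]; its `rangeFlag` assay marks
#'   out-of-range values (derived from panel limits at construction).
#' @param panel A [MetabolitePanel-class] covering every metabolite of
#'   `dataset`.
#' @param retainIfDependent Keep 20-40% metabolites whose chi-squared test
#'   indicates condition-dependent missingness (p < 0.05). Default `FALSE`:
#'   all metabolites above 20% are removed.
#' @param substitute `"clamp"` (violated limit) or `"half_lloq"`.
#' @param yatesCorrection Apply the continuity correction in the chi-squared
#'   test (default `FALSE`, the plain Pearson statistic).
#' @return A list with `dataset` (filtered [PairedMetabolome-class]) and
#'   `report` (a [QCReport-class]).
#' @examples
#' cfg <- simConfig(nSubjects = 6, seed = 1)
#' sim <- simulatePairedMetabolome(cfg)
#' qc <- quantitationFilter(sim$dataset, sim$panel)
#' @export
quantitationFilter <- function(dataset, panel,
                               retainIfDependent = FALSE,
                               substitute = c("clamp", "half_lloq"),
                               yatesCorrection = FALSE) {
  substitute <- match.arg(substitute)
  stopifnot(methods::is(dataset, "PairedMetabolome"))
  if (ncol(dataset) == 0L) stop("empty dataset")
  d <- panelDescriptors(subsetPanel(panel, rownames(dataset)))
  conc <- concentrations(dataset)
  flags <- rangeFlags(dataset)
  cond <- sampleConditions(dataset)
  n <- ncol(conc)

  frac_out <- rowMeans(flags != 0L)
  decision <- rep("retained_leq20", nrow(conc))
  chi2 <- chi2p <- rep(NA_real_, nrow(conc))
  n_clamped <- integer(nrow(conc))

  mid <- frac_out > 0.20 & frac_out < 0.40
  for (j in which(mid)) {
    tab <- table(factor(flags[j, ] != 0L, c(FALSE, TRUE)),
                 factor(cond, c("rest", "post")))
    ct <- suppressWarnings(
      stats::chisq.test(tab, correct = yatesCorrection))
    chi2[j] <- unname(ct$statistic)
    chi2p[j] <- ct$p.value
    keep <- retainIfDependent && !is.na(chi2p[j]) && chi2p[j] < 0.05
    decision[j] <- if (keep) "retained" else "removed_20to40"
    if (!keep && !is.na(chi2p[j]) && chi2p[j] < 0.05)
      warning("metabolite '", rownames(conc)[j],
              "' shows condition-dependent missingness (chi2 p = ",
              signif(chi2p[j], 3), ") and is removed")
  }
  decision[frac_out >= 0.40] <- "removed_gt40"

  retained <- decision %in% c("retained_leq20", "retained")
  for (j in which(retained)) {
    below <- flags[j, ] == -1L
    above <- flags[j, ] == 1L
    conc[j, below] <- if (substitute == "clamp") d$lloq[j] else d$lloq[j] / 2
    conc[j, above] <- d$uloq[j]
    n_clamped[j] <- sum(below | above)
    flags[j, ] <- 0L
  }

  report <- methods::new("QCReport", nSamples = n, table = S4Vectors::DataFrame(
    analyte_id = rownames(conc), fraction_out = frac_out,
    decision = decision, chi2_statistic = chi2, chi2_p = chi2p,
    n_clamped = n_clamped, row.names = rownames(conc)))

  filtered <- dataset[retained, ]
  SummarizedExperiment::assay(filtered, "concentration") <-
    conc[retained, , drop = FALSE]
  SummarizedExperiment::assay(filtered, "rangeFlag") <-
    flags[retained, , drop = FALSE]
  S4Vectors::metadata(filtered)$qc <-
    list(filtered = TRUE, removed = rownames(conc)[!retained],
         substitute = substitute)
  list(dataset = filtered, report = report)
}

#' Accessor for the QC report table
#' @param report A [QCReport-class].
#' @return The per-metabolite decision [S4Vectors::DataFrame].
#' @export
qcTable <- function(report) {
  stopifnot(methods::is(report, "QCReport"))
  report@table
}

#' Serialize a QC report
#'
#' Writes the per-metabolite decision table as tab-separated text and, when
#' `json` is given, a JSON rendering of the same content.
#'
#' @param report A [QCReport-class].
#' @param tsv,json Output paths (either may be `NULL`).
#' @export
writeQCReport <- function(report, tsv = NULL, json = NULL) {
  t <- as.data.frame(qcTable(report))
  if (!is.null(tsv)) {
    con <- file(tsv, "w")
    writeLines(paste0("# quantitation-range QC report; n_samples=",
                      report@nSamples), con)
    utils::write.table(t, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  if (!is.null(json))
    jsonlite::write_json(list(n_samples = report@nSamples, table = t),
                         json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}
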