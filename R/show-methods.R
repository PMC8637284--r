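#' @describeIn MetabolitePanel-class Compact display with class counts.
#' @param object A MetabolitePanel.
#' @export
setMethod("show", "MetabolitePanel", function(object) {
  d <- object@descriptors
  cat("MetabolitePanel with", nrow(d), "analytes\n")
  print(table(d$metabolite_class))
})

#' @describeIn QCReport-class Decision counts and flagged metabolites.
#' @param object A QCReport.
#' @export
setMethod("show", "QCReport", function(object) {
  t <- object@table
  cat("QCReport over", nrow(t), "metabolites,", object@nSamples, "samples\n")
  print(table(t$decision))
  dep <- !is.na(t$chi2_p) & t$chi2_p < 0.05
  if (any(dep))
    cat("condition-dependent missingness (chi2 p < 0.05):",
        paste(t$analyte_id[dep], collapse = ", "), "\n")
})

#' @describeIn TcPO2Recording-class Probe and phase overview.
#' @param object A TcPO2Recording.
#' @export
setMethod("show", "TcPO2Recording", function(object) {
  cat("TcPO2Recording:", length(object@time), "samples,",
      ncol(object@pressures), "probes\n")
  cat("  phases (s):",
      paste(names(object@phases), round(object@phases), sep = "=",
            collapse = ", "), "\n")
  bad <- names(object@probeStatus)[!object@probeStatus]
  if (length(bad)) cat("  failed probes:", paste(bad, collapse = ", "), "\n")
})

#' @describeIn DropSummary-class Minimal DROPs, flags and severity index.
#' @param object A DropSummary.
#' @export
setMethod("show", "DropSummary", function(object) {
  cat("DropSummary (reference:", object@referenceProbe, ")\n")
  print(round(object@minimalDrops, 1))
  cat("  ischemic probes:", sum(object@ischemia, na.rm = TRUE),
      "| chest decrease:", round(object@chestDecrease, 1),
      "mmHg | hypoxemia:", object@hypoxemia, "\n")
  cat("  severity index:", round(object@severityIndex, 1), "mmHg\n")
})

#' @describeIn PcaResult-class Explained variance per component.
#' @param object A PcaResult.
#' @export
setMethod("show", "PcaResult", function(object) {
  cat("PcaResult:", ncol(object@scores), "components over",
      nrow(object@scores), "samples\n")
  cat("  explained variance:",
      paste(round(100 * object@explainedVariance, 1), "%", collapse = ", "),
      "\n")
})

#' @describeIn PlsdaModel-class Component overview.
#' @param object A PlsdaModel.
#' @export
setMethod("show", "PlsdaModel", function(object) {
  cat("PlsdaModel:", object@nComponents, "component(s),",
      nrow(object@weights), "variables,", nrow(object@scores),
      "training samples\n")
})

#' @describeIn SplitScheme-class Allocation overview.
#' @param object A SplitScheme.
#' @export
setMethod("show", "SplitScheme", function(object) {
  n <- length(object@poolSubjects)
  cat("SplitScheme:", length(object@subjects), "subjects =",
      n, "pool +", length(object@testSubjects), "test\n")
  cat("  training", object@trainSize, "/ validation",
      n - object@trainSize, "; stride", object@stride, "->",
      length(object@combinationIndices), "of",
      format(countCombinations(n, object@trainSize), big.mark = ","),
      "combinations\n")
})

#' @describeIn EnsembleResult-class Medians, gate and discriminant count.
#' @param object An EnsembleResult.
#' @export
setMethod("show", "EnsembleResult", function(object) {
  cat("EnsembleResult:", nrow(object@evaluations), "models\n")
  cat("  median validation AUROC", round(object@medianValidationAuroc, 3),
      "| median p", signif(object@medianValidationP, 3),
      "| gate", if (object@gatePassed) "passed" else "FAILED", "\n")
  if (object@gatePassed) {
    cat("  best models:", length(object@bestIndices),
        "(AUROC >=", object@bestCutoff, ")",
        "| median test AUROC", round(object@medianTestAuroc, 3),
        "| median test p", signif(object@medianTestP, 3), "\n")
    cat("  discriminant metabolites (VIP >= 1):",
        sum(object@discriminants$discriminant), "\n")
  }
})
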