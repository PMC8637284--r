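#' Run the end-to-end analysis pipeline
#'
#' Orchestrates the full flow on a synthetic or supplied cohort: load or
#' simulate -> quantitation-range QC -> paired-PCA outlier screen (flagged
#' subjects removed) -> split scheme -> combination-ensemble paired PLS-DA
#' -> discriminant (volcano) table -> severity correlations. All stage
#' outputs are written under `outDir` as commented UTF-8 TSV/JSON, together
#' with a run manifest (configuration, package version, seeds, output file
#' checksums). The master seed fans out deterministically to per-stage
#' seeds, so identical configuration and seed give byte-identical outputs.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   `seed` (master seed, required); either `simulate = TRUE` plus optional
#'   `n_subjects`/`effect_size`, or `concentrations` (path), `scores`
#'   (path) and optional `panel` (path); optional ensemble settings
#'   `test_size` (9), `train_size` (20), `stride`, `n_models` (target model
#'   count when `stride` is absent), `n_components` (2), `best_cutoff`
#'   (0.95), `gate_auroc` (0.8), `gate_p` (0.05), `outlier_k` (5).
#' @param outDir Output directory (created if needed).
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
runPipeline <- function(config, outDir, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must provide a master seed")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[exermet] ", ...)
  opt <- function(key, default) if (is.null(config[[key]])) default
                                else config[[key]]
  seed <- as.integer(config$seed)
  stageSeeds <- .subSeeds(seed, 4)

  say("stage 1/5: input")
  if (isTRUE(config$simulate) || is.null(config$concentrations)) {
    cfg <- paperLikeConfig(stageSeeds[1],
                           effectSize = opt("effect_size", 0.6))
    if (!is.null(config$n_subjects)) cfg$nSubjects <-
        as.integer(config$n_subjects)
    cohort <- simulateCohort(cfg)
    dataset <- cohort$dataset; panel <- cohort$panel
    scores <- cohort$scores; truth <- cohort$truth
  } else {
    panel <- if (is.null(config$panel)) buildP180Panel()
             else buildP180Panel(config$panel)
    dataset <- readConcentrationTable(config$concentrations, panel)
    scores <- utils::read.delim(config$scores, comment.char = "#")
    truth <- NULL
  }
  writeConcentrationTable(dataset, file.path(outDir, "concentrations.tsv"))

  say("stage 2/5: quantitation-range QC")
  qc <- quantitationFilter(dataset, panel)
  writeQCReport(qc$report, tsv = file.path(outDir, "qc_report.tsv"),
                json = file.path(outDir, "qc_report.json"))
  ds <- qc$dataset

  say("stage 3/5: paired-PCA outlier screen")
  dec <- pairedWithinMatrix(ds)
  pca <- fitPCA(autoscale(dec$within)$x, nComponents = 2)
  flagged <- flagOutliers(pca, dec$subject, k = opt("outlier_k", 5))
  if (length(flagged)) {
    say("removing outlier subject(s): ", paste(flagged, collapse = ", "))
    ds <- removeSubjects(ds, flagged)
  }

  say("stage 4/5: combination ensemble")
  subj <- unique(subjectIds(ds))
  testSize <- opt("test_size", 9)
  trainSize <- opt("train_size", 20)
  stride <- config$stride
  if (is.null(stride)) {
    total <- countCombinations(length(subj) - testSize, trainSize)
    stride <- max(1, floor(total / opt("n_models", 500)))
  }
  scheme <- makeSplitScheme(subj, testSize = testSize,
                            trainSize = trainSize, stride = stride,
                            seed = stageSeeds[2])
  ens <- runEnsemble(ds, scheme,
                     nComponents = opt("n_components", 2),
                     bestCutoff = opt("best_cutoff", 0.95),
                     gateAuroc = opt("gate_auroc", 0.8),
                     gateP = opt("gate_p", 0.05))
  utils::write.table(ens@evaluations, file.path(outDir, "evaluations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    median_validation_auroc = ens@medianValidationAuroc,
    median_validation_p = ens@medianValidationP,
    gate_passed = ens@gatePassed, n_models = nrow(ens@evaluations),
    n_best = length(ens@bestIndices),
    median_test_auroc = ens@medianTestAuroc,
    median_test_p = ens@medianTestP),
    file.path(outDir, "ensemble_medians.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  if (ens@gatePassed) {
    utils::write.table(ens@discriminants, file.path(outDir, "volcano.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample = rownames(ens@sampleScores), ens@sampleScores),
      file.path(outDir, "sample_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  say("stage 5/5: severity correlations")
  deltas <- exerciseDelta(ds, panel = panel)
  corr <- correlationTable(deltas, scores)
  writeCorrelationTable(corr, file.path(outDir, "correlations.tsv"),
                        file.path(outDir, "correlations_significant.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("exermet")),
    config = config[setdiff(names(config), "panel_object")],
    master_seed = seed, stage_seeds = stageSeeds,
    removed_outliers = flagged,
    outputs = as.list(tools::md5sum(setdiff(
      list.files(outDir, full.names = TRUE, pattern = "\\.(tsv|json)$"),
      file.path(outDir, "manifest.json")))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(dataset = ds, qc = qc, pca = pca, outliers = flagged,
                 scheme = scheme, ensemble = ens, correlations = corr,
                 truth = truth, manifest = manifest))
}
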