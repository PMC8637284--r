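#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

.P180_CLASSES <- c("free_carnitine", "acylcarnitine", "amino_acid",
                   "biogenic_amine", "hexose", "lysoPC", "PC_aa", "PC_ae", "SM")
.LIPID_CLASSES <- c("lysoPC", "PC_aa", "PC_ae", "SM")

#' MetabolitePanel: registry of targeted-panel analyte descriptors
#'
#' Holds one descriptor per analyte of a targeted metabolomics panel:
#' analyte identifier, metabolite class, the lipid chain annotation (total
#' acyl carbons and double bonds, for lipid classes only) and the lower/upper
#' limits of quantitation (LLOQ/ULOQ, in the concentration unit of the data,
#' conventionally uM).
#'
#' @slot descriptors A [S4Vectors::DataFrame] with columns `analyte_id`,
#'   `metabolite_class`, `total_carbons`, `double_bonds`, `lloq`, `uloq`.
#' @seealso [buildP180Panel()]
#' @exportClass MetabolitePanel
setClass("MetabolitePanel", slots = c(descriptors = "DataFrame"))

setValidity("MetabolitePanel", function(object) {
  d <- object@descriptors
  need <- c("analyte_id", "metabolite_class", "total_carbons",
            "double_bonds", "lloq", "uloq")
  if (!all(need %in% colnames(d)))
    return(paste("descriptors must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(d$analyte_id)) return("duplicated analyte_id")
  if (!all(d$metabolite_class %in% .P180_CLASSES))
    return("unknown metabolite_class")
  if (any(d$lloq <= 0)) return("lloq must be > 0")
  if (any(d$uloq <= d$lloq)) return("uloq must be > lloq")
  is_lipid <- d$metabolite_class %in% .LIPID_CLASSES
  if (any(is_lipid & (is.na(d$total_carbons) | is.na(d$double_bonds))))
    return("lipid analytes must carry a chain annotation")
  if (any(!is_lipid & (!is.na(d$total_carbons) | !is.na(d$double_bonds))))
    return("non-lipid analytes must not carry a chain annotation")
  if (any(d$double_bonds < 0, na.rm = TRUE)) return("double_bonds must be >= 0")
  TRUE
})

#' PairedMetabolome: subject-paired rest/post-exercise concentration data
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding a
#' metabolite x sample concentration matrix (assay `"concentration"`, uM)
#' together with an in/below/above-quantitation-range flag matrix (assay
#' `"rangeFlag"`: -1 below LLOQ, 0 in range, +1 above ULOQ). `colData` must
#' carry `subject_id` and `condition` (`"rest"` or `"post"`); every subject
#' contributes exactly one rest and one post sample. Panel descriptors live
#' in `rowData`; QC state is recorded in `metadata(x)$qc`.
#'
#' @exportClass PairedMetabolome
setClass("PairedMetabolome", contains = "SummarizedExperiment")

setValidity("PairedMetabolome", function(object) {
  if (ncol(object) == 0L) return(TRUE)
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("subject_id", "condition") %in% colnames(cd)))
    return("colData must have subject_id and condition")
  if (!all(cd$condition %in% c("rest", "post")))
    return("condition must be 'rest' or 'post'")
  if (!"concentration" %in% SummarizedExperiment::assayNames(object))
    return("assay 'concentration' is required")
  tab <- table(cd$subject_id, factor(cd$condition, c("rest", "post")))
  if (!all(tab == 1L))
    return(paste("unpaired subjects:",
                 paste(rownames(tab)[rowSums(tab != 1L) > 0], collapse = ", ")))
  TRUE
})

#' QCReport: quantitation-range filtering report
#'
#' One row per panel metabolite: fraction of values outside the quantitation
#' range, the filtering decision, the chi-squared test of independence between
#' in/out-of-range status and the rest/post condition (computed only when the
#' out-of-range fraction lies strictly between 20% and 40%), and the number of
#' out-of-range values clamped in retained metabolites.
#'
#' @slot table A [S4Vectors::DataFrame], one row per metabolite.
#' @slot nSamples Number of samples the fractions refer to.
#' @exportClass QCReport
setClass("QCReport", slots = c(table = "DataFrame", nSamples = "integer"))

setValidity("QCReport", function(object) {
  t <- object@table
  need <- c("analyte_id", "fraction_out", "decision", "chi2_statistic",
            "chi2_p", "n_clamped")
  if (!all(need %in% colnames(t)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  ok_dec <- c("retained_leq20", "removed_20to40", "removed_gt40", "retained")
  if (!all(t$decision %in% ok_dec)) return("unknown decision code")
  bad <- (t$fraction_out >= 0.40) != (t$decision == "removed_gt40")
  if (any(bad)) return("decision 'removed_gt40' must align with fraction >= 0.40")
  mid <- t$fraction_out > 0.20 & t$fraction_out < 0.40
  if (any(mid & is.na(t$chi2_statistic)))
    return("chi2 must be recorded for fractions in (0.2, 0.4)")
  if (any(!mid & !is.na(t$chi2_statistic)))
    return("chi2 must be absent outside (0.2, 0.4)")
  TRUE
})

#' TcPO2Recording: multi-probe transcutaneous oximetry recording
#'
#' Time series of transcutaneous oxygen pressure (TcPO2, mmHg) from up to
#' eight heated skin probes (two chest reference sites, and
#' buttock/thigh/calf on each side) recorded over a standing rest phase, a
#' treadmill exercise phase and a standing recovery phase.
#'
#' @slot time Numeric vector, seconds from recording start.
#' @slot pressures Numeric matrix, `length(time)` x probes; columns named by
#'   canonical site (`chest_left`, `chest_right`, `buttock_left`,
#'   `buttock_right`, `thigh_left`, `thigh_right`, `calf_left`, `calf_right`).
#' @slot phases Named numeric vector with `rest_start`, `exercise_start`,
#'   `exercise_end`, `recovery_end` (seconds).
#' @slot probeStatus Named logical vector, `TRUE` for a valid probe.
#' @exportClass TcPO2Recording
setClass("TcPO2Recording",
         slots = c(time = "numeric", pressures = "matrix",
                   phases = "numeric", probeStatus = "logical"))

.TCPO2_SITES <- c("chest_left", "chest_right", "buttock_left", "buttock_right",
                  "thigh_left", "thigh_right", "calf_left", "calf_right")
.LIMB_SITES <- setdiff(.TCPO2_SITES, c("chest_left", "chest_right"))

setValidity("TcPO2Recording", function(object) {
  if (length(object@time) != nrow(object@pressures))
    return("time and pressures disagree in length")
  if (is.unsorted(object@time, strictly = TRUE))
    return("time must be strictly increasing")
  if (!all(colnames(object@pressures) %in% .TCPO2_SITES))
    return(paste("unknown probe site; allowed:",
                 paste(.TCPO2_SITES, collapse = ", ")))
  ph <- object@phases
  need <- c("rest_start", "exercise_start", "exercise_end", "recovery_end")
  if (!all(need %in% names(ph))) return("phases must name all four marks")
  if (!(ph["rest_start"] < ph["exercise_start"] &&
        ph["exercise_start"] < ph["exercise_end"] &&
        ph["exercise_end"] < ph["recovery_end"]))
    return("phase marks must be ordered rest < exercise < recovery")
  if (!setequal(names(object@probeStatus), colnames(object@pressures)))
    return("probeStatus must name every probe")
  chest <- intersect(c("chest_left", "chest_right"), colnames(object@pressures))
  if (length(chest) == 0L) return("at least one chest probe is required")
  TRUE
})

#' DropSummary: per-recording DROP indices and ischemia classification
#'
#' DROP (decrease from rest of oxygen pressure) is the limb TcPO2 change from
#' its rest baseline minus the chest reference change. Per limb probe the
#' minimal (most negative) DROP over the analysis window is kept; ischemia is
#' a minimal DROP below -15 mmHg, systemic hypoxemia a chest decrease above
#' 5 mmHg, and the severity index is the summed magnitude of the six limb
#' minimal DROPs.
#'
#' @slot minimalDrops Named numeric, minimal DROP (mmHg) per limb probe.
#' @slot ischemia Named logical, per limb probe.
#' @slot chestDecrease Chest TcPO2 decrease from rest during exercise (mmHg).
#' @slot hypoxemia Logical flag.
#' @slot severityIndex Non-negative summed DROP magnitude (mmHg).
#' @slot referenceProbe Chest site used as reference.
#' @exportClass DropSummary
setClass("DropSummary",
         slots = c(minimalDrops = "numeric", ischemia = "logical",
                   chestDecrease = "numeric", hypoxemia = "logical",
                   severityIndex = "numeric", referenceProbe = "character"))

#' PcaResult: principal component analysis result
#'
#' @slot scores Sample x component score matrix.
#' @slot loadings Variable x component loading matrix.
#' @slot explainedVariance Fraction of total variance per component
#'   (non-increasing, each in `[0, 1]`, summing to at most 1).
#' @exportClass PcaResult
setClass("PcaResult",
         slots = c(scores = "matrix", loadings = "matrix",
                   explainedVariance = "numeric"))

setValidity("PcaResult", function(object) {
  ev <- object@explainedVariance
  if (any(ev < -1e-12 | ev > 1 + 1e-12)) return("explained fractions outside [0,1]")
  if (sum(ev) > 1 + 1e-8) return("explained fractions sum above 1")
  if (is.unsorted(rev(ev), strictly = FALSE) && any(diff(ev) > 1e-12))
    return("explained fractions must be non-increasing")
  TRUE
})

#' PlsdaModel: NIPALS PLS-DA model (PLS1 on a binary class vector)
#'
#' @slot weights Variable x component weight matrix W (columns unit norm).
#' @slot scores Training sample x component score matrix T.
#' @slot xLoadings Variable x component X-loading matrix P.
#' @slot yLoadings Per-component Y-loading q.
#' @slot center,scale Column scaling parameters learned on the training data.
#' @slot yMean Mean of the centered 0/1 class vector.
#' @slot nComponents Number of extracted components.
#' @slot columnIds Training column (variable) identifiers.
#' @exportClass PlsdaModel
setClass("PlsdaModel",
         slots = c(weights = "matrix", scores = "matrix", xLoadings = "matrix",
                   yLoadings = "numeric", center = "numeric", scale = "numeric",
                   yMean = "numeric", nComponents = "integer",
                   columnIds = "character"))

setValidity("PlsdaModel", function(object) {
  A <- object@nComponents
  if (ncol(object@weights) != A || ncol(object@scores) != A ||
      ncol(object@xLoadings) != A || length(object@yLoadings) != A)
    return("component dimensions disagree")
  if (A >= 2L) {
    G <- crossprod(object@scores)
    off <- G[upper.tri(G)]
    if (any(abs(off) > 1e-6 * max(diag(G))))
      return("score vectors must be mutually orthogonal")
  }
  TRUE
})

#' SplitScheme: subject allocation for the combination ensemble
#'
#' One test set of subjects drawn once; the remaining pool is repeatedly
#' split into training and validation subjects by enumerating k-subsets of
#' the pool in lexicographic order and sampling every `stride`-th combination
#' (the columns of the full combination matrix C are never materialised).
#' Subjects, not samples, are allocated, so both members of each rest/post
#' pair travel together.
#'
#' @slot subjects All subject ids.
#' @slot testSubjects Held-out test subjects.
#' @slot poolSubjects Training-validation pool.
#' @slot trainSize Subjects per training set.
#' @slot stride Sampling stride through the lexicographic combinations.
#' @slot combinationIndices 1-based indices of the sampled combinations.
#' @slot seed Seed used to draw the test split.
#' @exportClass SplitScheme
setClass("SplitScheme",
         slots = c(subjects = "character", testSubjects = "character",
                   poolSubjects = "character", trainSize = "integer",
                   stride = "integer", combinationIndices = "numeric",
                   seed = "integer"))

setValidity("SplitScheme", function(object) {
  if (length(intersect(object@testSubjects, object@poolSubjects)) > 0L)
    return("test and pool subjects must be disjoint")
  if (!setequal(object@subjects,
                c(object@testSubjects, object@poolSubjects)))
    return("subjects must be the union of test and pool")
  if (object@trainSize < 1L || object@trainSize >= length(object@poolSubjects))
    return("trainSize must leave a non-empty validation set")
  total <- countCombinations(length(object@poolSubjects), object@trainSize)
  if (any(object@combinationIndices < 1 | object@combinationIndices > total))
    return("combination indices out of range")
  TRUE
})

#' EnsembleResult: per-model evaluations and aggregated discriminant summary
#'
#' @slot evaluations data.frame: combination index, validation AUROC, p-value.
#' @slot medianValidationAuroc,medianValidationP Medians over all models.
#' @slot gatePassed Whether the global-performance gate (median AUROC >= 0.8
#'   and median p <= 0.05) was satisfied.
#' @slot bestIndices Combination indices of the best models.
#' @slot bestCutoff AUROC cutoff used for the best-model set.
#' @slot medianTestAuroc,medianTestP Medians of the best models on the test set.
#' @slot vipMedian,loadingMedian Per-metabolite medians across best models.
#' @slot sampleScores Per-sample median latent-variable scores (LV1, LV2).
#' @slot discriminants data.frame: metabolite, median VIP, median loading,
#'   discriminant flag (VIP >= 1) and direction (sign of median loading).
#' @exportClass EnsembleResult
setClass("EnsembleResult",
         slots = c(evaluations = "data.frame",
                   medianValidationAuroc = "numeric",
                   medianValidationP = "numeric",
                   gatePassed = "logical",
                   bestIndices = "numeric", bestCutoff = "numeric",
                   medianTestAuroc = "numeric", medianTestP = "numeric",
                   vipMedian = "numeric", loadingMedian = "numeric",
                   sampleScores = "matrix", discriminants = "data.frame"))
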