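#' Construct a PairedMetabolome from a concentration matrix
#'
#' @param concentration Metabolite x sample numeric matrix (uM), analyte ids
#'   as rownames.
#' @param subjectId Character vector, one entry per sample (column).
#' @param condition Character vector, `"rest"` or `"post"` per sample.
#' @param panel Optional [MetabolitePanel-class]; its descriptors (subset to
#'   the rows present) populate `rowData` and provide quantitation limits.
#' @param rangeFlag Optional metabolite x sample integer matrix (-1 below
#'   LLOQ, 0 in range, +1 above ULOQ). Derived from the panel limits when
#'   omitted and a panel is given.
#' @return A [PairedMetabolome-class].
#' @export
PairedMetabolome <- function(concentration, subjectId, condition,
                             panel = NULL, rangeFlag = NULL) {
  stopifnot(is.matrix(concentration),
            length(subjectId) == ncol(concentration),
            length(condition) == ncol(concentration))
  if (is.null(colnames(concentration)) && ncol(concentration) > 0)
    colnames(concentration) <- paste0(subjectId, "_", condition)
  rd <- NULL
  if (!is.null(panel)) {
    rd <- panelDescriptors(subsetPanel(panel, rownames(concentration)))
    if (is.null(rangeFlag))
      rangeFlag <- deriveRangeFlags(concentration, rd$lloq, rd$uloq)
  }
  if (is.null(rangeFlag))
    rangeFlag <- matrix(0L, nrow(concentration), ncol(concentration),
                        dimnames = dimnames(concentration))
  dimnames(rangeFlag) <- dimnames(concentration)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(concentration = concentration, rangeFlag = rangeFlag),
    colData = S4Vectors::DataFrame(subject_id = as.character(subjectId),
                                   condition = as.character(condition),
                                   row.names = colnames(concentration)))
  if (!is.null(rd)) SummarizedExperiment::rowData(se) <- rd
  methods::new("PairedMetabolome", se)
}

deriveRangeFlags <- function(concentration, lloq, uloq) {
  f <- matrix(0L, nrow(concentration), ncol(concentration))
  f[concentration < lloq] <- -1L
  f[concentration > uloq] <- 1L
  dimnames(f) <- dimnames(concentration)
  f
}

#' Read a MetIDQ-style concentration export
#'
#' Expects delimited text with one row per sample, columns `subject_id`,
#' `condition` (`rest`/`post`) and one column per analyte (uM). Out-of-range
#' values may be encoded as `"<LLOQ"` / `">ULOQ"` tokens, which are replaced
#' by the panel limit and flagged below/above range.
#'
#' @param file Path to the delimited file.
#' @param panel A [MetabolitePanel-class] providing analytes and limits.
#' @param sep Field separator (default tab; use `","` for CSV).
#' @return A [PairedMetabolome-class].
#' @export
readConcentrationTable <- function(file, panel = buildP180Panel(), sep = "\t") {
  raw <- utils::read.table(file, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("subject_id", "condition")
  if (!all(need %in% colnames(raw)))
    stop("missing columns: ", paste(setdiff(need, colnames(raw)), collapse = ", "))
  analytes <- setdiff(colnames(raw), need)
  d <- panelDescriptors(subsetPanel(panel, analytes))
  conc <- matrix(NA_real_, length(analytes), nrow(raw),
                 dimnames = list(analytes, NULL))
  flag <- matrix(0L, length(analytes), nrow(raw),
                 dimnames = list(analytes, NULL))
  for (j in seq_along(analytes)) {
    v <- as.character(raw[[analytes[j]]])
    below <- v == "<LLOQ"
    above <- v == ">ULOQ"
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num) & !below & !above))
      stop("non-numeric value in column '", analytes[j], "', row ",
           which(is.na(num) & !below & !above)[1])
    num[below] <- d$lloq[j]
    num[above] <- d$uloq[j]
    conc[j, ] <- num
    flag[j, below] <- -1L
    flag[j, above] <- 1L
    flag[j, !below & !above] <-
      deriveRangeFlags(matrix(num[!below & !above], 1), d$lloq[j], d$uloq[j])
  }
  PairedMetabolome(conc, raw$subject_id, raw$condition,
                   panel = panel, rangeFlag = flag)
}

#' @describeIn PairedMetabolome-class Subject id per sample.
#' @param x A [PairedMetabolome-class].
#' @export
subjectIds <- function(x) SummarizedExperiment::colData(x)$subject_id

#' @describeIn PairedMetabolome-class Condition (`rest`/`post`) per sample.
#' @export
sampleConditions <- function(x) SummarizedExperiment::colData(x)$condition

#' @describeIn PairedMetabolome-class Concentration matrix (metabolite x sample).
#' @export
concentrations <- function(x) SummarizedExperiment::assay(x, "concentration")

#' @describeIn PairedMetabolome-class Quantitation-range flag matrix.
#' @export
rangeFlags <- function(x) SummarizedExperiment::assay(x, "rangeFlag")

#' Write a PairedMetabolome as a sample x analyte delimited table
#' @param x A [PairedMetabolome-class].
#' @param file Output path.
#' @param sep Field separator.
#' @export
writeConcentrationTable <- function(x, file, sep = "\t") {
  out <- data.frame(subject_id = subjectIds(x),
                    condition = sampleConditions(x),
                    t(concentrations(x)), check.names = FALSE)
  utils::write.table(out, file, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(file)
}
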