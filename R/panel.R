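#' Build the AbsoluteIDQ p180 panel registry
#'
#' Loads the 188-analyte targeted panel: free carnitine (C0), 39
#' acylcarnitines, the hexose sum (H1), 21 amino acids, 21 biogenic amines
#' and 105 lipids (14 lysoPC, 38 PC aa, 38 PC ae, 15 SM). Lipid chain
#' annotations (total carbons, double bonds) are parsed from the analyte
#' names. The shipped quantitation limits are order-of-magnitude, per-class
#' placeholders, not kit calibration values; supply real limits via
#' `lloq`/`uloq` or a custom `file` when available.
#'
#' @param file Path to a panel definition TSV with columns `analyte_id`,
#'   `metabolite_class`, `lloq`, `uloq`. Defaults to the packaged p180 list.
#' @param lloq,uloq Optional named numeric vectors overriding limits for
#'   selected analytes.
#' @return A [MetabolitePanel-class] object.
#' @examples
#' panel <- buildP180Panel()
#' nrow(panelDescriptors(panel))  # 188
#' @export
buildP180Panel <- function(file = system.file("extdata", "p180_panel.tsv",
                                              package = "exermet"),
                           lloq = NULL, uloq = NULL) {
  d <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  ann <- lapply(d$analyte_id, function(id) {
    if (grepl("^(lysoPC a|PC a[ae]|SM) ", id) || grepl("^SM \\(OH\\) ", id))
      parseLipidName(id)
    else
      list(class = NA_character_, total_carbons = NA_integer_,
           double_bonds = NA_integer_)
  })
  desc <- S4Vectors::DataFrame(
    analyte_id = d$analyte_id,
    metabolite_class = d$metabolite_class,
    total_carbons = vapply(ann, function(a) as.integer(a$total_carbons), 1L),
    double_bonds = vapply(ann, function(a) as.integer(a$double_bonds), 1L),
    lloq = d$lloq, uloq = d$uloq)
  rownames(desc) <- desc$analyte_id
  if (!is.null(lloq)) desc[names(lloq), "lloq"] <- unname(lloq)
  if (!is.null(uloq)) desc[names(uloq), "uloq"] <- unname(uloq)
  methods::new("MetabolitePanel", descriptors = desc)
}

#' Parse a p180 lipid analyte name
#'
#' Lipid species are named `"<class> Cn:m"` where `n` is the summed length of
#' the acyl / acyl-alkyl chains and `m` the number of double bonds, e.g.
#' `"PC aa C42:6"`, `"lysoPC a C18:1"`, `"SM (OH) C14:1"`.
#'
#' @param name Analyte name string.
#' @return A list with `class` (one of `lysoPC`, `PC_aa`, `PC_ae`, `SM`),
#'   `total_carbons` and `double_bonds`.
#' @examples
#' parseLipidName("PC aa C42:6")
#' @export
parseLipidName <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- regmatches(name, regexec(
    "^(lysoPC a|PC aa|PC ae|SM \\(OH\\)|SM) C([0-9]+):([0-9]+)$", name))[[1]]
  if (length(m) == 0L)
    stop("unparseable lipid name: '", name, "'")
  cls <- switch(m[2], "lysoPC a" = "lysoPC", "PC aa" = "PC_aa",
                "PC ae" = "PC_ae", "SM (OH)" = "SM", "SM" = "SM")
  list(class = cls, total_carbons = as.integer(m[3]),
       double_bonds = as.integer(m[4]))
}

#' Accessor for the descriptor table of a panel
#' @param panel A [MetabolitePanel-class].
#' @return The descriptor [S4Vectors::DataFrame].
#' @export
panelDescriptors <- function(panel) {
  stopifnot(methods::is(panel, "MetabolitePanel"))
  panel@descriptors
}

#' Subset a panel to a set of analytes
#' @param panel A [MetabolitePanel-class].
#' @param ids Analyte identifiers to keep (order preserved).
#' @return A [MetabolitePanel-class] restricted to `ids`.
#' @export
subsetPanel <- function(panel, ids) {
  d <- panelDescriptors(panel)
  missing <- setdiff(ids, d$analyte_id)
  if (length(missing))
    stop("analytes absent from panel: ", paste(missing, collapse = ", "))
  methods::new("MetabolitePanel", descriptors = d[match(ids, d$analyte_id), ])
}

#' Per-sample indicator ratios of a concentration profile
#'
#' Computes the three ratio indicators used alongside single metabolites:
#' kynurenine / tryptophan, SDMA / arginine, and MUFA(PC) / SFA(PC), where
#' SFA(PC) sums all PC (aa + ae) species with 0 double bonds and MUFA(PC)
#' all PC species with exactly 1 double bond (species-level saturation on
#' the summed-chain annotation). A zero or absent denominator yields `NA`
#' for that ratio, not an error.
#'
#' @param x A [PairedMetabolome-class] or a metabolite x sample numeric
#'   matrix with analyte ids as rownames.
#' @param panel A [MetabolitePanel-class] describing the analytes.
#' @return A 3 x sample matrix with rows `Kynurenine/Trp`, `SDMA/Arg`,
#'   `MUFA (PC)/SFA (PC)`.
#' @export
computeIndicatorRatios <- function(x, panel = buildP180Panel()) {
  conc <- if (methods::is(x, "PairedMetabolome"))
    SummarizedExperiment::assay(x, "concentration") else x
  stopifnot(is.matrix(conc), !is.null(rownames(conc)))
  d <- panelDescriptors(panel)
  one <- function(id) {
    if (id %in% rownames(conc)) conc[id, ] else
      rep(NA_real_, ncol(conc))
  }
  safe_div <- function(num, den) {
    r <- num / den
    r[!is.finite(r)] <- NA_real_
    r
  }
  pc <- d$metabolite_class %in% c("PC_aa", "PC_ae") &
    d$analyte_id %in% rownames(conc)
  sfa_ids <- d$analyte_id[pc & d$double_bonds == 0L]
  mufa_ids <- d$analyte_id[pc & d$double_bonds == 1L]
  col_sum <- function(ids) {
    if (length(ids) == 0L) rep(0, ncol(conc))
    else colSums(conc[ids, , drop = FALSE])
  }
  out <- rbind(
    "Kynurenine/Trp" = safe_div(one("Kynurenine"), one("Trp")),
    "SDMA/Arg" = safe_div(one("SDMA"), one("Arg")),
    "MUFA (PC)/SFA (PC)" = safe_div(col_sum(mufa_ids), col_sum(sfa_ids)))
  colnames(out) <- colnames(conc)
  out
}
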