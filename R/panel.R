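#' SMN-region labels
#'
#' The target-region vocabulary shared by every stage of the pipeline.
#' Gene-specific regions are interrogated by probes that discriminate the
#' single-base differences between \emph{SMN1} and \emph{SMN2} (exon 7 and
#' exon 8) or target a unique neighboring gene; combined regions are
#' interrogated by probes hybridizing identically to both genes and report
#' only the summed copy number. Labels are abstract: the SMN region has no
#' complete physical map, so no coordinates are attached.
#'
#' @return character vector of the 12 SMN-region labels, in the assumed
#'   chromosomal order (Ensembl-derived).
#' @export
#' @examples
#' smnRegions()
smnRegions <- function() {
  c("RAD17", "SERF1B", "SMN12_e1", "SMN12_e4", "SMN12_e6",
    "SMN1_e7", "SMN1_e8", "SMN2_e7", "SMN2_e8",
    "NAIP_e5", "NAIPc_e13", "GTF2H2_e5")
}

#' @rdname smnRegions
#' @export
combinedRegions <- function() {
  c("SMN12_e1", "SMN12_e4", "SMN12_e6", "NAIPc_e13", "GTF2H2_e5")
}

#' @rdname smnRegions
#' @export
geneSpecificRegions <- function() {
  setdiff(smnRegions(), combinedRegions())
}

# Builds the bundled P021 probe table: 46 probes = 7 dq_control + 2 sex +
# 22 reference + 15 smn_target. Combined regions SMN12_e1, NAIPc_e13 and
# GTF2H2_e5 carry two probes each (the published kit description gives probe
# counts, not a per-probe region breakdown).
.p021ProbeTable <- function() {
  smn <- data.frame(
    probe_id = c("SMN1_e7_p1", "SMN1_e8_p1", "SMN2_e7_p1", "SMN2_e8_p1",
                 "SMN12_e1_p1", "SMN12_e1_p2", "SMN12_e4_p1", "SMN12_e6_p1",
                 "NAIP_e5_p1", "NAIPc_e13_p1", "NAIPc_e13_p2",
                 "GTF2H2_e5_p1", "GTF2H2_e5_p2", "SERF1B_p1", "RAD17_p1"),
    region = c("SMN1_e7", "SMN1_e8", "SMN2_e7", "SMN2_e8",
               "SMN12_e1", "SMN12_e1", "SMN12_e4", "SMN12_e6",
               "NAIP_e5", "NAIPc_e13", "NAIPc_e13",
               "GTF2H2_e5", "GTF2H2_e5", "SERF1B", "RAD17"),
    category = "smn_target", stringsAsFactors = FALSE)
  smn$specificity <- ifelse(smn$region %in% combinedRegions(),
                            "combined", "gene_specific")
  smn$expected_diploid_copies <- ifelse(smn$specificity == "combined", 4L, 2L)

  ref <- data.frame(
    probe_id = sprintf("REF_%02d_p1", 1:22),
    region = sprintf("REF_%02d", 1:22),
    category = "reference", specificity = "gene_specific",
    expected_diploid_copies = 2L, stringsAsFactors = FALSE)

  sex <- data.frame(
    probe_id = c("SEX_X_p1", "SEX_Y_p1"), region = c("SEX_X", "SEX_Y"),
    category = "sex", specificity = "gene_specific",
    expected_diploid_copies = 2L, stringsAsFactors = FALSE)

  ctl <- data.frame(
    probe_id = c("QFRAG_1_p1", "QFRAG_1_p2", "QFRAG_2_p1", "QFRAG_3_p1",
                 "QFRAG_4_p1", "DFRAG_1_p1", "DFRAG_2_p1"),
    region = c("QFRAG_1", "QFRAG_1", "QFRAG_2", "QFRAG_3", "QFRAG_4",
               "DFRAG_1", "DFRAG_2"),
    category = "dq_control", specificity = "gene_specific",
    expected_diploid_copies = 2L, stringsAsFactors = FALSE)

  rbind(ctl, sex, ref, smn)
}

#' Load an MLPA probe panel
#'
#' Loads either the bundled \code{"P021"} probe-mix definition (46 probes:
#' 7 dosage-quality control, 2 sex, 22 autosomal reference, 15 SMN-region
#' targets) or a custom panel descriptor written in YAML.
#'
#' @param source either a builtin panel name (currently \code{"P021"}) or a
#'   path to a YAML panel descriptor (see \code{\link{writePanelDescriptor}}).
#' @return a validated \linkS4class{ProbePanel}.
#' @export
#' @examples
#' p <- loadPanel("P021")
#' p
loadPanel <- function(source) {
  stopifnot(is.character(source), length(source) == 1)
  if (file.exists(source)) return(readPanelDescriptor(source))
  if (source == "P021") {
    path <- system.file("extdata", "panels", "P021.yaml", package = "SMNcnv")
    if (nzchar(path)) return(readPanelDescriptor(path))
    # fall back to the in-code definition (pre-installation contexts)
    return(new("ProbePanel", name = "P021", version = "1.0",
               probes = .p021ProbeTable(), regionOrder = smnRegions()))
  }
  stop("unknown builtin panel name: '", source, "'")
}

#' Validate a probe panel
#'
#' Diagnostic check of the panel invariants: unique probe ids, recognised
#' categories/specificities, reference probes gene-specific with expected
#' diploid dose 2, combined probes with expected dose 4, SMN-target probes
#' confined to the SMN-region vocabulary, and at least one reference probe
#' (normalization is impossible without one).
#'
#' @param panel a \linkS4class{ProbePanel}.
#' @return character vector of violation descriptions; empty when the panel
#'   is valid.
#' @export
validatePanel <- function(panel) {
  p <- panel@probes
  v <- character()
  need <- c("probe_id", "region", "category", "specificity",
            "expected_diploid_copies")
  miss <- setdiff(need, names(p))
  if (length(miss))
    return(paste("probe table lacks column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(p$probe_id))
    v <- c(v, paste("duplicate probe_id:",
                    paste(unique(p$probe_id[duplicated(p$probe_id)]),
                          collapse = ", ")))
  badcat <- !p$category %in% c("dq_control", "sex", "reference", "smn_target")
  if (any(badcat))
    v <- c(v, paste0(p$probe_id[badcat], ": unknown category '",
                     p$category[badcat], "'"))
  badspec <- !p$specificity %in% c("gene_specific", "combined")
  if (any(badspec))
    v <- c(v, paste0(p$probe_id[badspec], ": unknown specificity"))
  bad <- p$category == "reference" &
    (p$specificity != "gene_specific" | p$expected_diploid_copies != 2)
  if (any(bad))
    v <- c(v, paste0(p$probe_id[bad],
                     ": reference probes must be gene_specific with expected",
                     " diploid copies 2"))
  bad <- p$specificity == "combined" & p$expected_diploid_copies != 4
  if (any(bad))
    v <- c(v, paste0(p$probe_id[bad],
                     ": combined probes must have expected diploid copies 4"))
  bad <- p$specificity == "gene_specific" & p$expected_diploid_copies != 2
  if (any(bad))
    v <- c(v, paste0(p$probe_id[bad],
                     ": gene_specific probes must have expected diploid",
                     " copies 2"))
  bad <- p$category == "smn_target" & !p$region %in% smnRegions()
  if (any(bad))
    v <- c(v, paste0(p$probe_id[bad], ": smn_target region '",
                     p$region[bad], "' is not an SMN-region label"))
  bad <- p$category == "smn_target" &
    (p$region %in% combinedRegions()) != (p$specificity == "combined")
  if (any(bad))
    v <- c(v, paste0(p$probe_id[bad],
                     ": specificity inconsistent with region class"))
  if (!any(p$category == "reference")) v <- c(v, "no reference probes")
  v
}

#' Read / write panel descriptors
#'
#' Panels round-trip through a YAML descriptor holding the panel name,
#' version, region order and one record per probe.
#'
#' @param panel a \linkS4class{ProbePanel}.
#' @param path file path of the YAML descriptor.
#' @return \code{readPanelDescriptor} returns a validated
#'   \linkS4class{ProbePanel}; \code{writePanelDescriptor} returns
#'   \code{path} invisibly.
#' @export
writePanelDescriptor <- function(panel, path) {
  doc <- list(
    name = panel@name, version = panel@version,
    region_order = as.list(panel@regionOrder),
    probes = lapply(seq_len(nrow(panel@probes)), function(i)
      as.list(panel@probes[i, , drop = FALSE])))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname writePanelDescriptor
#' @export
readPanelDescriptor <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("malformed panel descriptor: ",
                                           conditionMessage(e)))
  for (fld in c("name", "probes"))
    if (is.null(doc[[fld]]))
      stop("panel descriptor lacks required field '", fld, "'")
  rows <- lapply(doc$probes, function(pr) {
    for (fld in c("probe_id", "region", "category", "specificity",
                  "expected_diploid_copies"))
      if (is.null(pr[[fld]]))
        stop("panel descriptor probe record lacks field '", fld, "'")
    data.frame(probe_id = pr$probe_id, region = pr$region,
               category = pr$category, specificity = pr$specificity,
               expected_diploid_copies = as.integer(pr$expected_diploid_copies),
               stringsAsFactors = FALSE)
  })
  probes <- do.call(rbind, rows)
  panel <- new("ProbePanel",
               name = doc$name,
               version = if (is.null(doc$version)) "" else doc$version,
               probes = probes,
               regionOrder = if (is.null(doc$region_order)) smnRegions()
                             else unlist(doc$region_order))
  v <- validatePanel(panel)
  if (length(v)) stop("invalid panel descriptor: ", paste(v, collapse = "; "))
  panel
}

#' Panel accessors
#'
#' @param panel a \linkS4class{ProbePanel}.
#' @return \code{probes} returns the probe \code{data.frame};
#'   \code{panelName} the panel name; \code{regionOrder} the assumed
#'   SMN-region order; \code{targetProbes} the SMN-target subset;
#'   \code{referenceProbes} the reference-probe ids;
#'   \code{controlFragmentProbes} the dosage-quality control probe ids.
#' @export
probes <- function(panel) panel@probes

#' @rdname probes
#' @export
panelName <- function(panel) panel@name

#' @rdname probes
#' @export
regionOrder <- function(panel) panel@regionOrder

#' @rdname probes
#' @export
targetProbes <- function(panel)
  panel@probes[panel@probes$category == "smn_target", , drop = FALSE]

#' @rdname probes
#' @export
referenceProbes <- function(panel)
  panel@probes$probe_id[panel@probes$category == "reference"]

#' @rdname probes
#' @export
controlFragmentProbes <- function(panel)
  panel@probes$probe_id[panel@probes$category == "dq_control"]
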