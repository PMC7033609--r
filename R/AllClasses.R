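#' @import methods
NULL

#' ProbePanel: an MLPA probe-mix definition
#'
#' Describes one MLPA probe mix: which probes it contains, the region each
#' probe interrogates, the probe category (dosage-quality control fragment,
#' sex-chromosome probe, autosomal reference probe, or SMN-region target) and
#' its specificity. Gene-specific probes hybridize to a single gene copy and
#' have an expected diploid dose of 2; combined probes hybridize identically
#' to \emph{SMN1} and \emph{SMN2} (exons 1, 4, 6 and part of 8) and report the
#' summed dose of both genes, expected diploid dose 4.
#'
#' Region identifiers are abstract labels, not genomic coordinates: the SMN
#' region has no complete, stable physical map, so the panel carries an
#' assumed region order as an attribute (configurable) rather than positions.
#'
#' @slot name panel name, e.g. \code{"P021"}.
#' @slot version free-form version string.
#' @slot probes \code{data.frame} with columns \code{probe_id}, \code{region},
#'   \code{category}, \code{specificity}, \code{expected_diploid_copies}.
#' @slot regionOrder character vector giving the assumed order of SMN-region
#'   labels along the chromosome-5 homolog.
#' @export
setClass("ProbePanel", representation(
  name = "character",
  version = "character",
  probes = "data.frame",
  regionOrder = "character"
))

setValidity("ProbePanel", function(object) {
  v <- validatePanel(object)
  if (length(v)) paste(v, collapse = "; ") else TRUE
})

#' PopulationModel: a population pool of SMN-region haplotypes
#'
#' Holds per-homolog copy-count frequencies for the SMN-region labels together
#' with a per-meiosis de novo event rate. Two parameterizations are supported:
#' \code{"independent"} (a per-region allele copy-count frequency vector; the
#' haplotype distribution is their product, matching the observation that
#' copy numbers of different exons do not correlate fully) and
#' \code{"table"} (an explicit haplotype table with frequencies, for linked
#' configurations).
#'
#' @slot name model name (\code{"black_SA"}, \code{"white_SA"}, or custom).
#' @slot mode \code{"independent"} or \code{"table"}.
#' @slot alleleFreqs named list (one element per region) of probability
#'   vectors over per-homolog copy count 0..k; used when mode is independent.
#' @slot haplotypes integer matrix (haplotype x region); used in table mode.
#' @slot hapFreqs numeric vector of haplotype probabilities (table mode).
#' @slot deNovoRate probability of a de novo event per transmitted haplotype
#'   per meiosis.
#' @export
setClass("PopulationModel", representation(
  name = "character",
  mode = "character",
  alleleFreqs = "list",
  haplotypes = "matrix",
  hapFreqs = "numeric",
  deNovoRate = "numeric"
))

setValidity("PopulationModel", function(object) {
  msg <- character()
  if (!object@mode %in% c("independent", "table"))
    msg <- c(msg, "mode must be 'independent' or 'table'")
  if (object@deNovoRate < 0 || object@deNovoRate > 1)
    msg <- c(msg, "deNovoRate must lie in [0, 1]")
  if (object@mode == "independent") {
    bad <- vapply(object@alleleFreqs, function(f)
      any(f < -1e-12) || abs(sum(f) - 1) > 1e-9, logical(1))
    if (any(bad))
      msg <- c(msg, paste0("allele frequencies of ",
        paste(names(object@alleleFreqs)[bad], collapse = ", "),
        " do not sum to 1"))
  } else {
    if (abs(sum(object@hapFreqs) - 1) > 1e-9)
      msg <- c(msg, "haplotype frequencies do not sum to 1")
    if (nrow(object@haplotypes) != length(object@hapFreqs))
      msg <- c(msg, "haplotype table and frequency vector lengths differ")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' MlpaRun: raw peak signals for one MLPA experiment
#'
#' One batch of capillary-electrophoresis peak signals: a probe x sample
#' matrix of non-negative fluorescence intensities plus a sample manifest
#' flagging external control samples used for inter-sample normalization.
#'
#' @slot panel the \linkS4class{ProbePanel} the signals were measured with.
#' @slot signal numeric matrix, rows = probe_ids, columns = sample_ids.
#' @slot samples \code{data.frame} with columns \code{sample_id},
#'   \code{is_control} and optionally \code{sex}.
#' @export
setClass("MlpaRun", representation(
  panel = "ProbePanel",
  signal = "matrix",
  samples = "data.frame"
))

setValidity("MlpaRun", function(object) {
  msg <- character()
  pid <- object@panel@probes$probe_id
  if (!identical(sort(rownames(object@signal)), sort(pid)))
    msg <- c(msg, "signal rows do not match panel probe_ids")
  if (!identical(colnames(object@signal), object@samples$sample_id))
    msg <- c(msg, "signal columns do not match sample manifest")
  if (any(!is.finite(object@signal)) || any(object@signal < 0))
    msg <- c(msg, "signals must be finite and non-negative")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' DosageSet: normalized dosage quotients plus QC flags
#'
#' Dosage quotients (DQ) after two-stage normalization: probe signals are
#' first ratioed to the median reference-probe signal within each sample,
#' then each ratio is divided by the median of the same ratio across the
#' external control samples. DQ 1.0 corresponds to the reference diploid
#' dose (2 copies for a gene-specific probe, 4 for a combined probe).
#'
#' @slot panel the \linkS4class{ProbePanel} used.
#' @slot dq numeric matrix (non-control-fragment probes x samples).
#' @slot qc \code{data.frame} of per-sample QC flags: \code{dna_quantity_ok},
#'   \code{ligation_ok}, \code{denaturation_ok}, \code{sex_consistent}.
#' @export
setClass("DosageSet", representation(
  panel = "ProbePanel",
  dq = "matrix",
  qc = "data.frame"
))

#' CopyNumberSet: integer copy-number calls per region
#'
#' Integer copy-number calls keyed by region (region x sample matrix), the
#' set of borderline calls (DQ within \code{tol} of a bin boundary), the
#' calling mode used, and per-sample QC carried through from normalization.
#'
#' @slot cn integer matrix, rows = regions, columns = samples.
#' @slot borderline logical matrix, same shape as \code{cn}.
#' @slot qc per-sample QC \code{data.frame} (may be empty for fixture data).
#' @slot mode calling mode, \code{"table1"} or \code{"rounding"}.
#' @slot tol borderline tolerance in DQ units.
#' @export
setClass("CopyNumberSet", representation(
  cn = "matrix",
  borderline = "matrix",
  qc = "data.frame",
  mode = "character",
  tol = "numeric"
))

#' Pedigree: one family with optional simulated truth
#'
#' A single family: member records with parent links, plus (for simulated
#' families) the true per-homolog copy-count configuration of every member
#' and the list of de novo events applied during transmission.
#'
#' @slot familyId family identifier.
#' @slot members \code{data.frame} with columns \code{member_id},
#'   \code{father_id}, \code{mother_id} (\code{NA} for founders), \code{sex}.
#' @slot diplotypes named list; per member a list with elements \code{mat}
#'   and \code{pat}, each a named integer vector over the SMN-region labels.
#'   Empty for real (non-simulated) families.
#' @slot events \code{data.frame} of simulated de novo events with columns
#'   \code{member_id}, \code{parent}, \code{region}, \code{type},
#'   \code{delta}.
#' @export
setClass("Pedigree", representation(
  familyId = "character",
  members = "data.frame",
  diplotypes = "list",
  events = "data.frame"
))

setValidity("Pedigree", function(object) {
  m <- object@members
  msg <- character()
  for (col in c("member_id", "father_id", "mother_id", "sex"))
    if (is.null(m[[col]])) msg <- c(msg, paste("members lacks column", col))
  if (!length(msg)) {
    ids <- m$member_id
    if (anyDuplicated(ids)) msg <- c(msg, "duplicate member_id")
    par <- c(m$father_id, m$mother_id)
    par <- par[!is.na(par)]
    if (!all(par %in% ids))
      msg <- c(msg, "parent reference does not resolve within the family")
    if (!length(msg) && .pedHasCycle(m)) msg <- c(msg, "pedigree contains a cycle")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' PhaseReport: result of phasing one family
#'
#' Per-family phase analysis: feasible parental allele-split assignments per
#' region, the informativeness status, and any minimal de novo event
#' explanations found for discrepant regions.
#'
#' Status is \code{"informative"} when every analyzed region admits exactly
#' one feasible parental split assignment (up to within-parent allele order),
#' \code{"uninformative"} when some region admits several and none admits
#' zero, and \code{"discrepant"} when at least one region admits none under
#' strictly Mendelian transmission.
#'
#' @slot familyId family identifier.
#' @slot status one of \code{"informative"}, \code{"uninformative"},
#'   \code{"discrepant"}.
#' @slot nFeasible named integer vector: feasible assignment count per region.
#' @slot assignments named list: per region, a list of feasible assignments,
#'   each a list with \code{father} and \code{mother} unordered splits.
#' @slot events list of minimal de novo event explanations (possibly empty);
#'   each a \code{data.frame} with columns \code{member_id}, \code{parent},
#'   \code{region}, \code{type}.
#' @slot notes character vector of analyst-facing remarks.
#' @export
setClass("PhaseReport", representation(
  familyId = "character",
  status = "character",
  nFeasible = "integer",
  assignments = "list",
  events = "list",
  notes = "character"
))

# ---- show methods -----------------------------------------------------------

setMethod("show", "ProbePanel", function(object) {
  tab <- table(object@probes$category)
  cat("ProbePanel '", object@name, "' (version ", object@version, "): ",
      nrow(object@probes), " probes\n  ", sep = "")
  cat(paste(names(tab), as.integer(tab), sep = "="), sep = ", ")
  cat("\n")
})

setMethod("show", "PopulationModel", function(object) {
  cat("PopulationModel '", object@name, "' [", object@mode, "], de novo rate ",
      object@deNovoRate, "\n", sep = "")
  if (object@mode == "independent")
    cat("  regions:", paste(names(object@alleleFreqs), collapse = ", "), "\n")
  else
    cat("  ", nrow(object@haplotypes), "explicit haplotypes\n")
})

setMethod("show", "MlpaRun", function(object) {
  cat("MlpaRun:", ncol(object@signal), "samples (",
      sum(object@samples$is_control), "controls ) x",
      nrow(object@signal), "probes [panel", object@panel@name, "]\n")
})

setMethod("show", "DosageSet", function(object) {
  cat("DosageSet:", ncol(object@dq), "samples x", nrow(object@dq), "probes\n")
})

setMethod("show", "CopyNumberSet", function(object) {
  cat("CopyNumberSet:", ncol(object@cn), "samples x", nrow(object@cn),
      "regions; mode =", object@mode, ", tol =", object@tol, "\n")
})

setMethod("show", "Pedigree", function(object) {
  nf <- sum(is.na(object@members$father_id) & is.na(object@members$mother_id))
  cat("Pedigree", object@familyId, ":", nrow(object@members), "members (",
      nf, "founders );", nrow(object@events), "simulated de novo events\n")
})

setMethod("show", "PhaseReport", function(object) {
  cat("PhaseReport", object@familyId, ":", object@status, "\n")
  cat("  feasible assignments per region:",
      paste(names(object@nFeasible), object@nFeasible, sep = "=",
            collapse = ", "), "\n")
  if (length(object@events))
    cat(" ", length(object@events), "minimal de novo explanation(s)\n")
})

# topological cycle check on parent links
.pedHasCycle <- function(m) {
  ids <- m$member_id
  kids <- lapply(ids, function(i)
    m$member_id[!is.na(m$father_id) & m$father_id == i |
                !is.na(m$mother_id) & m$mother_id == i])
  names(kids) <- ids
  state <- setNames(rep(0L, length(ids)), ids)  # 0 unseen, 1 on stack, 2 done
  found <- FALSE
  visit <- function(i) {
    if (found || state[[i]] == 2L) return(invisible())
    if (state[[i]] == 1L) { found <<- TRUE; return(invisible()) }
    state[[i]] <<- 1L
    for (k in kids[[i]]) visit(k)
    state[[i]] <<- 2L
  }
  for (i in ids) visit(i)
  found
}
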