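#' QC evaluation of a raw MLPA sample
#'
#' Evaluates the dosage-quality control fragments of one sample. The four
#' Q fragments amplify strongly when too little sample DNA has been ligated:
#' a Q-fragment median at or above \code{q_frac} times the reference-probe
#' median marks insufficient DNA (and, by the same evidence, failed
#' ligation). The two D fragments report denaturation: a D-fragment median
#' below \code{d_frac} times the reference median marks incomplete
#' denaturation. Sex consistency compares the X/Y probe signals against the
#' reported sex when one is supplied.
#'
#' @param signal named numeric vector of raw peak signals for one sample
#'   (names are probe_ids), or an \linkS4class{MlpaRun} column.
#' @param panel a \linkS4class{ProbePanel}.
#' @param thresholds list with elements \code{q_frac} (default 0.5) and
#'   \code{d_frac} (default 0.3).
#' @param sex reported sex (\code{"M"}, \code{"F"} or \code{NA}).
#' @return a one-row \code{data.frame} with logical columns
#'   \code{dna_quantity_ok}, \code{ligation_ok}, \code{denaturation_ok} and
#'   \code{sex_consistent} (NA when no sex was reported).
#' @export
qcCheck <- function(signal, panel, thresholds = list(), sex = NA) {
  thr <- utils::modifyList(list(q_frac = 0.5, d_frac = 0.3), thresholds)
  pr <- panel@probes
  ctl <- pr$probe_id[pr$category == "dq_control"]
  .stopIf(!all(ctl %in% names(signal)),
          "missing control-fragment signal(s): ",
          paste(setdiff(ctl, names(signal)), collapse = ", "))
  refmed <- stats::median(signal[pr$probe_id[pr$category == "reference"]])
  qprobes <- pr$probe_id[pr$category == "dq_control" &
                           startsWith(pr$region, "QFRAG")]
  dprobes <- pr$probe_id[pr$category == "dq_control" &
                           startsWith(pr$region, "DFRAG")]
  qmed <- stats::median(signal[qprobes])
  dmed <- stats::median(signal[dprobes])
  dna_ok <- qmed < thr$q_frac * refmed
  den_ok <- dmed >= thr$d_frac * refmed
  sexc <- NA
  if (!is.na(sex) && "SEX_Y_p1" %in% names(signal) && refmed > 0) {
    inferred <- if (signal["SEX_Y_p1"] / refmed > 0.25) "M" else "F"
    sexc <- identical(inferred, toupper(substr(sex, 1, 1)))
  }
  data.frame(dna_quantity_ok = dna_ok, ligation_ok = dna_ok,
             denaturation_ok = den_ok, sex_consistent = sexc)
}

#' Two-stage dosage-quotient normalization
#'
#' Converts raw peak signals to dosage quotients (DQ). Stage one ratios each
#' probe signal to the median reference-probe signal of the same sample,
#' cancelling sample-level scale effects (DNA input, injection, pipetting).
#' Stage two divides each within-sample ratio by the median of the same
#' ratio across the external control samples, cancelling probe-specific
#' amplification efficiency. A DQ of 1.0 therefore means the reference
#' diploid dose. Medians (not means) are used at both stages for robustness
#' to single-probe outliers.
#'
#' @param run an \linkS4class{MlpaRun}; its manifest must flag at least
#'   three control samples.
#' @param thresholds QC thresholds forwarded to \code{\link{qcCheck}}.
#' @return a \linkS4class{DosageSet} with DQ values for every
#'   non-control-fragment probe of every non-control sample, plus per-sample
#'   QC flags.
#' @export
normalizeRun <- function(run, thresholds = list()) {
  panel <- run@panel
  ctrl_ids <- run@samples$sample_id[run@samples$is_control]
  .stopIf(length(ctrl_ids) < 3,
          "normalization needs at least 3 control samples, got ",
          length(ctrl_ids))
  refp <- referenceProbes(panel)
  keep <- setdiff(rownames(run@signal), controlFragmentProbes(panel))

  ratio1 <- function(col) {
    m <- stats::median(col[refp])
    .stopIf(!is.finite(m) || m <= 0,
            "normalization failure: zero or undefined reference median")
    col[keep] / m
  }
  rat <- apply(run@signal, 2, ratio1)           # keep x samples
  ctrl_med <- apply(rat[, ctrl_ids, drop = FALSE], 1, stats::median)
  .stopIf(any(!is.finite(ctrl_med) | ctrl_med <= 0),
          "normalization failure: zero control-median ratio for probe(s) ",
          paste(keep[!is.finite(ctrl_med) | ctrl_med <= 0], collapse = ", "))
  dq <- sweep(rat, 1, ctrl_med, "/")

  test_ids <- run@samples$sample_id[!run@samples$is_control]
  sexes <- if (!is.null(run@samples$sex)) run@samples$sex else
    rep(NA, nrow(run@samples))
  qc <- do.call(rbind, lapply(seq_along(run@samples$sample_id), function(i)
    qcCheck(run@signal[, i], panel, thresholds, sexes[i])))
  qc <- cbind(sample_id = run@samples$sample_id, qc)
  rownames(qc) <- NULL

  new("DosageSet", panel = panel,
      dq = dq[, test_ids, drop = FALSE],
      qc = qc[match(test_ids, qc$sample_id), , drop = FALSE])
}

# Table 1 bin edges: left-closed, right-open ("«" read as <=)
.TABLE1_EDGES <- c(0, 0.35, 0.65, 1.35, 1.65, 2.35)

#' Dosage quotient to integer copy number
#'
#' Maps a DQ value to an integer copy number. In \code{"table1"} mode the
#' published P021 lookup is applied: gene-specific probes call 0/1/2/3/4
#' copies over the DQ bins [0,0.35), [0.35,0.65), [0.65,1.35), [1.35,1.65),
#' [1.65,2.35); combined probes call 0/2/4/6/8 over the same bins. Bins are
#' left-closed (a DQ of exactly 0.65 calls two copies). Above 2.35 the table
#' is extended by rounding DQ times the expected diploid dose, the only
#' continuation consistent with the bin centres. In \code{"rounding"} mode
#' \code{round(dq * expected_diploid_copies)} is used throughout; this is
#' the only mode able to call odd totals on combined probes (the published
#' table lists even counts only). Rounding is half-away-from-zero.
#'
#' A call is flagged borderline when the DQ lies within \code{tol} of a
#' table bin boundary.
#'
#' @param dq numeric vector of dosage quotients (non-negative).
#' @param specificity \code{"gene_specific"} or \code{"combined"} (recycled).
#' @param mode \code{"table1"} or \code{"rounding"}.
#' @param tol borderline tolerance in DQ units (default 0.05).
#' @return a \code{data.frame} with integer column \code{cn} and logical
#'   column \code{borderline}.
#' @export
#' @examples
#' callCN(c(0.5, 1.0, 1.5), "gene_specific")$cn   # 1 2 3
#' callCN(1.0, "combined")$cn                     # 4
callCN <- function(dq, specificity = "gene_specific",
                   mode = c("table1", "rounding"), tol = 0.05) {
  mode <- match.arg(mode)
  .stopIf(any(!is.finite(dq) | dq < 0), "dq values must be finite and >= 0")
  specificity <- rep_len(specificity, length(dq))
  .stopIf(!all(specificity %in% c("gene_specific", "combined")),
          "specificity must be 'gene_specific' or 'combined'")
  edc <- ifelse(specificity == "combined", 4L, 2L)
  if (mode == "rounding") {
    cn <- as.integer(.roundHalfUp(dq * edc))
  } else {
    bin <- findInterval(dq, .TABLE1_EDGES)  # 1..5 within table, 6 above
    cn <- ifelse(bin <= 5L,
                 (bin - 1L) * ifelse(specificity == "combined", 2L, 1L),
                 .roundHalfUp(dq * edc))
    cn <- as.integer(cn)
  }
  bdist <- vapply(dq, function(x) min(abs(x - .TABLE1_EDGES[-1])), numeric(1))
  data.frame(cn = cn, borderline = bdist < tol)
}

#' Call integer copy numbers for every region of a dosage set
#'
#' Applies \code{\link{callCN}} per probe and aggregates probe-level calls
#' to region-level calls. Where a region carries several probes (the panel
#' has duplicate probes for some combined regions) their DQs are averaged
#' before calling. Gene-specific and combined probes use their respective
#' Table-1 columns; QC flags are carried through from normalization.
#'
#' @param dosage a \linkS4class{DosageSet}.
#' @param mode,tol see \code{\link{callCN}}. Default mode is
#'   \code{"rounding"} (callable odd combined totals); \code{"table1"}
#'   reproduces the published lookup exactly.
#' @param regions which regions to call (default: all SMN-region labels).
#' @return a \linkS4class{CopyNumberSet} (regions x samples).
#' @export
callProfiles <- function(dosage, mode = c("rounding", "table1"), tol = 0.05,
                         regions = smnRegions()) {
  mode <- match.arg(mode)
  pr <- dosage@panel@probes
  pr <- pr[pr$category == "smn_target" & pr$region %in% regions, , drop = FALSE]
  .stopIf(!all(regions %in% pr$region),
          "panel has no probe for region(s): ",
          paste(setdiff(regions, pr$region), collapse = ", "))
  .stopIf(!all(pr$probe_id %in% rownames(dosage@dq)),
          "dosage set lacks probe(s): ",
          paste(setdiff(pr$probe_id, rownames(dosage@dq)), collapse = ", "))
  ns <- ncol(dosage@dq)
  cn <- matrix(NA_integer_, nrow = length(regions), ncol = ns,
               dimnames = list(regions, colnames(dosage@dq)))
  bl <- matrix(FALSE, nrow = length(regions), ncol = ns,
               dimnames = dimnames(cn))
  for (r in regions) {
    pids <- pr$probe_id[pr$region == r]
    spec <- pr$specificity[pr$region == r][1]
    rdq <- colMeans(dosage@dq[pids, , drop = FALSE])
    res <- callCN(rdq, spec, mode = mode, tol = tol)
    cn[r, ] <- res$cn
    bl[r, ] <- res$borderline
  }
  new("CopyNumberSet", cn = cn, borderline = bl, qc = dosage@qc,
      mode = mode, tol = tol)
}

#' Copy-number accessors
#'
#' @param x a \linkS4class{CopyNumberSet} (or \linkS4class{DosageSet} for
#'   \code{dosageQuotients}).
#' @return \code{copyNumbers}: integer matrix regions x samples;
#'   \code{borderlineCalls}: logical matrix of the same shape;
#'   \code{dosageQuotients}: numeric DQ matrix probes x samples;
#'   \code{sampleQC}: the per-sample QC data.frame.
#' @export
copyNumbers <- function(x) x@cn

#' @rdname copyNumbers
#' @export
borderlineCalls <- function(x) x@borderline

#' @rdname copyNumbers
#' @export
dosageQuotients <- function(x) x@dq

#' @rdname copyNumbers
#' @export
sampleQC <- function(x) x@qc
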