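#' Classify an individual's SMN genotype group
#'
#' Maps SMN1/SMN2 exon-7 copy-number totals to the diagnostic genotype
#' labels: \code{M1M1} (homozygous SMN1 exon-7 deletion), \code{M2M2}
#' (homozygous SMN2 exon-7 deletion with SMN1 present), \code{NULL_BOTH}
#' (both exon-7 regions absent; never reported by the assay's diagnostic
#' groups and flagged for manual review), and otherwise by the SMN1 exon-7
#' count: \code{HET_DEL} (1 copy, the 1:0 carrier state), \code{NORMAL_2}
#' (2 copies), \code{MULTI} (more than 2). The joint-null test takes
#' priority over M1M1/M2M2, which take priority over the count classes, so
#' every pair of non-negative totals maps to exactly one label.
#'
#' @param smn1_e7,smn2_e7 integer copy-number totals; vectors are accepted
#'   and recycled to common length. Alternatively pass a
#'   \linkS4class{CopyNumberSet} as \code{smn1_e7}.
#' @return character vector of genotype labels.
#' @export
#' @examples
#' classifyGenotype(0, 2)  # "M1M1"
#' classifyGenotype(1, 2)  # "HET_DEL"
classifyGenotype <- function(smn1_e7, smn2_e7 = NULL) {
  if (is(smn1_e7, "CopyNumberSet")) {
    cn <- copyNumbers(smn1_e7)
    .stopIf(!all(c("SMN1_e7", "SMN2_e7") %in% rownames(cn)),
            "copy-number set lacks SMN1_e7/SMN2_e7")
    smn2_e7 <- cn["SMN2_e7", ]
    smn1_e7 <- cn["SMN1_e7", ]
  }
  .stopIf(is.null(smn2_e7), "SMN2_e7 totals missing")
  .stopIf(any(is.na(smn1_e7)) || any(is.na(smn2_e7)),
          "missing copy-number totals")
  n <- max(length(smn1_e7), length(smn2_e7))
  s1 <- rep_len(smn1_e7, n); s2 <- rep_len(smn2_e7, n)
  .stopIf(any(s1 < 0 | s2 < 0), "totals must be non-negative")
  out <- ifelse(s1 == 0 & s2 == 0, "NULL_BOTH",
         ifelse(s1 == 0, "M1M1",
         ifelse(s2 == 0, "M2M2",
         ifelse(s1 == 1, "HET_DEL",
         ifelse(s1 == 2, "NORMAL_2", "MULTI")))))
  setNames(out, names(s1))
}

#' Summarize a cohort's copy-number distribution
#'
#' Tabulates, per region, the number of individuals with 0, 1, 2 or more
#' than 2 copies — the layout of the published cohort summary.
#'
#' @param cnset a \linkS4class{CopyNumberSet}, or an integer matrix
#'   (regions x samples), or a cohort \code{data.frame} as written by
#'   \code{\link{makeFixtures}} (sample_id + region columns).
#' @param group_name cohort label carried in the output.
#' @param regions regions to tabulate (default: the four SMN exon regions
#'   of the published table).
#' @return \code{data.frame} with columns \code{group}, \code{region},
#'   \code{bin} (\code{"0"},\code{"1"},\code{"2"},\code{">2"}),
#'   \code{count} and \code{n}; counts sum to \code{n} within each region.
#' @export
summarizeCohort <- function(cnset, group_name = "cohort",
                            regions = c("SMN1_e7", "SMN1_e8",
                                        "SMN2_e7", "SMN2_e8")) {
  cn <- .asRegionMatrix(cnset)
  .stopIf(ncol(cn) == 0, "empty cohort")
  .stopIf(!all(regions %in% rownames(cn)),
          "region(s) absent from cohort: ",
          paste(setdiff(regions, rownames(cn)), collapse = ", "))
  n <- ncol(cn)
  out <- lapply(regions, function(r) {
    v <- cn[r, ]
    data.frame(group = group_name, region = r,
               bin = c("0", "1", "2", ">2"),
               count = c(sum(v == 0), sum(v == 1), sum(v == 2), sum(v > 2)),
               n = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Published-style cohort percentages
#'
#' Converts bin counts to percentages of the cohort size, rounded half-up
#' to one decimal (the published formatting, e.g. 62/122 prints as 50.8).
#'
#' @param summary a cohort summary from \code{\link{summarizeCohort}}, or a
#'   numeric vector of counts (then \code{n} must be given).
#' @param n cohort size when \code{summary} is a plain count vector.
#' @return the summary with a \code{pct} column added, or a numeric vector
#'   of percentages.
#' @export
#' @examples
#' cohortPercentages(62, 122)   # 50.8
cohortPercentages <- function(summary, n = NULL) {
  if (is.data.frame(summary)) {
    summary$pct <- .roundHalfUp(100 * summary$count / summary$n, 1)
    return(summary)
  }
  .stopIf(is.null(n) || n <= 0, "cohort size n must be positive")
  .roundHalfUp(100 * summary / n, 1)
}

# coerce the accepted cohort representations to a regions x samples matrix
.asRegionMatrix <- function(x) {
  if (is(x, "CopyNumberSet")) return(copyNumbers(x))
  if (is.data.frame(x)) {
    .stopIf(is.null(x$sample_id), "cohort data.frame needs a sample_id column")
    m <- t(as.matrix(x[, setdiff(names(x), "sample_id"), drop = FALSE]))
    colnames(m) <- x$sample_id
    storage.mode(m) <- "integer"
    return(m)
  }
  .stopIf(!is.matrix(x), "unsupported cohort representation")
  x
}
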