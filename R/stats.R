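# Cohort inferential statistics: tie-corrected Kruskal-Wallis on copy
# numbers and Pearson chi-square on contingency tables.

#' Tie-corrected Kruskal-Wallis test
#'
#' Rank-based k-sample location test on mid-ranks with the standard tie
#' correction: H is divided by 1 - sum(t^3 - t) / (N^3 - N) over the tied
#' groups. The p-value uses the chi-square approximation with k - 1 degrees
#' of freedom. Copy numbers are treated as ordinal integers; when every
#' pooled value is identical the statistic is defined as H = 0, p = 1.
#'
#' @param values numeric vector of pooled observations, or a list of
#'   per-group vectors (then \code{groups} is ignored).
#' @param groups group labels aligned with \code{values}.
#' @return list with \code{H}, \code{df} and \code{p}.
#' @export
#' @examples
#' kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))$H   # 3.857
kruskalWallis <- function(values, groups = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values)
  }
  .stopIf(is.null(groups), "group labels required")
  groups <- factor(groups)
  .stopIf(nlevels(groups) < 2, "need at least 2 groups")
  .stopIf(any(tapply(values, groups, length) == 0), "empty group")
  N <- length(values)
  .stopIf(N < 3, "need at least 3 observations")
  r <- rank(values)                      # mid-ranks
  Rj <- tapply(r, groups, sum)
  nj <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr <= 0) return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  H <- H / corr
  df <- nlevels(groups) - 1L
  list(H = H, df = df, p = stats::pchisq(H, df, lower.tail = FALSE))
}

#' Pearson chi-square test on a contingency table
#'
#' Classical sum of (O - E)^2 / E with expectations from the row/column
#' margins; df = (r - 1)(c - 1). No continuity correction by default; set
#' \code{yates = TRUE} for the Yates-corrected 2x2 variant.
#'
#' @param table integer matrix of counts, at least 2x2, with positive
#'   margins.
#' @param yates apply the Yates continuity correction (2x2 only).
#' @return list with \code{chisq}, \code{df} and \code{p}.
#' @export
#' @examples
#' pearsonChi2(matrix(c(123, 9, 868, 183), 2))  # chisq ~ 9.68
pearsonChi2 <- function(table, yates = FALSE) {
  tab <- as.matrix(table)
  .stopIf(nrow(tab) < 2 || ncol(tab) < 2, "table must be at least 2x2")
  .stopIf(any(tab < 0), "counts must be non-negative")
  rs <- rowSums(tab); cs <- colSums(tab)
  .stopIf(any(rs == 0) || any(cs == 0), "zero row/column margin")
  E <- outer(rs, cs) / sum(tab)
  if (yates) {
    .stopIf(nrow(tab) != 2 || ncol(tab) != 2,
            "Yates correction applies to 2x2 tables only")
    chisq <- sum((pmax(abs(tab - E) - 0.5, 0))^2 / E)
  } else {
    chisq <- sum((tab - E)^2 / E)
  }
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Compare two cohorts' copy-number distributions per region
#'
#' Runs the tie-corrected Kruskal-Wallis test region by region between two
#' cohorts and flags regions significant at level \code{alpha} (default
#' 0.05). Raw integer copy numbers are required: pre-binned data (e.g. a
#' ">2" category) carry no rank information and are rejected. No
#' multiple-testing correction is applied by default; set \code{adjust} to
#' a \code{\link[stats]{p.adjust}} method to add adjusted p-values.
#'
#' @param cohortA,cohortB \linkS4class{CopyNumberSet}s, region x sample
#'   integer matrices, or cohort \code{data.frame}s.
#' @param regions regions to test (default: regions present in both).
#' @param alpha significance level for the flag.
#' @param adjust optional multiple-testing correction method (default
#'   \code{"none"}).
#' @return \code{data.frame} with columns \code{region}, \code{H},
#'   \code{df}, \code{p} (and \code{p_adj} if requested),
#'   \code{significant}.
#' @export
compareGroups <- function(cohortA, cohortB, regions = NULL, alpha = 0.05,
                          adjust = "none") {
  a <- .asRegionMatrix(cohortA)
  b <- .asRegionMatrix(cohortB)
  .stopIf(ncol(a) == 0 || ncol(b) == 0, "empty cohort")
  if (is.null(regions)) regions <- intersect(rownames(a), rownames(b))
  .stopIf(!all(regions %in% rownames(a)) || !all(regions %in% rownames(b)),
          "region(s) absent from a cohort: ",
          paste(setdiff(regions, intersect(rownames(a), rownames(b))),
                collapse = ", "))
  .checkUnbinned <- function(m) .stopIf(
    any(is.na(m)) || any(m != round(m)),
    "binned or non-integer copy-number input: raw integer totals required")
  .checkUnbinned(a[regions, , drop = FALSE])
  .checkUnbinned(b[regions, , drop = FALSE])
  res <- lapply(regions, function(r) {
    kw <- kruskalWallis(c(a[r, ], b[r, ]),
                        c(rep("A", ncol(a)), rep("B", ncol(b))))
    data.frame(region = r, H = kw$H, df = kw$df, p = kw$p)
  })
  res <- do.call(rbind, res)
  if (!identical(adjust, "none")) {
    res$p_adj <- stats::p.adjust(res$p, method = adjust)
    res$significant <- res$p_adj < alpha
  } else {
    res$significant <- res$p < alpha
  }
  res
}
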