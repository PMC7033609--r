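# Hardy-Weinberg machinery: per-allele copy-count frequency estimation from
# diploid totals, and posterior silent-carrier risk.

# Censored-data EM core. Each observation i is the event
# lo[i] <= a + b <= hi[i] for two independent allele copy counts a, b drawn
# from f over 0..kmax. Exact totals are the special case lo == hi.
.emFitCensored <- function(lo, hi, kmax = 6, tol = 1e-8, max_iter = 10000) {
  stopifnot(length(lo) == length(hi), all(lo <= hi))
  .stopIf(any(lo < 0) || any(hi > 2 * kmax),
          "total outside the representable range 0..", 2 * kmax)
  obs <- table(paste(lo, hi))
  key <- do.call(rbind, strsplit(names(obs), " "))
  olo <- as.integer(key[, 1]); ohi <- as.integer(key[, 2])
  wts <- as.numeric(obs)
  pairs <- expand.grid(a = 0:kmax, b = 0:kmax)
  tot <- pairs$a + pairs$b
  # Start from a smoothed histogram of halved totals rather than the exact
  # uniform vector: the complete-data likelihood has symmetric saddle points
  # (e.g. all totals even and equal) on which a perfectly symmetric start
  # would sit forever; the halved-totals start is deterministic, breaks the
  # symmetry toward the data, and keeps every class reachable.
  f <- rep(1e-3, kmax + 1)
  mid <- (olo + ohi) / 2
  for (j in seq_along(mid)) {
    lo2 <- min(floor(mid[j] / 2), kmax)
    hi2 <- min(ceiling(mid[j] / 2), kmax)
    f[lo2 + 1] <- f[lo2 + 1] + wts[j] / 2
    f[hi2 + 1] <- f[hi2 + 1] + wts[j] / 2
  }
  f <- f / sum(f)
  for (it in seq_len(max_iter)) {
    num <- rep(0, kmax + 1)
    for (j in seq_along(olo)) {
      sel <- tot >= olo[j] & tot <= ohi[j]
      w <- f[pairs$a[sel] + 1] * f[pairs$b[sel] + 1]
      s <- sum(w)
      if (s <= 0) next
      w <- w / s * wts[j]
      num <- num + vapply(0:kmax, function(k)
        sum(w[pairs$a[sel] == k]) + sum(w[pairs$b[sel] == k]), numeric(1))
    }
    fnew <- num / sum(num)
    delta <- sum(abs(fnew - f))
    f <- fnew
    if (delta < tol) break
  }
  names(f) <- as.character(0:kmax)
  f
}

#' Estimate per-allele copy-count frequencies from diploid totals
#'
#' Maximum-likelihood estimate, under Hardy-Weinberg equilibrium, of the
#' population frequency vector f over per-homolog copy counts 0..k_max,
#' given observed diploid totals (each total the sum of two independent
#' draws from f). Fitted by expectation-maximization from a uniform start;
#' fully deterministic given the inputs.
#'
#' @param totals integer vector of observed diploid copy-number totals.
#' @param k_max largest per-allele copy count modeled (default 6, covering
#'   the observed 1-6 diploid range with margin).
#' @param tol stop when the L1 change of f falls below this (default 1e-8).
#' @param max_iter iteration cap (default 10000).
#' @return named numeric vector of length \code{k_max + 1} (names
#'   \code{"0"}..\code{"k_max"}) summing to 1.
#' @export
#' @examples
#' estimateAlleleFreqs(rep(2L, 50))   # converges to a point mass at 1 copy
estimateAlleleFreqs <- function(totals, k_max = 6, tol = 1e-8,
                                max_iter = 10000) {
  .stopIf(length(totals) == 0, "no totals supplied")
  .stopIf(any(totals < 0 | totals > 2 * k_max),
          "impossible total(s): ",
          paste(unique(totals[totals < 0 | totals > 2 * k_max]),
                collapse = ", "))
  .emFitCensored(totals, totals, kmax = k_max, tol = tol, max_iter = max_iter)
}

#' Posterior over allelic decompositions of a diploid total
#'
#' A diploid total t can arise from any unordered allele split (a, b) with
#' a + b = t; quantitative dosage data cannot distinguish them (two copies
#' in cis versus in trans). Under Hardy-Weinberg with allele copy-count
#' frequencies f, the posterior weight of split (a, b) is proportional to
#' 2 f_a f_b for a != b and f_a^2 for a == b.
#'
#' @param total observed diploid copy-number total.
#' @param freqs allele copy-count frequency vector as returned by
#'   \code{\link{estimateAlleleFreqs}}.
#' @return \code{data.frame} with columns \code{a}, \code{b} (a <= b) and
#'   \code{prob} (summing to 1).
#' @export
alleleSplitPosterior <- function(total, freqs) {
  kmax <- length(freqs) - 1
  .stopIf(total < 0 || total > 2 * kmax,
          "total ", total, " unreachable with k_max ", kmax)
  a <- 0:(total %/% 2)
  b <- total - a
  ok <- b <= kmax
  a <- a[ok]; b <- b[ok]
  w <- ifelse(a == b, 1, 2) * freqs[a + 1] * freqs[b + 1]
  .stopIf(sum(w) <= 0,
          "total ", total, " has zero probability under these frequencies")
  data.frame(a = a, b = b, prob = as.numeric(w / sum(w)))
}

#' Silent-carrier risk of a diploid copy-number total
#'
#' Probability that an observed diploid total hides a zero-copy allele,
#' i.e. that the individual is a deletion carrier despite a normal-looking
#' total (the 2:0, 3:0, ... configurations). Computed as the posterior mass
#' of splits with min(a, b) = 0 under \code{\link{alleleSplitPosterior}}.
#' A total of 0 returns 1 (both alleles are null); a total of 1 returns 1
#' (the only split is 0:1).
#'
#' @inheritParams alleleSplitPosterior
#' @return a probability in [0, 1].
#' @export
#' @examples
#' f <- c(0.1, 0.8, 0.1, 0, 0, 0, 0)
#' carrierRisk(2, f)   # 2*f0*f2 / (2*f0*f2 + f1^2) = 0.0303
carrierRisk <- function(total, freqs) {
  if (total == 0) return(1)
  post <- alleleSplitPosterior(total, freqs)
  sum(post$prob[post$a == 0])
}

#' Carrier-risk table for a cohort
#'
#' Applies \code{\link{carrierRisk}} to every sample of a copy-number set at
#' one region, using region-specific allele frequencies.
#'
#' @param cnset a \linkS4class{CopyNumberSet} or an integer matrix
#'   (regions x samples).
#' @param region region label to assess (default \code{"SMN1_e7"}).
#' @param freqs allele copy-count frequency vector for that region.
#' @return \code{data.frame} with columns \code{sample_id}, \code{region},
#'   \code{total}, \code{risk}.
#' @export
carrierRiskTable <- function(cnset, freqs, region = "SMN1_e7") {
  cn <- if (is(cnset, "CopyNumberSet")) copyNumbers(cnset) else cnset
  .stopIf(!region %in% rownames(cn), "region ", region, " absent from calls")
  tot <- cn[region, ]
  data.frame(sample_id = colnames(cn), region = region,
             total = as.integer(tot),
             risk = vapply(tot, carrierRisk, numeric(1), freqs = freqs),
             row.names = NULL)
}
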