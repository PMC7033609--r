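# Pedigree phasing of copy-number totals: exhaustive allelic decomposition,
# Mendelian-consistency checking, informativeness classification, and
# minimal de novo event search.

#' Enumerate allelic decompositions of a diploid total
#'
#' All unordered pairs (a, b) with a + b = total and a <= b <= k_max: the
#' possible distributions of an observed diploid copy-number total over the
#' two chromosome-5 homologs. Dosage data alone cannot distinguish them
#' (cis versus trans).
#'
#' @param total observed diploid total (>= 0).
#' @param k_max largest per-homolog copy count (default 6).
#' @return \code{data.frame} with integer columns \code{a} and \code{b};
#'   \code{floor(total/2) + 1} rows when \code{k_max >= total}.
#' @export
#' @examples
#' alleleSplits(2)  # (0,2) and (1,1)
alleleSplits <- function(total, k_max = 6) {
  .stopIf(total < 0, "total must be non-negative")
  .stopIf(k_max < ceiling(total / 2),
          "total ", total, " infeasible with k_max ", k_max)
  a <- 0:(total %/% 2)
  b <- total - a
  keep <- b <= k_max
  data.frame(a = as.integer(a[keep]), b = as.integer(b[keep]))
}

# nuclear-family structure: returns list(father, mother, children)
.nuclearStructure <- function(ped) {
  m <- ped@members
  kids <- m$member_id[!is.na(m$father_id) | !is.na(m$mother_id)]
  .stopIf(length(kids) < 1, "family ", ped@familyId, " has no children")
  fa <- unique(m$father_id[m$member_id %in% kids])
  mo <- unique(m$mother_id[m$member_id %in% kids])
  fa <- fa[!is.na(fa)]; mo <- mo[!is.na(mo)]
  .stopIf(length(fa) != 1 || length(mo) != 1,
          "family ", ped@familyId,
          ": phasing supports one nuclear couple per family")
  list(father = fa, mother = mo, children = kids)
}

# coerce totals input (matrix members x regions, or cohort data.frame)
.asTotalsMatrix <- function(totals) {
  if (is.data.frame(totals)) {
    .stopIf(is.null(totals$sample_id), "totals data.frame needs sample_id")
    m <- as.matrix(totals[, setdiff(names(totals), "sample_id"),
                          drop = FALSE])
    rownames(m) <- totals$sample_id
    storage.mode(m) <- "integer"
    return(m)
  }
  totals
}

# Per-region zero-event feasibility enumeration. Children may carry a total
# adjustment (events already subtracted) and a minimum on the allele
# received from a given parent (a loss/conversion donor must hold >= 1
# copy before the event). Returns the list of feasible unordered
# (father split, mother split) pairs.
.feasibleSplits <- function(F, M, childTotals, k_max,
                            minFromFather = NULL, minFromMother = NULL) {
  if (is.null(minFromFather)) minFromFather <- rep(0L, length(childTotals))
  if (is.null(minFromMother)) minFromMother <- rep(0L, length(childTotals))
  if (any(childTotals < 0)) return(list())
  sf <- alleleSplits(F, k_max)
  sm <- alleleSplits(M, k_max)
  out <- list()
  for (i in seq_len(nrow(sf))) for (j in seq_len(nrow(sm))) {
    fx <- unique(c(sf$a[i], sf$b[i]))
    my <- unique(c(sm$a[j], sm$b[j]))
    ok <- all(vapply(seq_along(childTotals), function(c) {
      any(outer(fx, my, function(x, y)
        x + y == childTotals[c] & x >= minFromFather[c] &
          y >= minFromMother[c]))
    }, logical(1)))
    if (ok) out[[length(out) + 1]] <-
        list(father = c(sf$a[i], sf$b[i]), mother = c(sm$a[j], sm$b[j]))
  }
  out
}

#' Phase one family's copy-number totals
#'
#' Exhaustively enumerates, per region, the unordered allelic splits of each
#' parent's diploid total and every child transmission, retaining the
#' parental split assignments under which every child's total is the sum of
#' one allele from each parent. The family is \code{informative} when every
#' analyzed region admits exactly one feasible assignment,
#' \code{uninformative} when some region admits several (multiple
#' combinations possible), and \code{discrepant} when some region admits
#' none under strictly Mendelian transmission. For discrepant families a
#' minimal de novo event search (\code{\link{detectDeNovo}}) is run with a
#' budget of \code{max_events}.
#'
#' By default regions are phased independently; with \code{joint = TRUE}
#' the per-region assignments are intersected under a shared transmission
#' choice per child (each child receives one whole haplotype per parent).
#'
#' @param pedigree a \linkS4class{Pedigree}.
#' @param totals integer matrix (members x regions, rownames = member ids)
#'   or a cohort \code{data.frame} with a \code{sample_id} column.
#' @param regions regions to analyze (default: all SMN-region labels).
#' @param k_max largest per-homolog copy count (default 6, raised
#'   automatically if a parental total requires it).
#' @param max_events de novo search budget for discrepant families.
#' @param joint intersect regions under shared child transmissions.
#' @return a \linkS4class{PhaseReport}.
#' @export
phaseFamily <- function(pedigree, totals, regions = smnRegions(), k_max = 6,
                        max_events = 1, joint = FALSE) {
  tot <- .asTotalsMatrix(totals)
  st <- .nuclearStructure(pedigree)
  ids <- c(st$father, st$mother, st$children)
  .stopIf(!all(ids %in% rownames(tot)),
          "totals missing for member(s): ",
          paste(setdiff(ids, rownames(tot)), collapse = ", "))
  .stopIf(!all(regions %in% colnames(tot)),
          "totals missing for region(s): ",
          paste(setdiff(regions, colnames(tot)), collapse = ", "))
  k_max <- max(k_max, ceiling(max(tot[ids, regions]) / 2))

  assignments <- if (joint)
    .phaseJoint(tot, st, regions, k_max)
  else
    lapply(setNames(regions, regions), function(r)
      .feasibleSplits(tot[st$father, r], tot[st$mother, r],
                      tot[st$children, r], k_max))
  nfeas <- vapply(assignments, length, integer(1))
  status <- if (any(nfeas == 0)) "discrepant"
            else if (all(nfeas == 1)) "informative"
            else "uninformative"
  notes <- character()
  events <- list()
  if (status == "discrepant") {
    notes <- paste("zero feasible assignments at:",
                   paste(regions[nfeas == 0], collapse = ", "))
    events <- detectDeNovo(pedigree, tot, regions = regions,
                           max_events = max_events, k_max = k_max)
    if (length(events))
      notes <- c(notes, sprintf("resolved by %d minimal %d-event explanation(s)",
                                length(events), nrow(events[[1]])))
  }
  new("PhaseReport", familyId = pedigree@familyId, status = status,
      nFeasible = nfeas, assignments = assignments, events = events,
      notes = notes)
}

# joint-mode feasible assignment sets: shared per-child transmission choice
.phaseJoint <- function(tot, st, regions, k_max) {
  nch <- length(st$children)
  # transmission vectors: per child, which parental homolog (1/2) per parent
  tchoices <- expand.grid(rep(list(1:2), 2 * nch))
  keysets <- setNames(vector("list", length(regions)), regions)
  for (ti in seq_len(nrow(tchoices))) {
    tv <- as.integer(tchoices[ti, ])
    regsets <- list()
    viable <- TRUE
    for (r in regions) {
      sf <- alleleSplits(tot[st$father, r], k_max)
      sm <- alleleSplits(tot[st$mother, r], k_max)
      found <- list()
      for (i in seq_len(nrow(sf))) for (oi in 1:2) {
        fh <- if (oi == 1) c(sf$a[i], sf$b[i]) else c(sf$b[i], sf$a[i])
        for (j in seq_len(nrow(sm))) for (oj in 1:2) {
          mh <- if (oj == 1) c(sm$a[j], sm$b[j]) else c(sm$b[j], sm$a[j])
          ok <- all(vapply(seq_len(nch), function(c)
            fh[tv[2 * c - 1]] + mh[tv[2 * c]] == tot[st$children[c], r],
            logical(1)))
          if (ok) found[[length(found) + 1]] <-
              list(father = sort(fh), mother = sort(mh))
        }
      }
      if (!length(found)) { viable <- FALSE; break }
      regsets[[r]] <- found
    }
    if (!viable) next
    for (r in regions) {
      for (as_ in regsets[[r]]) {
        key <- paste(c(as_$father, as_$mother), collapse = ",")
        if (is.null(keysets[[r]])) keysets[[r]] <- list()
        keysets[[r]][[key]] <- as_
      }
    }
  }
  lapply(keysets, function(x) if (is.null(x)) list() else unname(x))
}

#' Search minimal de novo event explanations for a family
#'
#' For a family whose totals are not Mendelian-consistent, searches event
#' sets of growing size (up to \code{max_events}) that restore consistency.
#' An event is a one-copy gain or loss on one transmitted allele at one
#' region, or an SMN1-to-SMN2 exon-7 conversion on one transmitted
#' haplotype (one copy leaves SMN1_e7 and joins SMN2_e7); every event class
#' costs 1, and all explanations of minimal total cost are returned,
#' none adjudicated.
#'
#' @inheritParams phaseFamily
#' @param max_events largest event count searched (>= 0).
#' @return list of minimal explanations, each a \code{data.frame} with
#'   columns \code{member_id}, \code{parent}, \code{region}, \code{type};
#'   empty when the family is consistent without events or no explanation
#'   exists within the budget.
#' @export
detectDeNovo <- function(pedigree, totals, regions = smnRegions(),
                         max_events = 1, k_max = 6) {
  .stopIf(max_events < 0, "max_events must be >= 0")
  tot <- .asTotalsMatrix(totals)
  st <- .nuclearStructure(pedigree)
  k_max <- max(k_max, ceiling(max(tot[c(st$father, st$mother, st$children),
                                     regions]) / 2))
  if (.familyFeasible(tot, st, regions, k_max, NULL)) return(list())
  if (max_events == 0) return(list())

  cand <- list()
  for (ch in st$children) for (p in c("father", "mother")) {
    for (r in regions) for (ty in c("gain", "loss"))
      cand[[length(cand) + 1]] <- data.frame(
        member_id = ch, parent = p, region = r, type = ty,
        stringsAsFactors = FALSE)
    if (all(c("SMN1_e7", "SMN2_e7") %in% regions))
      cand[[length(cand) + 1]] <- data.frame(
        member_id = ch, parent = p, region = "SMN1_e7",
        type = "conversion", stringsAsFactors = FALSE)
  }
  for (e in seq_len(max_events)) {
    hits <- list()
    for (idx in utils::combn(length(cand), e, simplify = FALSE)) {
      ev <- do.call(rbind, cand[idx])
      if (.familyFeasible(tot, st, regions, k_max, ev))
        hits[[length(hits) + 1]] <- ev
    }
    if (length(hits)) return(hits)
  }
  list()
}

# family-wide feasibility under an (optional) event set
.familyFeasible <- function(tot, st, regions, k_max, events) {
  nch <- length(st$children)
  for (r in regions) {
    ct <- tot[st$children, r]
    minF <- rep(0L, nch); minM <- rep(0L, nch)
    if (!is.null(events)) {
      for (k in seq_len(nrow(events))) {
        ev <- events[k, ]
        ci <- match(ev$member_id, st$children)
        delta_r <- 0L
        if (ev$type == "gain" && ev$region == r) delta_r <- 1L
        if (ev$type == "loss" && ev$region == r) delta_r <- -1L
        if (ev$type == "conversion") {
          if (r == "SMN1_e7") delta_r <- -1L
          if (r == "SMN2_e7") delta_r <- 1L
        }
        if (delta_r == 0L) next
        ct[ci] <- ct[ci] - delta_r  # totals the child must have inherited
        if (delta_r < 0L) {         # donor allele must hold >= 1 copy
          if (ev$parent == "father") minF[ci] <- max(minF[ci], 1L)
          else minM[ci] <- max(minM[ci], 1L)
        }
      }
    }
    if (any(ct > tot[st$father, r] + tot[st$mother, r])) return(FALSE)
    feas <- .feasibleSplits(tot[st$father, r], tot[st$mother, r], ct,
                            k_max, minF, minM)
    if (!length(feas)) return(FALSE)
  }
  TRUE
}

#' Phase a set of families and report the de novo event rate
#'
#' Convenience drivers over \code{\link{phaseFamily}}: \code{phaseFamilies}
#' phases every family against a shared copy-number table;
#' \code{deNovoRateReport} tallies statuses and computes the family-level
#' de novo event rate (percentage of families whose discrepancy is resolved
#' by a within-budget event explanation), rounded half-up to one decimal.
#'
#' @param pedigrees list of \linkS4class{Pedigree} objects.
#' @param totals shared totals table (see \code{\link{phaseFamily}}).
#' @param ... forwarded to \code{\link{phaseFamily}}.
#' @return \code{phaseFamilies}: named list of \linkS4class{PhaseReport};
#'   \code{deNovoRateReport}: list with \code{n_families},
#'   \code{n_informative}, \code{n_uninformative}, \code{n_discrepant},
#'   \code{n_event_families} and \code{event_rate_pct}.
#' @export
phaseFamilies <- function(pedigrees, totals, ...) {
  reps <- lapply(pedigrees, phaseFamily, totals = totals, ...)
  setNames(reps, vapply(reps, function(r) r@familyId, character(1)))
}

#' @rdname phaseFamilies
#' @param reports list of \linkS4class{PhaseReport} objects.
#' @export
deNovoRateReport <- function(reports) {
  status <- vapply(reports, function(r) r@status, character(1))
  nev <- sum(vapply(reports, function(r)
    r@status == "discrepant" && length(r@events) > 0, logical(1)))
  list(n_families = length(reports),
       n_informative = sum(status == "informative"),
       n_uninformative = sum(status == "uninformative"),
       n_discrepant = sum(status == "discrepant"),
       n_event_families = nev,
       event_rate_pct = .roundHalfUp(100 * nev / length(reports), 1))
}
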