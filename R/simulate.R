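# Forward simulator: population haplotype pools, pedigrees with de novo
# events, and noisy MLPA peak signals.

.cohortGroupSizes <- c(NNb = 122L, NNw = 30L, M1M1b = 75L, M1M1w = 30L,
                       M2M2b = 50L, M2M2w = 8L, UUb = 72L)

# Read the bundled cohort bin-count configuration (published per-group
# copy-number bin counts for the regions with reported distributions).
.cohortBins <- function() {
  path <- system.file("extdata", "cohort_bins.tsv", package = "SMNcnv")
  .stopIf(!nzchar(path), "bundled cohort_bins.tsv not found")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# run expr with a private, restored RNG stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build a population haplotype-pool model
#'
#' Constructs a \linkS4class{PopulationModel} either from a named preset
#' (\code{"black_SA"}, \code{"white_SA"}) or from an explicit frequency
#' specification. Preset per-region allele copy-count frequencies are fitted
#' at call time from the bundled cohort bin-count configuration
#' (\code{inst/extdata/cohort_bins.tsv}) with an interval-censored variant
#' of the Hardy-Weinberg EM estimator: the 0/1/2 bins enter as exact diploid
#' totals and the ">2" bin as the censored event total >= 3. Regions without
#' a published distribution default to the diploid state (per-homolog copy
#' count 1 for gene-specific regions, 2 for combined regions). Haplotypes
#' are composed per region independently (reported exon copy numbers do not
#' correlate fully); supply an explicit haplotype table for linked
#' configurations.
#'
#' @param preset preset name, or a named list of per-region allele
#'   copy-count frequency vectors (independent mode), or a list with
#'   elements \code{haplotypes} (integer matrix, haplotype x region) and
#'   \code{freqs} (probabilities) for an explicit joint table.
#' @param de_novo_rate probability of a de novo event per transmitted
#'   haplotype per meiosis. Default 0.0165, the per-haplotype rate implied
#'   by a 3.3\% per-family event rate in one-child families.
#' @param k_max largest per-homolog copy count (default 6).
#' @return a validated \linkS4class{PopulationModel}.
#' @export
#' @examples
#' m <- makePopulationModel("white_SA")
#' m
makePopulationModel <- function(preset, de_novo_rate = 0.0165, k_max = 6) {
  if (is.character(preset) && length(preset) == 1) {
    .stopIf(!preset %in% c("black_SA", "white_SA"),
            "unknown preset '", preset, "'")
    grp <- if (preset == "black_SA") "NNb" else "NNw"
    bins <- .cohortBins()
    bins <- bins[bins$group == grp, , drop = FALSE]
    n <- .cohortGroupSizes[[grp]]
    af <- list()
    for (r in smnRegions()) {
      row <- bins[bins$region == r, , drop = FALSE]
      if (nrow(row) == 1) {
        lo <- c(rep(0L, row$b0), rep(1L, row$b1), rep(2L, row$b2),
                rep(3L, row$bgt2))
        hi <- c(rep(0L, row$b0), rep(1L, row$b1), rep(2L, row$b2),
                rep(2L * k_max, row$bgt2))
        af[[r]] <- .emFitCensored(lo, hi, kmax = k_max)
      } else {
        # no published distribution: diploid default
        base <- if (r %in% combinedRegions()) 4L else 2L
        af[[r]] <- .emFitCensored(rep(base, n), rep(base, n), kmax = k_max)
      }
    }
    mdl <- new("PopulationModel", name = preset, mode = "independent",
               alleleFreqs = af, haplotypes = matrix(integer(), 0, 0),
               hapFreqs = numeric(), deNovoRate = de_novo_rate)
  } else if (is.list(preset) && !is.null(preset$haplotypes)) {
    hap <- as.matrix(preset$haplotypes)
    storage.mode(hap) <- "integer"
    mdl <- new("PopulationModel", name = "custom", mode = "table",
               alleleFreqs = list(), haplotypes = hap,
               hapFreqs = as.numeric(preset$freqs),
               deNovoRate = de_novo_rate)
  } else if (is.list(preset)) {
    .stopIf(is.null(names(preset)) || !all(names(preset) %in% smnRegions()),
            "explicit frequency lists must be named by SMN-region label")
    af <- lapply(preset, function(f) {
      .stopIf(abs(sum(f) - 1) > 1e-9, "frequencies do not sum to 1")
      if (is.null(names(f))) names(f) <- as.character(seq_along(f) - 1)
      f
    })
    # unspecified regions: diploid point mass
    for (r in setdiff(smnRegions(), names(af))) {
      base <- if (r %in% combinedRegions()) 2L else 1L
      f <- setNames(rep(0, k_max + 1), as.character(0:k_max))
      f[as.character(base)] <- 1
      af[[r]] <- f
    }
    mdl <- new("PopulationModel", name = "custom", mode = "independent",
               alleleFreqs = af[smnRegions()], haplotypes = matrix(integer(), 0, 0),
               hapFreqs = numeric(), deNovoRate = de_novo_rate)
  } else stop("preset must be a name or a frequency specification")
  validObject(mdl)
  mdl
}

# draw one haplotype (named integer vector over smnRegions())
.sampleHaplotype <- function(model) {
  if (model@mode == "table") {
    i <- sample.int(length(model@hapFreqs), 1, prob = model@hapFreqs)
    h <- model@haplotypes[i, ]
    return(setNames(as.integer(h), colnames(model@haplotypes)))
  }
  vapply(model@alleleFreqs, function(f)
    sample.int(length(f), 1, prob = f) - 1L, integer(1))
}

#' Draw one diplotype from a population model
#'
#' Two independent haplotype draws from the pool (random mating under
#' Hardy-Weinberg). Uses the current RNG stream; call \code{set.seed} for
#' reproducibility.
#'
#' @param model a \linkS4class{PopulationModel}.
#' @return list with named integer vectors \code{mat} and \code{pat} over
#'   the SMN-region labels.
#' @export
sampleDiplotype <- function(model) {
  list(mat = .sampleHaplotype(model), pat = .sampleHaplotype(model))
}

#' Simulate diploid copy-number totals for a cohort
#'
#' @param model a \linkS4class{PopulationModel}.
#' @param n number of individuals.
#' @param prefix sample-id prefix.
#' @return list with \code{totals} (integer matrix regions x n) and
#'   \code{diplotypes} (list of n diplotypes).
#' @export
simulateCohort <- function(model, n, prefix = "S") {
  dips <- replicate(n, sampleDiplotype(model), simplify = FALSE)
  tot <- vapply(dips, function(d) d$mat + d$pat,
                integer(length(smnRegions())))
  rownames(tot) <- smnRegions()
  colnames(tot) <- sprintf("%s%04d", prefix, seq_len(n))
  list(totals = tot, diplotypes = setNames(dips, colnames(tot)))
}

# apply one random de novo event to a haplotype; returns list(hap, record)
.applyDeNovoEvent <- function(hap, k_max = 6) {
  for (try in 1:100) {
    if (stats::runif(1) < 0.5) {
      r <- sample(smnRegions(), 1)
      delta <- sample(c(-1L, 1L), 1)
      if (hap[r] + delta < 0 || hap[r] + delta > k_max) next
      hap[r] <- hap[r] + delta
      return(list(hap = hap,
                  rec = data.frame(region = r,
                                   type = if (delta > 0) "gain" else "loss",
                                   delta = delta)))
    } else {
      if (hap["SMN1_e7"] < 1 || hap["SMN2_e7"] >= k_max) next
      hap["SMN1_e7"] <- hap["SMN1_e7"] - 1L
      hap["SMN2_e7"] <- hap["SMN2_e7"] + 1L
      return(list(hap = hap,
                  rec = data.frame(region = "SMN1_e7", type = "conversion",
                                   delta = -1L)))
    }
  }
  list(hap = hap, rec = NULL)
}

#' Simulate one nuclear family
#'
#' Draws two founders from the population model and transmits one uniformly
#' chosen haplotype from each parent to every child. With probability
#' \code{deNovoRate(model)} per transmitted haplotype, a de novo event is
#' applied: a one-copy gain or loss at a uniformly chosen region, or an
#' SMN1-to-SMN2 exon-7 conversion (one copy moves from SMN1_e7 to SMN2_e7),
#' the event class chosen uniformly. All true diplotypes and events are
#' recorded.
#'
#' @param model a \linkS4class{PopulationModel}.
#' @param n_children number of children (>= 1).
#' @param family_id family identifier.
#' @return a \linkS4class{Pedigree} carrying true diplotypes and the event
#'   log.
#' @export
simulatePedigree <- function(model, n_children = 1, family_id = "FAM1") {
  .stopIf(n_children < 1, "n_children must be >= 1")
  fa <- sampleDiplotype(model)
  mo <- sampleDiplotype(model)
  members <- data.frame(
    member_id = c("FA", "MO", sprintf("C%d", seq_len(n_children))),
    father_id = c(NA, NA, rep("FA", n_children)),
    mother_id = c(NA, NA, rep("MO", n_children)),
    sex = c("M", "F", rep(NA_character_, n_children)),
    stringsAsFactors = FALSE)
  dips <- list(FA = fa, MO = mo)
  events <- data.frame(member_id = character(), parent = character(),
                       region = character(), type = character(),
                       delta = integer(), stringsAsFactors = FALSE)
  for (ci in seq_len(n_children)) {
    cid <- sprintf("C%d", ci)
    hp <- if (stats::runif(1) < 0.5) fa$mat else fa$pat
    hm <- if (stats::runif(1) < 0.5) mo$mat else mo$pat
    for (side in c("father", "mother")) {
      if (stats::runif(1) < model@deNovoRate) {
        res <- .applyDeNovoEvent(if (side == "father") hp else hm)
        if (!is.null(res$rec)) {
          if (side == "father") hp <- res$hap else hm <- res$hap
          events <- rbind(events, cbind(member_id = cid, parent = side,
                                        res$rec))
        }
      }
    }
    dips[[cid]] <- list(mat = hm, pat = hp)
    members$sex[members$member_id == cid] <-
      if (stats::runif(1) < 0.5) "M" else "F"
  }
  new("Pedigree", familyId = family_id, members = members,
      diplotypes = dips, events = events)
}

#' Pedigree accessors
#'
#' @param ped a \linkS4class{Pedigree}.
#' @return \code{pedMembers}: the member table; \code{trueTotals}: integer
#'   matrix (members x regions) of true diploid totals, available for
#'   simulated pedigrees; \code{deNovoEvents}: the simulated event log.
#' @export
pedMembers <- function(ped) ped@members

#' @rdname pedMembers
#' @export
trueTotals <- function(ped) {
  .stopIf(!length(ped@diplotypes), "pedigree has no recorded diplotypes")
  t(vapply(ped@diplotypes, function(d) d$mat + d$pat,
           integer(length(smnRegions()))))
}

#' @rdname pedMembers
#' @export
deNovoEvents <- function(ped) ped@events

#' Forward-simulate an MLPA run
#'
#' Generates raw peak signals for a set of true diploid copy-number
#' profiles, inverting the normalization model: each probe's signal is a
#' probe-specific base intensity (drawn once per run, emulating ligation
#' and amplification efficiency) times the ratio of true to expected diploid
#' copies, times multiplicative lognormal noise exp(N(0, noise_sigma^2)).
#' External control samples carry the expected diploid dose at every probe.
#' Q-fragment signals are scaled low (they amplify only when DNA input is
#' insufficient) so simulated samples pass QC by default.
#'
#' @param profiles integer matrix of true diploid totals (regions x
#'   samples), e.g. \code{simulateCohort(...)$totals}, or a single named
#'   vector.
#' @param panel a \linkS4class{ProbePanel}.
#' @param noise_sigma lognormal sigma of the multiplicative signal noise
#'   (default 0.08; 0 gives a noiseless run).
#' @param n_controls number of external control samples (>= 3).
#' @return an \linkS4class{MlpaRun} containing controls plus test samples.
#' @export
simulateMlpaRun <- function(profiles, panel, noise_sigma = 0.08,
                            n_controls = 3) {
  .stopIf(noise_sigma < 0, "noise_sigma must be >= 0")
  .stopIf(n_controls < 3, "normalization needs >= 3 control samples")
  if (is.null(dim(profiles)))
    profiles <- matrix(profiles, ncol = 1,
                       dimnames = list(names(profiles), "S0001"))
  pr <- panel@probes
  npr <- nrow(pr)
  # per-probe amplification efficiency, shared by all samples in the run
  base <- stats::rlnorm(npr, meanlog = log(1000), sdlog = 0.25)
  names(base) <- pr$probe_id
  qsel <- pr$category == "dq_control" & startsWith(pr$region, "QFRAG")
  base[qsel] <- base[qsel] * 0.1

  expectedRatio <- function(totals) {
    r <- rep(1, npr)
    tgt <- pr$category == "smn_target"
    r[tgt] <- totals[pr$region[tgt]] / pr$expected_diploid_copies[tgt]
    r
  }
  ctl_ids <- sprintf("CTRL%02d", seq_len(n_controls))
  smp_ids <- colnames(profiles)
  sig <- matrix(0, nrow = npr, ncol = n_controls + length(smp_ids),
                dimnames = list(pr$probe_id, c(ctl_ids, smp_ids)))
  for (j in seq_len(n_controls))
    sig[, j] <- base * exp(stats::rnorm(npr, 0, noise_sigma))
  for (j in seq_along(smp_ids))
    sig[, n_controls + j] <- base * expectedRatio(profiles[, j]) *
      exp(stats::rnorm(npr, 0, noise_sigma))
  samples <- data.frame(sample_id = colnames(sig),
                        is_control = c(rep(TRUE, n_controls),
                                       rep(FALSE, length(smp_ids))),
                        stringsAsFactors = FALSE)
  new("MlpaRun", panel = panel, signal = sig, samples = samples)
}

#' @rdname makePopulationModel
#' @param model a \linkS4class{PopulationModel}.
#' @export
deNovoRate <- function(model) model@deNovoRate

#' Diploid-total probability mass function of a model region
#'
#' Probability distribution of the diploid copy-number total at one region
#' under the model (the convolution of the per-homolog frequency vector
#' with itself, for independent-mode models).
#'
#' @param model a \linkS4class{PopulationModel} in independent mode.
#' @param region region label.
#' @return named numeric vector over totals 0..2*k_max.
#' @export
diploidTotalPmf <- function(model, region) {
  .stopIf(model@mode != "independent",
          "total pmf is defined for independent-mode models")
  f <- model@alleleFreqs[[region]]
  .stopIf(is.null(f), "model has no region '", region, "'")
  k <- length(f) - 1
  p <- rep(0, 2 * k + 1)
  for (a in 0:k) for (b in 0:k) p[a + b + 1] <- p[a + b + 1] + f[a + 1] * f[b + 1]
  setNames(p, as.character(0:(2 * k)))
}
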