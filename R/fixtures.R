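# Deterministic packaged-style fixtures mirroring the published cohort
# tables and the 61-family pedigree set.

#' Write deterministic validation fixtures
#'
#' Generates, with fixed seeds, (a) one copy-number cohort file per
#' published study group whose per-region 0/1/2/>2 bin counts equal the
#' published rows exactly (the ">2" bin expanded deterministically as threes
#' except one four per ten samples), and (b) a 61-family trio pedigree
#' fixture in which exactly two families carry one planted
#' Mendelian-inconsistent transmission each (a de novo one-copy gain at
#' SMN2_e7 against two zero-copy parents), matching a 3.3\% (2/61)
#' family-level event rate.
#'
#' Regions without a published distribution are filled with the diploid
#' state. Cohort files are copy-number TSVs (sample_id + one column per
#' region); the pedigree fixture is a PED-style text file plus a companion
#' copy-number TSV of the true totals. A JSON manifest lists files and
#' seeds.
#'
#' @param out_dir destination directory (created if needed).
#' @param seed base seed for the pedigree founder draws (default 104729).
#' @return (invisibly) the manifest as a list.
#' @export
makeFixtures <- function(out_dir, seed = 104729) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .stopIf(file.access(out_dir, 2) != 0, "destination not writable: ", out_dir)
  bins <- .cohortBins()
  files <- character()

  for (grp in names(.cohortGroupSizes)) {
    n <- .cohortGroupSizes[[grp]]
    cn <- matrix(NA_integer_, nrow = n, ncol = length(smnRegions()),
                 dimnames = list(NULL, smnRegions()))
    for (r in smnRegions()) {
      row <- bins[bins$group == grp & bins$region == r, , drop = FALSE]
      if (nrow(row) == 1) {
        cn[, r] <- .binTotals(row$b0, row$b1, row$b2, row$bgt2)
      } else {
        cn[, r] <- if (r %in% combinedRegions()) 4L else 2L
      }
    }
    df <- data.frame(sample_id = sprintf("%s_%03d", grp, seq_len(n)), cn,
                     check.names = FALSE)
    f <- file.path(out_dir, sprintf("cohort_%s.tsv", grp))
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }

  ped <- .withSeed(seed, .makePedigreeFixture())
  pedfile <- file.path(out_dir, "families.ped")
  cnfile <- file.path(out_dir, "families_cn.tsv")
  utils::write.table(ped$ped, pedfile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ped$cn, cnfile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, pedfile, cnfile)

  manifest <- list(files = basename(files), seed = seed,
                   n_families = 61L, planted_event_families = ped$planted,
                   groups = as.list(.cohortGroupSizes))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# 61 trio families from the black_SA pool; families 17 and 42 get a planted
# +1 de novo gain at SMN2_e7 on a transmitted haplotype, made strictly
# Mendelian-inconsistent by forcing both parents to zero copies there.
.makePedigreeFixture <- function() {
  model <- makePopulationModel("black_SA", de_novo_rate = 0)
  planted <- c(17L, 42L)
  pedrows <- list()
  cnrows <- list()
  for (i in seq_len(61)) {
    fid <- sprintf("FAM%02d", i)
    ped <- simulatePedigree(model, n_children = 1, family_id = fid)
    dips <- ped@diplotypes
    if (i %in% planted) {
      for (m in names(dips)) {
        dips[[m]]$mat["SMN2_e7"] <- 0L
        dips[[m]]$pat["SMN2_e7"] <- 0L
      }
      dips[["C1"]]$pat["SMN2_e7"] <- 1L  # de novo gain on the paternal copy
    }
    m <- ped@members
    m$family_id <- fid
    m$role <- c("father", "mother", "child")
    m$father_id[is.na(m$father_id)] <- "0"
    m$mother_id[is.na(m$mother_id)] <- "0"
    m$sexcode <- ifelse(m$sex == "M", 1L, 2L)
    uid <- paste(fid, m$member_id, sep = "_")
    pedrows[[i]] <- data.frame(
      family_id = fid, member_id = uid,
      father_id = ifelse(m$father_id == "0", "0",
                         paste(fid, m$father_id, sep = "_")),
      mother_id = ifelse(m$mother_id == "0", "0",
                         paste(fid, m$mother_id, sep = "_")),
      sex = m$sexcode, role = m$role, stringsAsFactors = FALSE)
    tot <- t(vapply(dips, function(d) d$mat + d$pat,
                    integer(length(smnRegions()))))
    cnrows[[i]] <- data.frame(sample_id = uid, tot, check.names = FALSE,
                              row.names = NULL)
  }
  list(ped = do.call(rbind, pedrows), cn = do.call(rbind, cnrows),
       planted = sprintf("FAM%02d", planted))
}
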