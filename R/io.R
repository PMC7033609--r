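# Readers/writers for the pipeline's tabular formats, and the pipeline
# driver with provenance blocks.

.readTable <- function(path, csv = FALSE) {
  .stopIf(!file.exists(path), "file not found: ", path)
  .stopIf(file.size(path) == 0, "empty file: ", path)
  utils::read.delim(path, sep = if (csv) "," else "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read an MLPA export
#'
#' Reads a long-format MLPA export (TSV with columns \code{sample_id},
#' \code{probe_id}, \code{signal}) into an \linkS4class{MlpaRun}. Control
#' samples are flagged through an optional samples manifest (TSV with
#' columns \code{sample_id}, \code{is_control}); without one, no sample is
#' marked as control. Every panel probe must be present for every sample.
#'
#' @param path export file path.
#' @param panel a \linkS4class{ProbePanel}.
#' @param manifest optional manifest path.
#' @param csv read comma-separated input instead of tab-separated.
#' @return an \linkS4class{MlpaRun}.
#' @export
readMlpaExport <- function(path, panel, manifest = NULL, csv = FALSE) {
  df <- .readTable(path, csv)
  need <- c("sample_id", "probe_id", "signal")
  .stopIf(!all(need %in% names(df)),
          "export must have columns sample_id, probe_id, signal")
  pid <- panel@probes$probe_id
  unknown <- setdiff(unique(df$probe_id), pid)
  .stopIf(length(unknown) > 0,
          "unknown probe_id(s): ", paste(unknown, collapse = ", "))
  samples <- unique(df$sample_id)
  sig <- matrix(NA_real_, nrow = length(pid), ncol = length(samples),
                dimnames = list(pid, samples))
  sig[cbind(match(df$probe_id, pid), match(df$sample_id, samples))] <-
    df$signal
  if (anyNA(sig)) {
    miss <- which(is.na(sig), arr.ind = TRUE)
    stop("missing probe signal(s): ",
         paste(sprintf("%s/%s", colnames(sig)[miss[, 2]],
                       rownames(sig)[miss[, 1]]), collapse = ", "),
         call. = FALSE)
  }
  man <- data.frame(sample_id = samples, is_control = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(manifest)) {
    md <- .readTable(manifest, csv)
    .stopIf(!all(c("sample_id", "is_control") %in% names(md)),
            "manifest must have columns sample_id, is_control")
    man$is_control <- as.logical(md$is_control[
      match(man$sample_id, md$sample_id)])
    man$is_control[is.na(man$is_control)] <- FALSE
    if (!is.null(md$sex)) man$sex <- md$sex[match(man$sample_id,
                                                  md$sample_id)]
  }
  new("MlpaRun", panel = panel, signal = sig, samples = man)
}

#' @rdname readMlpaExport
#' @param run an \linkS4class{MlpaRun} to serialize.
#' @export
writeMlpaExport <- function(run, path, manifest = NULL) {
  df <- data.frame(
    sample_id = rep(colnames(run@signal), each = nrow(run@signal)),
    probe_id = rep(rownames(run@signal), ncol(run@signal)),
    signal = as.vector(run@signal))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(manifest))
    utils::write.table(run@samples, manifest, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read / write copy-number tables
#'
#' Copy-number TSVs have a \code{sample_id} column plus one integer column
#' per region label.
#'
#' @param path file path.
#' @param csv comma-separated instead of tab-separated.
#' @return \code{readCopyNumbers}: integer matrix regions x samples.
#' @export
readCopyNumbers <- function(path, csv = FALSE) {
  df <- .readTable(path, csv)
  .stopIf(is.null(df$sample_id), "copy-number table needs sample_id column")
  .asRegionMatrix(df)
}

#' @rdname readCopyNumbers
#' @param cnset a \linkS4class{CopyNumberSet} or regions x samples matrix.
#' @export
writeCopyNumbers <- function(cnset, path) {
  cn <- if (is(cnset, "CopyNumberSet")) copyNumbers(cnset) else cnset
  df <- data.frame(sample_id = colnames(cn), t(cn), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read PED-style pedigree files
#'
#' Whitespace-delimited text with columns family_id, member_id, father_id,
#' mother_id, sex and (optionally) role; \code{0} marks a missing parent.
#' Families are partitioned by family_id; parent links must resolve within
#' the family and must be acyclic. Singleton families are allowed (phasing
#' will refuse them later).
#'
#' @param path PED file path.
#' @return named list of \linkS4class{Pedigree} objects.
#' @export
readPedigree <- function(path) {
  .stopIf(!file.exists(path), "file not found: ", path)
  hasHeader <- grepl("family_id", readLines(path, n = 1))
  df <- utils::read.table(path, header = hasHeader, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!hasHeader) {
    .stopIf(ncol(df) < 5, "PED file needs at least 5 columns")
    names(df)[1:5] <- c("family_id", "member_id", "father_id", "mother_id",
                        "sex")
    if (ncol(df) >= 6) names(df)[6] <- "role"
  }
  df$father_id <- as.character(df$father_id)
  df$mother_id <- as.character(df$mother_id)
  df$member_id <- as.character(df$member_id)
  df$father_id[df$father_id == "0"] <- NA
  df$mother_id[df$mother_id == "0"] <- NA
  peds <- lapply(split(df, df$family_id), function(fam) {
    new("Pedigree", familyId = as.character(fam$family_id[1]),
        members = data.frame(member_id = fam$member_id,
                             father_id = fam$father_id,
                             mother_id = fam$mother_id,
                             sex = as.character(fam$sex),
                             stringsAsFactors = FALSE),
        diplotypes = list(),
        events = data.frame())
  })
  peds[unique(df$family_id)]
}

# ---- pipeline driver --------------------------------------------------------

.defaultConfig <- function() {
  list(panel = "P021", mode = "rounding", tol = 0.05,
       q_frac = 0.5, d_frac = 0.3, preset = "black_SA", n = 100,
       families = 0, seed = 1, alpha = 0.05, max_events = 1,
       noise_sigma = 0.08, n_controls = 3, out_dir = ".",
       group = "cohort")
}

# provenance sidecar: tool version, config hash, input digests
.writeProvenance <- function(artifact, config, inputs = character()) {
  cfg <- config[order(names(config))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  prov <- list(
    tool = "SMNcnv",
    version = as.character(utils::packageVersion("SMNcnv")),
    config = cfg,
    config_hash = unname(tools::md5sum(tmp)),
    inputs = as.list(unname(tools::md5sum(inputs[file.exists(inputs)]))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, paste0(artifact, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(prov)
}

#' Run one pipeline stage
#'
#' File-level driver tying the package together: \code{simulate} writes a
#' simulated cohort (and optionally families), \code{call} normalizes an
#' MLPA export and writes DQ, copy-number and QC tables, \code{classify}
#' adds genotype labels to a copy-number table, \code{phase} phases a PED
#' file against a copy-number table, \code{risk} writes a carrier-risk
#' table, \code{summarize} writes a cohort summary and \code{compare}
#' writes per-region cohort tests. Every artifact receives a provenance
#' sidecar (tool version, config hash, input digests). With a fixed
#' \code{seed} the run is deterministic.
#'
#' @param config named list overriding the defaults (panel, mode, tol,
#'   preset, n, families, seed, alpha, max_events, noise_sigma, out_dir,
#'   group, plus per-command input paths: \code{export}, \code{manifest},
#'   \code{cn}, \code{cn_b}, \code{ped}, \code{freqs}), or a path to a
#'   YAML/JSON file with the same keys.
#' @param command one of \code{"simulate"}, \code{"call"},
#'   \code{"classify"}, \code{"phase"}, \code{"risk"}, \code{"summarize"},
#'   \code{"compare"}.
#' @return (invisibly) character vector of written artifact paths.
#' @export
runPipeline <- function(config = list(), command) {
  command <- match.arg(command, c("simulate", "call", "classify", "phase",
                                  "risk", "summarize", "compare"))
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(.defaultConfig(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(path, inputs = character()) {
    .writeProvenance(path, cfg, inputs)
    written <<- c(written, path)
    path
  }
  res <- tryCatch(switch(command,
    simulate = {
      set.seed(cfg$seed)
      model <- makePopulationModel(cfg$preset)
      sim <- simulateCohort(model, cfg$n)
      writeCopyNumbers(sim$totals,
                       emit(file.path(cfg$out_dir, "simulated_cn.tsv")))
      if (cfg$families > 0) {
        peds <- lapply(seq_len(cfg$families), function(i)
          simulatePedigree(model, 1, sprintf("FAM%03d", i)))
        pedrows <- do.call(rbind, lapply(peds, function(p) {
          m <- p@members
          data.frame(family_id = p@familyId,
                     member_id = paste(p@familyId, m$member_id, sep = "_"),
                     father_id = ifelse(is.na(m$father_id), "0",
                                        paste(p@familyId, m$father_id,
                                              sep = "_")),
                     mother_id = ifelse(is.na(m$mother_id), "0",
                                        paste(p@familyId, m$mother_id,
                                              sep = "_")),
                     sex = ifelse(m$sex == "M", 1L, 2L),
                     role = c("father", "mother",
                              rep("child", nrow(m) - 2)))
        }))
        utils::write.table(pedrows,
                           emit(file.path(cfg$out_dir, "simulated.ped")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        cnrows <- do.call(rbind, lapply(peds, function(p) {
          tt <- trueTotals(p)
          data.frame(sample_id = paste(p@familyId, rownames(tt), sep = "_"),
                     tt, check.names = FALSE, row.names = NULL)
        }))
        utils::write.table(cnrows,
                           emit(file.path(cfg$out_dir,
                                          "simulated_families_cn.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      written
    },
    call = {
      panel <- loadPanel(cfg$panel)
      run <- readMlpaExport(cfg$export, panel, cfg$manifest)
      ds <- normalizeRun(run, list(q_frac = cfg$q_frac, d_frac = cfg$d_frac))
      cns <- callProfiles(ds, mode = cfg$mode, tol = cfg$tol)
      dqdf <- data.frame(sample_id = colnames(ds@dq), t(ds@dq),
                         check.names = FALSE)
      utils::write.table(dqdf, emit(file.path(cfg$out_dir, "dq.tsv"),
                                    c(cfg$export)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeCopyNumbers(cns, emit(file.path(cfg$out_dir, "cn.tsv"),
                                 c(cfg$export)))
      jsonlite::write_json(
        list(mode = cfg$mode, tol = cfg$tol, qc = ds@qc,
             borderline = apply(borderlineCalls(cns), 2,
                                function(z) rownames(cns@borderline)[z],
                                simplify = FALSE)),
        emit(file.path(cfg$out_dir, "qc_report.json"), c(cfg$export)),
        auto_unbox = TRUE, pretty = TRUE)
      written
    },
    classify = {
      cn <- readCopyNumbers(cfg$cn)
      lab <- classifyGenotype(cn["SMN1_e7", ], cn["SMN2_e7", ])
      utils::write.table(
        data.frame(sample_id = colnames(cn), genotype = lab,
                   row.names = NULL),
        emit(file.path(cfg$out_dir, "genotypes.tsv"), cfg$cn),
        sep = "\t", quote = FALSE, row.names = FALSE)
      written
    },
    phase = {
      peds <- readPedigree(cfg$ped)
      cn <- readCopyNumbers(cfg$cn)
      reps <- phaseFamilies(peds, t(cn), max_events = cfg$max_events)
      out <- lapply(reps, function(r) list(
        family_id = r@familyId, status = r@status,
        n_feasible = as.list(r@nFeasible),
        events = lapply(r@events, function(e)
          e[, c("member_id", "parent", "region", "type")]),
        notes = r@notes))
      jsonlite::write_json(out,
        emit(file.path(cfg$out_dir, "phase_reports.json"),
             c(cfg$ped, cfg$cn)), auto_unbox = TRUE, pretty = TRUE)
      jsonlite::write_json(deNovoRateReport(reps),
        emit(file.path(cfg$out_dir, "de_novo_rate.json"),
             c(cfg$ped, cfg$cn)), auto_unbox = TRUE, pretty = TRUE)
      written
    },
    risk = {
      cn <- readCopyNumbers(cfg$cn)
      freqs <- if (!is.null(cfg$freqs))
        unlist(jsonlite::read_json(cfg$freqs, simplifyVector = TRUE))
      else estimateAlleleFreqs(cn["SMN1_e7", ])
      tab <- carrierRiskTable(cn, freqs, region = "SMN1_e7")
      utils::write.table(tab, emit(file.path(cfg$out_dir,
                                             "carrier_risk.tsv"), cfg$cn),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(as.list(freqs),
        emit(file.path(cfg$out_dir, "allele_freqs.json"), cfg$cn),
        auto_unbox = TRUE, pretty = TRUE)
      written
    },
    summarize = {
      cn <- readCopyNumbers(cfg$cn)
      summ <- cohortPercentages(summarizeCohort(cn, cfg$group))
      utils::write.table(summ, emit(file.path(cfg$out_dir, "summary.tsv"),
                                    cfg$cn),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      written
    },
    compare = {
      a <- readCopyNumbers(cfg$cn)
      b <- readCopyNumbers(cfg$cn_b)
      res <- compareGroups(a, b, alpha = cfg$alpha)
      utils::write.table(res, emit(file.path(cfg$out_dir, "compare.tsv"),
                                   c(cfg$cn, cfg$cn_b)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      written
    }),
    error = function(e) stop(command, ": ", conditionMessage(e),
                             call. = FALSE))
  invisible(res)
}
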