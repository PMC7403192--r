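## One-call orchestration: simulate or ingest -> annotate -> cells ->
## clones/clonotypes -> statistics -> overlap/search, with a manifest.

#' Validate a pipeline configuration
#'
#' Returns findings rather than raising errors; an empty result means the
#' configuration is runnable. Checked: exactly one input mode among
#' `fasta`, `rearrangements` and `simulate`; existence of every referenced
#' path (germline, inputs, control tables); presence of a numeric seed;
#' and, for simulate mode, the full simulation config (usage vector sums,
#' planted clone references, rate ranges).
#'
#' @param config named list (see [runPipeline()]) or path to a YAML file.
#' @return character vector of findings, each naming the offending field.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  f <- character()
  modes <- c("fasta", "rearrangements", "simulate")
  set_modes <- modes[!vapply(config[modes], is.null, logical(1))]
  if (length(set_modes) != 1) {
    f <- c(f, paste0("input mode: exactly one of fasta/rearrangements/simulate",
                     " must be set (found: ",
                     if (length(set_modes)) paste(set_modes, collapse = ", ")
                     else "none", ")"))
  }
  if (is.null(config$seed) || !is.numeric(config$seed))
    f <- c(f, "seed: a numeric seed is required")
  db <- NULL
  if (!is.null(config$germline)) {
    for (part in c("fasta", "anchors")) {
      p <- config$germline[[part]]
      if (is.null(p) || !file.exists(p))
        f <- c(f, paste0("germline$", part, ": file not found"))
    }
    if (!length(f) || !any(grepl("^germline", f)))
      db <- tryCatch(readGermlineFasta(config$germline$fasta,
                                       config$germline$anchors),
                     error = function(e) { NULL })
    if (is.null(db) && !any(grepl("^germline", f)))
      f <- c(f, "germline: reference failed to load")
  } else {
    db <- syntheticGermline()
  }
  for (field in c("fasta", "rearrangements")) {
    for (p in config[[field]]) {
      if (!file.exists(p)) f <- c(f, paste0(field, ": file not found: ", p))
    }
  }
  for (ctl in config$controls) {
    if (is.null(ctl$path) || !file.exists(ctl$path))
      f <- c(f, "controls: path not found")
    if (!is.null(ctl$dialect) && !ctl$dialect %in% c("airr", "mixcr"))
      f <- c(f, paste0("controls: unknown dialect: ", ctl$dialect))
  }
  if ("simulate" %in% set_modes && !is.null(db)) {
    sim <- tryCatch(do.call(simulationConfig, config$simulate),
                    error = function(e) NULL)
    if (is.null(sim)) f <- c(f, "simulate: invalid simulation parameters")
    else f <- c(f, validateSimConfig(sim, db))
  }
  if (!is.null(config$match_level) &&
      !config$match_level %in% c("allele", "gene"))
    f <- c(f, "match_level: must be 'allele' or 'gene'")
  f
}

## patient/cell metadata from ids of the form <patient>_<cell>_<chain...>
.idsToMeta <- function(ids) {
  parts <- strsplit(ids, "_")
  ok <- lengths(parts) >= 3
  data.frame(patient_id = ifelse(ok, vapply(parts, `[`, "", 1), NA),
             cell_id = ifelse(ok, vapply(parts, function(p)
               paste(p[1:2], collapse = "_"), ""), NA),
             stringsAsFactors = FALSE)
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  path
}

#' Run the full repertoire analysis pipeline
#'
#' Executes, in order: input (simulation, FASTA annotation, or a
#' pre-annotated AIRR rearrangement TSV), cell assembly and completeness,
#' clonal clustering and common-clone detection, shared paired-chain
#' clonotypes, repertoire statistics, and (when configured) control-cohort
#' overlap and CDR3 search. Every stage writes a TSV into `out_dir` and is
#' recorded, with its row count, in `manifest.json`; the run is a
#' deterministic function of config + seed. A stage failure writes the
#' manifest with the failed stage marked and then raises the error.
#'
#' Config fields: one of `fasta` (paths), `rearrangements` (path),
#' `simulate` (arguments to [simulationConfig()]); optional `germline`
#' (`fasta` + `anchors` paths; default bundled synthetic reference),
#' `annotation` (arguments to [annotationParams()]), `match_level`,
#' `min_patients`, `controls` (list of `name`/`path`/`dialect`),
#' `search_cdr3` (targets), `seed`, `out_dir`.
#'
#' @param config named list or path to a YAML config file.
#' @param out_dir output directory (default `config$out_dir`).
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  findings <- validateConfig(config)
  if (length(findings))
    stop("invalid configuration:\n  ", paste(findings, collapse = "\n  "))
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  db <- if (is.null(config$germline)) syntheticGermline()
        else readGermlineFasta(config$germline$fasta, config$germline$anchors)
  params <- do.call(annotationParams,
                    if (is.null(config$annotation)) list() else config$annotation)
  level <- if (is.null(config$match_level)) "allele" else config$match_level
  min_patients <- if (is.null(config$min_patients)) 2 else config$min_patients

  manifest <- list(seed = config$seed,
                   match_level = level, min_patients = min_patients,
                   germline_md5 = unname(md5sum(
                     if (is.null(config$germline))
                       system.file("extdata", "germline",
                                   "synthetic_germline.fasta",
                                   package = "repclone")
                     else config$germline$fasta)),
                   stages = list(), files = list())
  add_file <- function(name, path, rows) {
    manifest$files[[name]] <<- list(file = basename(path), rows = rows)
  }
  finish_stage <- function(name) {
    manifest$stages[[name]] <<- "ok"
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- paste("failed:", conditionMessage(e))
      write_manifest()
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  set.seed(config$seed)

  ## --- input + annotation -------------------------------------------------
  records <- run_stage("input", {
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- config$seed
      sim <- simulateCohort(do.call(simulationConfig, sim_args), db,
                            out_dir = file.path(out_dir, "simulated"))
      meta <- .idsToMeta(names(sim$sequences))
      rec <- annotateVdj(sim$sequences, db, params,
                         patient_id = meta$patient_id,
                         cell_id = meta$cell_id, verbose = FALSE)
      finish_stage("input")
      rec
    } else if (!is.null(config$fasta)) {
      seqs <- unlist(lapply(config$fasta, function(p) {
        s <- Biostrings::readDNAStringSet(p)
        setNames(as.character(s), sub("\\s.*$", "", names(s)))
      }))
      meta <- .idsToMeta(names(seqs))
      rec <- annotateVdj(seqs, db, params, patient_id = meta$patient_id,
                         cell_id = meta$cell_id, verbose = FALSE)
      finish_stage("input")
      rec
    } else {
      rec <- readRearrangements(config$rearrangements)
      finish_stage("input")
      rec
    }
  })
  rpath <- .writeTsv(records[, setdiff(names(records), "sequence")],
                     file.path(out_dir, "rearrangements.tsv"))
  add_file("rearrangements", rpath, nrow(records))
  message(sprintf("input: %d chain records (%d productive)",
                  nrow(records), sum(records$productive)))

  ## --- cells --------------------------------------------------------------
  cells <- run_stage("cells", {
    cs <- assembleCells(records)
    finish_stage("cells")
    cs
  })
  add_file("cells", .writeTsv(cellInfo(cells), file.path(out_dir, "cells.tsv")),
           nCells(cells))
  message(sprintf("cells: %d assembled (%d complete)", nCells(cells),
                  sum(cellInfo(cells)$completeness == "complete")))

  ## --- clones -------------------------------------------------------------
  clones <- run_stage("clones", {
    cl <- suppressMessages(clusterClones(records, level = level))
    finish_stage("clones")
    cl
  })
  add_file("clones", .writeTsv(clones, file.path(out_dir, "clones.tsv")),
           nrow(clones))
  common <- findCommonClones(clones, min_patients = min_patients)
  add_file("common_clones",
           .writeTsv(common, file.path(out_dir, "common_clones.tsv")),
           nrow(common))

  ## --- clonotypes ---------------------------------------------------------
  clonotypes <- run_stage("clonotypes", {
    ct <- findSharedClonotypes(cells, min_patients = min_patients,
                               level = level)
    finish_stage("clonotypes")
    ct
  })
  add_file("clonotypes",
           .writeTsv(clonotypes, file.path(out_dir, "clonotypes.tsv")),
           nrow(clonotypes))

  ## --- statistics ---------------------------------------------------------
  run_stage("stats", {
    heavy <- records[records$locus == "IGH" & records$productive, , drop = FALSE]
    for (ty in c("V", "D", "J")) {
      if (nrow(heavy) == 0) break
      u <- geneUsage(heavy, ty, level = "family", zero_fill = db,
                     locus = "IGH")
      add_file(paste0("usage_", ty),
               .writeTsv(u, file.path(out_dir, paste0("usage_", ty, ".tsv"))),
               nrow(u))
    }
    if (nrow(heavy)) {
      m <- vjMatrix(heavy, level = "allele")
      mdf <- data.frame(v_call = rownames(m), m, check.names = FALSE)
      add_file("vj_matrix",
               .writeTsv(mdf, file.path(out_dir, "vj_matrix.tsv")), nrow(mdf))
      cl3 <- cdr3LengthDistribution(heavy)
      add_file("cdr3_lengths",
               .writeTsv(cl3$histogram, file.path(out_dir, "cdr3_lengths.tsv")),
               nrow(cl3$histogram))
      manifest$cdr3_length <- list(modes = cl3$modes,
                                    shapiro_w = cl3$shapiro_w,
                                    shapiro_p = cl3$shapiro_p)
      if ("v_mutation_count" %in% names(heavy)) {
        mr <- suppressMessages(mutationRateSummary(heavy))
        add_file("mutation_rates",
                 .writeTsv(mr$rates, file.path(out_dir, "mutation_rates.tsv")),
                 mr$n)
        manifest$mutation_rate_summary <- as.list(mr$summary)
      }
    }
    lights <- records[records$locus %in% c("IGK", "IGL"), , drop = FALSE]
    if (nrow(lights))
      manifest$light_chain_classes <- lightChainClassCounts(lights)
    finish_stage("stats")
  })

  ## --- control overlap + CDR3 search --------------------------------------
  run_stage("controls", {
    if (length(config$controls)) {
      key_self <- cloneKeys(clones[clones$locus == "IGH", , drop = FALSE],
                            level = level)
      ov_rows <- list()
      for (ctl in config$controls) {
        tab <- readClonotypeTable(ctl$path, ctl$dialect)
        ov <- overlapCounts(key_self, cloneKeys(tab, level = level))
        ov_rows[[length(ov_rows) + 1L]] <- data.frame(
          control = ctl$name, cohort_only = ov$a_only,
          control_only = ov$b_only, shared = ov$shared,
          stringsAsFactors = FALSE)
      }
      ovdf <- do.call(rbind, ov_rows)
      add_file("overlap", .writeTsv(ovdf, file.path(out_dir, "overlap.tsv")),
               nrow(ovdf))
    }
    if (length(config$search_cdr3)) {
      rows <- list()
      for (target in config$search_cdr3) {
        rows[[length(rows) + 1L]] <- data.frame(
          target = target, repertoire = "cohort",
          n_hits = nrow(searchCdr3(target, records)), stringsAsFactors = FALSE)
        for (ctl in config$controls) {
          tab <- readClonotypeTable(ctl$path, ctl$dialect)
          rows[[length(rows) + 1L]] <- data.frame(
            target = target, repertoire = ctl$name,
            n_hits = nrow(searchCdr3(target, tab)), stringsAsFactors = FALSE)
        }
      }
      srch <- do.call(rbind, rows)
      add_file("search", .writeTsv(srch, file.path(out_dir, "search.tsv")),
               nrow(srch))
    }
    finish_stage("controls")
  })

  write_manifest()
  invisible(manifest)
}
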