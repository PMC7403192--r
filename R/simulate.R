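## Ground-truthed V(D)J recombination simulator: multi-patient paired-chain
## single-cell cohorts with skewed segment usage, junctional trimming and
## untemplated N insertion, per-site SHM, planted convergent clones and a
## configurable fraction of incomplete cells.

.NT <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Defaults model the study conditions the package targets: a 12-patient
#' cohort of CSF single B cells with few cells per patient, strongly skewed
#' segment usage, hypomutated sequences (low per-site SHM), lambda-skewed
#' light chains, and a modest fraction of incomplete cells.
#'
#' @param n_patients number of patients.
#' @param cells_per_patient cells per patient (scalar or one value per
#'   patient).
#' @param usage per-locus segment usage probabilities:
#'   `list(IGH = list(V = c(...), D = ..., J = ...), IGK = ..., IGL = ...)`
#'   with named probability vectors summing to 1. `NULL` uses a geometric
#'   (2-fold per rank) skew over the germline alleles in alphabetical
#'   order.
#' @param trim_max maximum exonuclease trimming (nt) at the 3'V, 5'D, 3'D
#'   and 5'J ends (capped so conserved anchors survive).
#' @param n_insert_max maximum untemplated N nucleotides per junction side.
#' @param shm_rate per-site substitution probability, in `[0, 0.2]`.
#' @param productive_fraction fraction of chains forced in-frame by
#'   construction; the remainder are emitted frameshifted to exercise the
#'   functional-sequence filter.
#' @param incomplete_fraction fraction of cells emitted incomplete (whole
#'   chain class dropped, or both classes duplicated as a doublet mimic).
#' @param light_locus_prob named probabilities for the light-chain locus.
#' @param planted_clones list of planted convergent clones, each a list
#'   with `id`, `patients` (character ids like `"P03"`), `cells_each`, and
#'   `heavy`/`light` specs `list(v = , j = , junction = )` where `junction`
#'   is an in-frame, stop-free nucleotide string starting with a cysteine
#'   codon.
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of config + seed.
#' @return classed list (`repclone_sim_config`).
#' @export
simulationConfig <- function(n_patients = 12, cells_per_patient = 8,
                             usage = NULL, trim_max = 4, n_insert_max = 6,
                             shm_rate = 0.005, productive_fraction = 1,
                             incomplete_fraction = 0.15,
                             light_locus_prob = c(IGK = 0.35, IGL = 0.65),
                             planted_clones = list(), seed = 1) {
  structure(list(n_patients = n_patients,
                 cells_per_patient = cells_per_patient, usage = usage,
                 trim_max = trim_max, n_insert_max = n_insert_max,
                 shm_rate = shm_rate,
                 productive_fraction = productive_fraction,
                 incomplete_fraction = incomplete_fraction,
                 light_locus_prob = light_locus_prob,
                 planted_clones = planted_clones, seed = seed),
            class = "repclone_sim_config")
}

.patientIds <- function(n) sprintf("P%02d", seq_len(n))

## geometric skew over alphabetically ordered alleles
.defaultUsage <- function(db) {
  anch <- anchorInfo(db)
  out <- list()
  for (loc in unique(anch$locus)) {
    out[[loc]] <- list()
    for (ty in c("V", "D", "J")) {
      ids <- sort(anch$allele_id[anch$locus == loc & anch$segment_type == ty])
      if (!length(ids)) next
      w <- 2 ^ -(seq_along(ids) - 1)
      out[[loc]][[ty]] <- setNames(w / sum(w), ids)
    }
  }
  out
}

#' Validate a simulation configuration against a germline reference
#'
#' @param config a [simulationConfig()].
#' @param db a [GermlineDb-class].
#' @return character vector of findings; empty when the config is runnable.
#' @export
validateSimConfig <- function(config, db = syntheticGermline()) {
  f <- character()
  ids <- alleleNames(db)
  if (!is.numeric(config$n_patients) || config$n_patients < 1)
    f <- c(f, "n_patients: must be >= 1")
  if (any(config$cells_per_patient < 0))
    f <- c(f, "cells_per_patient: must be >= 0")
  if (config$shm_rate < 0 || config$shm_rate > 0.2)
    f <- c(f, "shm_rate: must be in [0, 0.2]")
  for (p in c("productive_fraction", "incomplete_fraction")) {
    if (config[[p]] < 0 || config[[p]] > 1)
      f <- c(f, paste0(p, ": must be in [0, 1]"))
  }
  if (!is.null(config$usage)) {
    for (loc in names(config$usage)) for (ty in names(config$usage[[loc]])) {
      u <- config$usage[[loc]][[ty]]
      if (abs(sum(u) - 1) > 1e-9)
        f <- c(f, sprintf("usage$%s$%s: probabilities must sum to 1", loc, ty))
      if (!all(names(u) %in% ids))
        f <- c(f, sprintf("usage$%s$%s: unknown allele(s) %s", loc, ty,
                          paste(setdiff(names(u), ids), collapse = ", ")))
    }
  }
  pats <- .patientIds(config$n_patients)
  for (pc in config$planted_clones) {
    tag <- if (is.null(pc$id)) "planted clone" else pc$id
    if (!all(pc$patients %in% pats))
      f <- c(f, paste0(tag, ": patient_ids outside the cohort"))
    for (side in c("heavy", "light")) {
      sp <- pc[[side]]
      if (is.null(sp)) { f <- c(f, paste0(tag, ": missing ", side, " spec")); next }
      if (!all(c(sp$v, sp$j) %in% ids))
        f <- c(f, paste0(tag, ": unknown allele in ", side, " spec"))
      if (nchar(sp$junction) %% 3 != 0)
        f <- c(f, paste0(tag, ": ", side, " junction not in frame"))
      else if (grepl("*", translateNt(sp$junction), fixed = TRUE))
        f <- c(f, paste0(tag, ": ", side, " junction contains a stop codon"))
      else if (substr(translateNt(sp$junction), 1, 1) != "C")
        f <- c(f, paste0(tag, ": ", side, " junction must start with a Cys codon"))
    }
  }
  f
}

#' Apply somatic hypermutation to a sequence
#'
#' Each site is independently substituted with probability `shm_rate` to a
#' uniformly chosen different base. Uses the current R random number
#' stream.
#'
#' @param sequence_nt nucleotide string.
#' @param shm_rate per-site substitution probability in `[0, 0.2]`.
#' @param exclude integer positions never mutated (e.g. a conserved
#'   junction).
#' @return list with `sequence` (mutated string) and `positions` (sorted
#'   1-based mutated positions).
#' @export
applyShm <- function(sequence_nt, shm_rate, exclude = integer()) {
  stopifnot(shm_rate >= 0, shm_rate <= 0.2)
  n <- nchar(sequence_nt)
  if (n == 0 || shm_rate == 0)
    return(list(sequence = sequence_nt, positions = integer()))
  pos <- which(runif(n) < shm_rate)
  pos <- setdiff(pos, exclude)
  if (!length(pos)) return(list(sequence = sequence_nt, positions = integer()))
  chars <- strsplit(sequence_nt, "")[[1]]
  for (p in pos) chars[p] <- sample(setdiff(.NT, chars[p]), 1)
  list(sequence = paste(chars, collapse = ""), positions = as.integer(pos))
}

## one germline rearrangement (pre-SHM); returns sequence + truth fields
.simChain <- function(db, locus, config, usage) {
  anch <- anchorInfo(db)
  seqs <- as.character(db@sequences)
  draw <- function(p) sample(names(p), 1, prob = p)
  heavy <- locus == "IGH"
  for (try in seq_len(100)) {
    v <- draw(usage[[locus]]$V)
    j <- draw(usage[[locus]]$J)
    d <- if (heavy) draw(usage[[locus]]$D) else NA_character_
    va <- anch[match(v, anch$allele_id), ]
    ja <- anch[match(j, anch$allele_id), ]
    vseq <- seqs[[v]]; jseq <- seqs[[j]]
    cys <- va$cys_codon_start; jm <- ja$j_motif_start
    cap <- function(x) sample.int(x + 1, 1) - 1L
    trim_v <- cap(min(config$trim_max, nchar(vseq) - (cys + 2L)))
    trim_j <- cap(min(config$trim_max, jm - 1L))
    if (heavy) {
      dseq <- seqs[[d]]
      side_cap <- min(config$trim_max, max(0L, (nchar(dseq) - 6L) %/% 2L))
      trim_d5 <- cap(side_cap); trim_d3 <- cap(side_cap)
      d_core <- substr(dseq, trim_d5 + 1L, nchar(dseq) - trim_d3)
      n1 <- cap(config$n_insert_max); n2 <- cap(config$n_insert_max)
    } else {
      d_core <- ""; trim_d5 <- trim_d3 <- NA_integer_
      n1 <- cap(config$n_insert_max); n2 <- 0L
    }
    v_part <- substr(vseq, 1L, nchar(vseq) - trim_v)
    j_part <- substr(jseq, trim_j + 1L, nchar(jseq))
    ## junction length: V tail from the cys codon + inserts + D core + J
    ## head through the end of the [W|F] codon
    L <- (nchar(v_part) - cys + 1L) + n1 + nchar(d_core) + n2 +
      (jm + 2L - trim_j)
    productive <- runif(1) < config$productive_fraction
    adj <- (3L - L %% 3L) %% 3L
    if (!productive) adj <- (adj + 1L) %% 3L
    n1 <- n1 + adj
    L <- L + adj
    for (resample in seq_len(50)) {
      ins1 <- paste(sample(.NT, n1, replace = TRUE), collapse = "")
      ins2 <- paste(sample(.NT, n2, replace = TRUE), collapse = "")
      seq_nt <- paste0(v_part, ins1, d_core, ins2, j_part)
      junction <- substr(seq_nt, cys, cys + L - 1L)
      ok <- !productive ||
        !grepl("*", translateNt(junction), fixed = TRUE)
      if (ok) {
        return(list(sequence = seq_nt, v_call = v, d_call = d, j_call = j,
                    junction_start = cys, junction_end = cys + L - 1L,
                    trim_v = trim_v, trim_j = trim_j,
                    trim_d5 = trim_d5, trim_d3 = trim_d3,
                    n_insert = n1 + n2, productive_intent = productive))
      }
      if (n1 + n2 == 0L) break  # nothing to resample; redraw segments
    }
  }
  stop("failed to build a stop-free junction after bounded retries")
}

## planted convergent clone chain: germline V to the cys, the fixed
## junction, then J after the [W|F] codon
.plantedChain <- function(db, spec) {
  anch <- anchorInfo(db)
  seqs <- as.character(db@sequences)
  va <- anch[match(spec$v, anch$allele_id), ]
  ja <- anch[match(spec$j, anch$allele_id), ]
  cys <- va$cys_codon_start; jm <- ja$j_motif_start
  seq_nt <- paste0(substr(seqs[[spec$v]], 1L, cys - 1L), spec$junction,
                   substr(seqs[[spec$j]], jm + 3L, nchar(seqs[[spec$j]])))
  list(sequence = seq_nt, v_call = spec$v, d_call = NA_character_,
       j_call = spec$j, junction_start = cys,
       junction_end = cys + nchar(spec$junction) - 1L,
       trim_v = NA_integer_, trim_j = NA_integer_,
       trim_d5 = NA_integer_, trim_d3 = NA_integer_,
       n_insert = NA_integer_, productive_intent = TRUE)
}

#' Simulate one V(D)J rearrangement
#'
#' Draws segments by the configured usage, trims uniformly on
#' `[0, trim_max]` (capped so the conserved anchors survive), inserts
#' uniform-random N nucleotides, and forces the junction in frame by
#' construction for the configured `productive_fraction`. No SHM is
#' applied; see [applyShm()].
#'
#' @param db a [GermlineDb-class].
#' @param locus `"IGH"`, `"IGK"` or `"IGL"`.
#' @param config a [simulationConfig()].
#' @return list with `sequence` and the truth fields (`v_call`, `d_call`,
#'   `j_call`, `junction_start`, `junction_end`, trims, insert lengths).
#' @export
simulateRearrangement <- function(db, locus, config = simulationConfig()) {
  usage <- config$usage
  if (is.null(usage)) usage <- .defaultUsage(db)
  .simChain(db, locus, config, usage)
}

#' Simulate a multi-patient paired-chain single-cell cohort
#'
#' Emits `cells_per_patient` cells per patient, each with one heavy and one
#' light chain (locus drawn from `light_locus_prob`), applies per-site SHM,
#' plants the configured convergent clones (their junctions are exempt from
#' SHM, modelling antigen-driven conservation), and converts an
#' `incomplete_fraction` of the non-planted cells to incomplete ones by
#' dropping a whole chain class or duplicating both chains with fresh SHM
#' (doublet mimic). Deterministic given config + seed.
#'
#' @param config a [simulationConfig()].
#' @param db a [GermlineDb-class].
#' @param out_dir if non-NULL, write `patient_<ID>.fasta` per patient,
#'   `truth.tsv` and `config_used.yaml` there.
#' @return list with `sequences` (named character vector), `truth`
#'   (data.frame, one row per emitted chain: calls, junction boundaries and
#'   sequence, SHM positions, planted clone id), `cells` (per-cell
#'   completeness truth) and the resolved `config`.
#' @export
simulateCohort <- function(config = simulationConfig(),
                           db = syntheticGermline(), out_dir = NULL) {
  findings <- validateSimConfig(config, db)
  if (length(findings))
    stop("invalid simulation config:\n  ", paste(findings, collapse = "\n  "))
  set.seed(config$seed)
  usage <- config$usage
  if (is.null(usage)) usage <- .defaultUsage(db)
  pats <- .patientIds(config$n_patients)
  n_cells <- rep_len(config$cells_per_patient, config$n_patients)

  ## planted cell bookkeeping: patient -> list of clone specs
  planted_by_pat <- setNames(vector("list", length(pats)), pats)
  for (k in seq_along(config$planted_clones)) {
    pc <- config$planted_clones[[k]]
    if (is.null(pc$id)) pc$id <- paste0("planted", k)
    if (is.null(pc$cells_each)) pc$cells_each <- 1L
    for (p in pc$patients)
      planted_by_pat[[p]] <- c(planted_by_pat[[p]],
                               rep(list(pc), pc$cells_each))
  }

  seq_out <- character(); seq_names <- character()
  truth_rows <- list(); cell_rows <- list()
  for (pi in seq_along(pats)) {
    pid <- pats[pi]
    planted <- planted_by_pat[[pid]]
    n_i <- n_cells[pi]
    if (length(planted) > n_i)
      stop("patient ", pid, ": more planted cells than cells_per_patient")
    n_reg <- n_i - length(planted)
    n_inc <- round(config$incomplete_fraction * n_i)
    if (n_inc > n_reg)
      stop("patient ", pid, ": incomplete_fraction leaves too few regular cells")
    inc_idx <- if (n_inc > 0) sample.int(n_reg, n_inc) else integer()

    reg_ct <- 0L
    for (ci in seq_len(n_i)) {
      cid <- sprintf("%s_c%03d", pid, ci)
      is_planted <- ci <= length(planted)
      if (is_planted) {
        pc <- planted[[ci]]
        light_locus <- parseAlleleName(pc$light$v)$locus
        chains <- list(.plantedChain(db, pc$heavy), .plantedChain(db, pc$light))
        loci <- c("IGH", light_locus)
        clone_id <- pc$id
        mode <- "complete"
      } else {
        reg_ct <- reg_ct + 1L
        light_locus <- sample(names(config$light_locus_prob), 1,
                              prob = config$light_locus_prob)
        chains <- list(.simChain(db, "IGH", config, usage),
                       .simChain(db, light_locus, config, usage))
        loci <- c("IGH", light_locus)
        clone_id <- ""
        mode <- if (reg_ct %in% inc_idx) {
          sample(c("drop_heavy", "drop_light", "doublet"), 1,
                 prob = c(0.25, 0.25, 0.5))
        } else "complete"
      }
      emit <- switch(mode,
                     complete = list(1L, 2L),
                     drop_heavy = list(2L),
                     drop_light = list(1L),
                     doublet = list(1L, 2L, 1L, 2L))
      counts <- integer(2)
      for (e in seq_along(emit)) {
        k <- emit[[e]]
        ch <- chains[[k]]
        counts[k] <- counts[k] + 1L
        excl <- if (is_planted) seq(ch$junction_start, ch$junction_end) else integer()
        mut <- applyShm(ch$sequence, config$shm_rate, exclude = excl)
        sid <- sprintf("%s_%s_%d", cid, loci[k], counts[k])
        seq_out <- c(seq_out, mut$sequence)
        seq_names <- c(seq_names, sid)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          sequence_id = sid, patient_id = pid, cell_id = cid,
          locus = loci[k], v_call = ch$v_call,
          d_call = ifelse(is.na(ch$d_call), "", ch$d_call),
          j_call = ch$j_call,
          junction_start = ch$junction_start,
          junction_end = ch$junction_end,
          junction = substr(mut$sequence, ch$junction_start, ch$junction_end),
          n_shm = length(mut$positions),
          shm_positions = paste(mut$positions, collapse = ","),
          productive_intent = ch$productive_intent,
          planted_clone = clone_id, stringsAsFactors = FALSE)
      }
      n_h <- counts[1]; n_l <- counts[2]
      cell_rows[[length(cell_rows) + 1L]] <- data.frame(
        patient_id = pid, cell_id = cid, n_heavy = n_h, n_light = n_l,
        completeness = classifyCompleteness(n_h, n_l),
        planted_clone = clone_id, stringsAsFactors = FALSE)
    }
  }
  names(seq_out) <- seq_names
  truth <- do.call(rbind, truth_rows)
  cells <- do.call(rbind, cell_rows)
  res <- list(sequences = seq_out, truth = truth, cells = cells,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (pid in pats) {
      sel <- truth$patient_id == pid
      con <- file(file.path(out_dir, paste0("patient_", pid, ".fasta")), "wb")
      writeLines(paste0(">", names(seq_out)[sel], "\n", seq_out[sel]),
                 con, sep = "\n")
      close(con)
    }
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    yaml::write_yaml(unclass(config), file.path(out_dir, "config_used.yaml"))
    res$files <- c(file.path(out_dir, paste0("patient_", pats, ".fasta")),
                   file.path(out_dir, "truth.tsv"),
                   file.path(out_dir, "config_used.yaml"))
  }
  res
}
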