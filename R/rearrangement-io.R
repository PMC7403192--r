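## AIRR Rearrangement TSV reading/writing, plus clone-table dialects.

.AIRR_REQUIRED <- c("sequence_id", "v_call", "d_call", "j_call",
                    "junction", "junction_aa", "productive")
.AIRR_INTEGER <- c("v_mutation_count", "v_germline_aligned_length",
                   "cdr3_shm", "junction_start", "junction_end",
                   "v_q_start", "v_q_end", "j_q_start", "j_q_end",
                   "d_q_start", "d_q_end")
.AIRR_NUMERIC <- c("mutation_rate", "v_score", "j_score")
.AIRR_LOGICAL <- c("productive", "rev_comp")

#' Read an AIRR Rearrangement TSV
#'
#' Tab-separated with header; the mandatory columns are `sequence_id`,
#' `v_call`, `d_call`, `j_call`, `junction`, `junction_aa`, `productive`.
#' Extension columns (`patient_id`, `cell_id`, `locus`, `cdr3_aa`,
#' `v_mutation_count`, `v_germline_aligned_length`, ...) and any unknown
#' columns are preserved. `productive` is parsed from the AIRR `T`/`F`
#' serialisation (also accepts `TRUE`/`FALSE`). Rows whose `junction_aa`
#' is not the standard-code translation of an in-frame `junction` are
#' flagged: a warning is raised and the offending `sequence_id`s are
#' attached as `attr(, "inconsistent")`.
#'
#' @param path path to the TSV file.
#' @return data.frame of chain records (zero rows for an empty table).
#' @seealso [writeRearrangements()]
#' @export
readRearrangements <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                   na.strings = NULL, check.names = FALSE)
  missing <- setdiff(.AIRR_REQUIRED, names(df))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  for (col in intersect(.AIRR_LOGICAL, names(df)))
    df[[col]] <- toupper(df[[col]]) %in% c("T", "TRUE")
  for (col in intersect(.AIRR_INTEGER, names(df)))
    df[[col]] <- as.integer(df[[col]])
  for (col in intersect(.AIRR_NUMERIC, names(df)))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  inconsistent <- character()
  if (nrow(df)) {
    has_nt <- nzchar(df$junction) & nchar(df$junction) %% 3 == 0
    has_aa <- nzchar(df$junction_aa)
    chk <- has_nt & has_aa
    bad <- chk & translateNt(df$junction) != df$junction_aa
    if (any(bad)) {
      inconsistent <- df$sequence_id[bad]
      warning("junction_aa is not the translation of junction for: ",
              paste(inconsistent, collapse = ", "))
    }
  }
  attr(df, "inconsistent") <- inconsistent
  df
}

#' Write an AIRR Rearrangement TSV
#'
#' Serialises `productive` as AIRR `T`/`F` and `NA` as the empty string;
#' [readRearrangements()] of the written file reproduces the input on all
#' defined fields, unknown columns included.
#'
#' @param records data.frame of chain records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRearrangements <- function(records, path) {
  missing <- setdiff(.AIRR_REQUIRED, names(records))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  out <- records
  for (col in intersect(.AIRR_LOGICAL, names(out)))
    out[[col]] <- ifelse(out[[col]], "T", "F")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a clonotype table in AIRR or MiXCR-like dialect
#'
#' Normalises control-cohort clone tables to the internal convention:
#' columns `v_call`, `j_call`, `cdr3_aa` (conserved anchors stripped) and
#' `count`. The `airr` dialect expects `v_call`, `j_call` and `junction_aa`
#' (or an anchor-bearing `cdr3_aa`) plus optional `duplicate_count`; the
#' `mixcr` dialect expects `allVHitsWithScore`/`vHit`, `jHit`,
#' `aaSeqCDR3` (printed with the leading C and trailing W/F) and
#' `cloneCount`.
#'
#' @param path path to the tab-separated table.
#' @param dialect `"airr"` or `"mixcr"`.
#' @return data.frame with columns `v_call`, `j_call`, `cdr3_aa`, `count`.
#' @export
readClonotypeTable <- function(path, dialect = c("airr", "mixcr")) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) stop("unknown dialect: ",
                                               dialect[1], call. = FALSE))
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                   na.strings = NULL, check.names = FALSE)
  if (nrow(df) == 0) {
    return(data.frame(v_call = character(), j_call = character(),
                      cdr3_aa = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  if (dialect == "airr") {
    aa <- if ("junction_aa" %in% names(df)) junctionToCdr3(df$junction_aa)
          else normalizeCdr3(df$cdr3_aa)
    cnt <- if ("duplicate_count" %in% names(df)) df$duplicate_count
           else if ("count" %in% names(df)) df$count else "1"
    out <- data.frame(v_call = df$v_call, j_call = df$j_call, cdr3_aa = aa,
                      count = as.integer(cnt), stringsAsFactors = FALSE)
  } else {
    vcol <- intersect(c("vHit", "allVHitsWithScore", "bestVHit"), names(df))[1]
    jcol <- intersect(c("jHit", "allJHitsWithScore", "bestJHit"), names(df))[1]
    if (is.na(vcol) || is.na(jcol) || !"aaSeqCDR3" %in% names(df))
      stop("mixcr-like table needs V/J hit columns and aaSeqCDR3")
    strip_score <- function(x) sub("\\(.*$", "", x)
    cnt <- if ("cloneCount" %in% names(df)) df$cloneCount else "1"
    out <- data.frame(v_call = strip_score(df[[vcol]]),
                      j_call = strip_score(df[[jcol]]),
                      cdr3_aa = normalizeCdr3(df$aaSeqCDR3),
                      count = as.integer(round(as.numeric(cnt))),
                      stringsAsFactors = FALSE)
  }
  if (any(out$count < 1)) stop("clonotype counts must be >= 1")
  out
}

#' The bundled anti-NMDAR encephalitis shared-clonotype cohort
#'
#' The published shared-clonotype table of a 12-patient anti-NMDAR
#' encephalitis CSF single-cell BCR study, expanded to one complete cell
#' per listed patient: 13 cells, each with one heavy and one light chain
#' record (26 AIRR rows). Junction nucleotides are a deterministic
#' reverse translation of the printed amino acids ([revTranslate()]); the
#' printed `IGJ3*02` light-chain J (a typo) is carried as `IGLJ3*02`.
#'
#' @return data.frame of 26 chain records in AIRR layout.
#' @examples
#' cells <- assembleCells(nmdarSharedClonotypeCells())
#' findSharedClonotypes(cells)
#' @export
nmdarSharedClonotypeCells <- function() {
  path <- system.file("extdata", "nmdar_shared_clonotype_cells.tsv",
                      package = "repclone")
  suppressWarnings(readRearrangements(path))
}
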