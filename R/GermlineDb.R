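#' GermlineDb: an anchored germline segment reference
#'
#' Holds the V, D and J germline segments of one or more immunoglobulin loci
#' as a [Biostrings::DNAStringSet], together with the per-allele anchor
#' annotations the annotator needs: the 1-based start of the conserved
#' 2nd-CYS codon on V segments and the 1-based start of the conserved
#' \[W|F\]GxG motif on J segments.
#'
#' @slot sequences [Biostrings::DNAStringSet] named by allele id.
#' @slot anchors data.frame with columns `allele_id`, `locus`
#'   (IGH/IGK/IGL), `segment_type` (V/D/J), `cys_codon_start` (V only,
#'   1-based), `j_motif_start` (J only, 1-based), `reading_frame_offset`
#'   (J only, `(j_motif_start - 1) %% 3`).
#' @seealso [readGermlineFasta()], [syntheticGermline()]
#' @export
setClass("GermlineDb",
         representation(sequences = "DNAStringSet", anchors = "data.frame"))

setValidity("GermlineDb", function(object) {
  msgs <- character()
  a <- object@anchors
  seqs <- object@sequences
  need <- c("allele_id", "locus", "segment_type", "cys_codon_start",
            "j_motif_start", "reading_frame_offset")
  if (!all(need %in% names(a)))
    return(paste("anchors must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(a$allele_id))
    msgs <- c(msgs, "duplicate allele_id in anchors")
  if (!identical(names(seqs), a$allele_id))
    msgs <- c(msgs, "sequence names must equal anchors$allele_id, in order")
  if (length(seqs)) {
    chars <- as.character(seqs)
    if (any(!nzchar(chars)) || any(grepl("[^ACGT]", chars)))
      msgs <- c(msgs, "sequences must be non-empty and uppercase ACGT only")
    if (!all(a$locus %in% c("IGH", "IGK", "IGL")))
      msgs <- c(msgs, "locus must be one of IGH, IGK, IGL")
    if (!all(a$segment_type %in% c("V", "D", "J")))
      msgs <- c(msgs, "segment_type must be one of V, D, J")
    isV <- a$segment_type == "V"
    isJ <- a$segment_type == "J"
    if (any(isV & is.na(a$cys_codon_start)))
      msgs <- c(msgs, "V segments must have cys_codon_start")
    if (any(isJ & is.na(a$j_motif_start)))
      msgs <- c(msgs, "J segments must have j_motif_start")
    for (i in which(isV & !is.na(a$cys_codon_start))) {
      cod <- substr(chars[i], a$cys_codon_start[i], a$cys_codon_start[i] + 2)
      if (!identical(translateNt(cod), "C"))
        msgs <- c(msgs, sprintf("%s: cys codon at %d does not translate to C",
                                a$allele_id[i], a$cys_codon_start[i]))
    }
    for (i in which(isJ & !is.na(a$j_motif_start))) {
      cod <- substr(chars[i], a$j_motif_start[i], a$j_motif_start[i] + 2)
      if (!translateNt(cod) %in% c("W", "F"))
        msgs <- c(msgs, sprintf("%s: J motif at %d does not start with W or F",
                                a$allele_id[i], a$j_motif_start[i]))
    }
    parsed <- tryCatch(parseAlleleName(a$allele_id), error = function(e) e)
    if (inherits(parsed, "error"))
      msgs <- c(msgs, conditionMessage(parsed))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GermlineDb
#'
#' @param sequences named [Biostrings::DNAStringSet] or named character
#'   vector of germline segment sequences.
#' @param anchors data.frame of anchor annotations (see [GermlineDb-class]).
#' @return A validated `GermlineDb`.
#' @export
GermlineDb <- function(sequences, anchors) {
  if (!is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  anchors <- anchors[match(names(sequences), anchors$allele_id), , drop = FALSE]
  rownames(anchors) <- NULL
  for (col in c("cys_codon_start", "j_motif_start", "reading_frame_offset"))
    anchors[[col]] <- as.integer(anchors[[col]])
  new("GermlineDb", sequences = sequences, anchors = anchors)
}

#' @describeIn GermlineDb-class number of segments
#' @param x a `GermlineDb`.
#' @export
setMethod("length", "GermlineDb", function(x) length(x@sequences))

setMethod("show", "GermlineDb", function(object) {
  a <- object@anchors
  cat("GermlineDb with", length(object), "segments\n")
  if (nrow(a)) {
    tab <- table(a$locus, a$segment_type)
    print(tab)
  }
  invisible(object)
})

#' Accessors for GermlineDb
#'
#' `alleleNames()` returns all allele ids, `anchorInfo()` the anchor table,
#' and `germlineSegments()` the sequences, optionally restricted by locus and
#' segment type.
#'
#' @param db a [GermlineDb-class].
#' @param locus optional locus filter (`"IGH"`, `"IGK"`, `"IGL"`).
#' @param segment_type optional type filter (`"V"`, `"D"`, `"J"`).
#' @return `alleleNames()`: character vector; `anchorInfo()`: data.frame;
#'   `germlineSegments()`: [Biostrings::DNAStringSet].
#' @export
alleleNames <- function(db) names(db@sequences)

#' @rdname alleleNames
#' @export
anchorInfo <- function(db) db@anchors

#' @rdname alleleNames
#' @export
germlineSegments <- function(db, locus = NULL, segment_type = NULL) {
  keep <- rep(TRUE, length(db))
  if (!is.null(locus)) keep <- keep & db@anchors$locus %in% locus
  if (!is.null(segment_type)) keep <- keep & db@anchors$segment_type %in% segment_type
  db@sequences[keep]
}

## anchor row for one allele
.anchorRow <- function(db, allele_id) {
  db@anchors[match(allele_id, db@anchors$allele_id), , drop = FALSE]
}

#' Read a germline reference from FASTA plus an anchor sidecar table
#'
#' FASTA headers must be IMGT-style allele names. The anchor table (a
#' tab-separated file or data.frame with columns `allele_id`, `locus`,
#' `segment_type`, `cys_codon_start`, `j_motif_start`,
#' `reading_frame_offset`; positions 1-based) supplies the conserved-anchor
#' coordinates that are not derivable without full IMGT gapped numbering.
#' Segments whose anchors are missing or fail the anchor-translation
#' invariants (V 2nd-CYS must translate to C, J motif must start W/F) are
#' rejected with a warning naming each one; duplicate allele ids and
#' non-ACGT characters are errors.
#'
#' @param fasta path to the germline FASTA file.
#' @param anchor_table path to the anchor TSV, or an equivalent data.frame.
#' @return A [GermlineDb-class] with the accepted segments.
#' @export
readGermlineFasta <- function(fasta, anchor_table) {
  seqs <- tryCatch(Biostrings::readDNAStringSet(fasta),
                   error = function(e) {
                     if (file.exists(fasta) && file.size(fasta) == 0)
                       Biostrings::DNAStringSet()
                     else stop(e)
                   })
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (length(seqs) == 0) {
    warning("no records in germline FASTA: ", fasta)
    empty <- data.frame(allele_id = character(), locus = character(),
                        segment_type = character(),
                        cys_codon_start = integer(), j_motif_start = integer(),
                        reading_frame_offset = integer(), stringsAsFactors = FALSE)
    return(new("GermlineDb", sequences = seqs, anchors = empty))
  }
  if (anyDuplicated(names(seqs)))
    stop("duplicate allele_id in germline FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  chars <- as.character(seqs)
  bad_nt <- grepl("[^ACGT]", chars)
  if (any(bad_nt))
    stop("non-ACGT characters in germline record(s): ",
         paste(names(seqs)[bad_nt], collapse = ", "))
  if (is.character(anchor_table))
    anchor_table <- read.delim(anchor_table, stringsAsFactors = FALSE)
  anchors <- anchor_table[match(names(seqs), anchor_table$allele_id), , drop = FALSE]

  reject <- character()
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    a <- anchors[i, ]
    if (is.na(a$allele_id)) {
      reject[id] <- "no anchor table entry"
      next
    }
    if (a$segment_type == "V") {
      if (is.na(a$cys_codon_start)) {
        reject[id] <- "V segment without cys_codon_start"
      } else if (!identical(translateNt(substr(chars[i], a$cys_codon_start,
                                               a$cys_codon_start + 2)), "C")) {
        reject[id] <- "cys codon does not translate to C"
      }
    } else if (a$segment_type == "J") {
      if (is.na(a$j_motif_start)) {
        reject[id] <- "J segment without j_motif_start"
      } else if (!translateNt(substr(chars[i], a$j_motif_start,
                                     a$j_motif_start + 2)) %in% c("W", "F")) {
        reject[id] <- "J motif does not start with W or F"
      }
    }
  }
  if (length(reject)) {
    warning("rejected germline segment(s): ",
            paste(sprintf("%s (%s)", names(reject), reject), collapse = "; "))
    keep <- !(names(seqs) %in% names(reject))
    seqs <- seqs[keep]
    anchors <- anchors[keep, , drop = FALSE]
  }
  GermlineDb(seqs, anchors)
}

#' The bundled synthetic germline reference
#'
#' A small built-in reference of 30 synthetic germline segments across IGH,
#' IGK and IGL (5 IGH V, 5 IGH D, 4 IGH J; 4+3 IGK; 5+4 IGL) carrying
#' IMGT-style allele names. The sequences are randomly generated (stop-free
#' in the V/J reading frames, conserved anchors built in, different genes of
#' a locus at least 10% divergent, alleles of the same gene 2 nt apart) and
#' are NOT the real IMGT alleles of those names; they exist so the simulator
#' and annotator can be exercised and validated offline.
#'
#' @return A [GermlineDb-class].
#' @examples
#' syntheticGermline()
#' @export
syntheticGermline <- function() {
  dir <- system.file("extdata", "germline", package = "repclone")
  readGermlineFasta(file.path(dir, "synthetic_germline.fasta"),
                    file.path(dir, "synthetic_germline_anchors.tsv"))
}
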