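#' CellSet: chain records bundled into patient-tagged cells
#'
#' Groups annotated chain records by `(patient_id, cell_id)` and carries the
#' per-cell completeness classification alongside the underlying records.
#'
#' @slot records data.frame of chain records (AIRR layout, must carry
#'   `patient_id`, `cell_id`, `locus`).
#' @slot cells data.frame with one row per cell: `patient_id`, `cell_id`,
#'   `n_heavy`, `n_light`, `completeness`.
#' @seealso [assembleCells()], [classifyCompleteness()]
#' @export
setClass("CellSet",
         representation(records = "data.frame", cells = "data.frame"))

setValidity("CellSet", function(object) {
  msgs <- character()
  need <- c("patient_id", "cell_id", "n_heavy", "n_light", "completeness")
  if (!all(need %in% names(object@cells)))
    return(paste("cells must have columns:", paste(need, collapse = ", ")))
  cells <- object@cells
  if (nrow(cells)) {
    if (anyDuplicated(paste(cells$patient_id, cells$cell_id)))
      msgs <- c(msgs, "duplicate (patient_id, cell_id)")
    expect <- classifyCompleteness(cells$n_heavy, cells$n_light)
    if (!identical(cells$completeness, expect))
      msgs <- c(msgs, "completeness inconsistent with the classification rule")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CellSet", function(object) {
  cat("CellSet with", nrow(object@cells), "cells (",
      sum(object@cells$completeness == "complete"), "complete,",
      sum(object@cells$completeness == "incomplete"), "incomplete ) from",
      length(unique(object@cells$patient_id)), "patient(s)\n")
  invisible(object)
})

#' Accessors for CellSet
#'
#' `cellInfo()` returns the per-cell table, `chainRecords()` the underlying
#' chain records, `nCells()` the number of cells.
#'
#' @param x a [CellSet-class].
#' @return data.frame / integer.
#' @export
cellInfo <- function(x) x@cells

#' @rdname cellInfo
#' @export
chainRecords <- function(x) x@records

#' @rdname cellInfo
#' @export
nCells <- function(x) nrow(x@cells)

#' Completeness classification of a cell
#'
#' A cell is complete when it has at least one heavy and one light chain
#' and at most one of the two classes is supernumerary: one heavy with one
#' or more lights, or one light with one or more heavies. Cells with two
#' or more chains of both classes at once, or with only heavy or only
#' light chains, are incomplete (the chain pairing cannot be determined).
#'
#' @param n_heavy,n_light integer vectors of per-cell chain counts.
#' @return character vector, `"complete"` or `"incomplete"`.
#' @examples
#' classifyCompleteness(1, 1)  # complete
#' classifyCompleteness(1, 2)  # complete
#' classifyCompleteness(2, 2)  # incomplete
#' classifyCompleteness(1, 0)  # incomplete
#' @export
classifyCompleteness <- function(n_heavy, n_light) {
  ifelse(n_heavy >= 1 & n_light >= 1 & (n_heavy == 1 | n_light == 1),
         "complete", "incomplete")
}

#' Assemble chain records into cells
#'
#' One cell per distinct `(patient_id, cell_id)`; chains are partitioned
#' into heavy (locus IGH) and light (IGK/IGL) classes and the completeness
#' rule applied. A `cell_id` appearing under two different `patient_id`s is
#' an error.
#'
#' @param records data.frame of chain records with `patient_id`, `cell_id`
#'   and `locus` columns.
#' @return A [CellSet-class].
#' @export
assembleCells <- function(records) {
  need <- c("patient_id", "cell_id", "locus")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("records lack column(s): ", paste(missing, collapse = ", "))
  if (nrow(records)) {
    per_cell <- unique(records[, c("patient_id", "cell_id")])
    dup <- duplicated(per_cell$cell_id)
    if (any(dup))
      stop("cell_id used by more than one patient: ",
           paste(unique(per_cell$cell_id[dup]), collapse = ", "))
    heavy <- records$locus == "IGH"
    key <- paste(records$patient_id, records$cell_id, sep = "\r")
    ckey <- paste(per_cell$patient_id, per_cell$cell_id, sep = "\r")
    n_heavy <- as.integer(tapply(heavy, key, sum)[ckey])
    n_light <- as.integer(tapply(!heavy, key, sum)[ckey])
    cells <- data.frame(patient_id = per_cell$patient_id,
                        cell_id = per_cell$cell_id,
                        n_heavy = n_heavy, n_light = n_light,
                        completeness = classifyCompleteness(n_heavy, n_light),
                        stringsAsFactors = FALSE)
    rownames(cells) <- NULL
  } else {
    cells <- data.frame(patient_id = character(), cell_id = character(),
                        n_heavy = integer(), n_light = integer(),
                        completeness = character(), stringsAsFactors = FALSE)
  }
  new("CellSet", records = records, cells = cells)
}
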