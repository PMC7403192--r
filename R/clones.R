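## Clonal clustering and convergent-clone detection.
##
## A clone is the set of chain records from the same locus whose V calls
## and J calls agree (set intersection at the chosen level, so tied
## multi-calls are tolerated) and whose junction translates to the same
## amino acids. A clonotype is the paired-chain analogue over complete
## cells. Since the matching rule is an intersection, membership is closed
## transitively (union-find), not by naive key equality.

.unionFind <- function(n) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
    invisible(NULL)
  }
  list(find = find, union = union)
}

## group indices 1..n by pairwise set-intersection of the supplied call
## sets; returns integer group labels
.closeByIntersection <- function(call_sets) {
  n <- length(call_sets[[1]])
  uf <- .unionFind(n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ok <- all(vapply(call_sets, function(cs) {
        length(intersect(cs[[i]], cs[[j]])) > 0
      }, logical(1)))
      if (ok) uf$union(i, j)
    }
  }
  vapply(seq_len(n), uf$find, integer(1))
}

.callSetsAtLevel <- function(calls, level) {
  lapply(splitCalls(calls), function(v) {
    if (!length(v)) character() else unique(collapseAllele(v, level))
  })
}

#' Cluster chain records into clones
#'
#' Partitions productive records with a defined junction into clones: two
#' records belong to the same clone iff they come from the same locus,
#' their V call sets intersect at the chosen level, their J call sets
#' intersect, and their junction amino-acid strings are identical. Records
#' that are non-productive or lack a junction are excluded (reported via a
#' message and `attr(, "excluded")`).
#'
#' @param records data.frame of annotated chain records.
#' @param level `"allele"` (default; reproduces printed allele-level clone
#'   keys) or `"gene"` (collapses allele designations).
#' @return data.frame with one row per clone: `clone_id`, `locus`,
#'   `v_call`, `d_call`, `j_call` (unions over members), `junction_aa`,
#'   `cdr3_aa`, `n_records`, `n_patients`, `patients`; member assignments
#'   in `attr(, "members")`, the matching level in `attr(, "level")`.
#' @export
clusterClones <- function(records, level = c("allele", "gene")) {
  level <- match.arg(level)
  if (!"patient_id" %in% names(records)) records$patient_id <- NA_character_
  usable <- records$productive & nzchar(records$junction_aa) &
    !is.na(records$junction_aa)
  excluded <- records$sequence_id[!usable]
  if (length(excluded))
    message(length(excluded),
            " record(s) excluded from clustering (non-productive or no junction)")
  rec <- records[usable, , drop = FALSE]
  clone_rows <- list()
  member_rows <- list()
  if (nrow(rec)) {
    v_sets <- .callSetsAtLevel(rec$v_call, level)
    j_sets <- .callSetsAtLevel(rec$j_call, level)
    bucket <- paste(rec$locus, rec$junction_aa, sep = "\r")
    for (b in unique(bucket)) {
      idx <- which(bucket == b)
      grp <- .closeByIntersection(list(v_sets[idx], j_sets[idx]))
      for (g in unique(grp)) {
        m <- idx[grp == g]
        pats <- sort(unique(rec$patient_id[m]))
        clone_rows[[length(clone_rows) + 1L]] <- data.frame(
          locus = rec$locus[m[1]],
          v_call = joinCalls(list(sort(unique(unlist(splitCalls(rec$v_call[m])))))),
          d_call = joinCalls(list(sort(unique(unlist(splitCalls(rec$d_call[m])))))),
          j_call = joinCalls(list(sort(unique(unlist(splitCalls(rec$j_call[m])))))),
          junction_aa = rec$junction_aa[m[1]],
          cdr3_aa = junctionToCdr3(rec$junction_aa[m[1]]),
          n_records = length(m),
          n_patients = length(pats[!is.na(pats)]),
          patients = paste(pats, collapse = ","),
          stringsAsFactors = FALSE)
        member_rows[[length(member_rows) + 1L]] <- data.frame(
          sequence_id = rec$sequence_id[m], patient_id = rec$patient_id[m],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, clone_rows)
  if (is.null(out)) {
    out <- data.frame(locus = character(), v_call = character(),
                      d_call = character(), j_call = character(),
                      junction_aa = character(), cdr3_aa = character(),
                      n_records = integer(), n_patients = integer(),
                      patients = character(), stringsAsFactors = FALSE)
  }
  ord <- order(out$locus, out$junction_aa, out$v_call, out$j_call)
  out <- out[ord, , drop = FALSE]
  member_rows <- member_rows[ord]
  out <- cbind(clone_id = sprintf("CL%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  members <- if (length(member_rows)) {
    do.call(rbind, lapply(seq_along(member_rows), function(i) {
      cbind(clone_id = out$clone_id[i], member_rows[[i]],
            stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(clone_id = character(), sequence_id = character(),
               patient_id = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- rownames(members) <- NULL
  attr(out, "members") <- members
  attr(out, "excluded") <- excluded
  attr(out, "level") <- level
  out
}

#' Common clones across patients, with the occurrence matrix
#'
#' Filters a clone table to clones spanning at least `min_patients`
#' distinct patients and attaches one count column per patient (the
#' clone-by-patient occurrence heat-map matrix), sorted by the number of
#' patients (descending) then clone key.
#'
#' @param clones clone table from [clusterClones()] (its `members`
#'   attribute provides the per-patient counts).
#' @param min_patients minimum number of distinct patients.
#' @param patients optional character vector fixing the patient column
#'   universe and order (e.g. all cohort patients, including those with no
#'   common clone).
#' @return data.frame of clone metadata plus per-patient count columns.
#' @export
findCommonClones <- function(clones, min_patients = 2, patients = NULL) {
  members <- attr(clones, "members")
  if (is.null(members))
    stop("clones must come from clusterClones() (missing members attribute)")
  if (is.null(patients))
    patients <- sort(unique(members$patient_id[!is.na(members$patient_id)]))
  keep <- clones$n_patients >= min_patients
  out <- clones[keep, , drop = FALSE]
  counts <- matrix(0L, nrow(out), length(patients),
                   dimnames = list(NULL, patients))
  if (nrow(out)) {
    for (i in seq_len(nrow(out))) {
      tab <- table(members$patient_id[members$clone_id == out$clone_id[i]])
      counts[i, names(tab)] <- as.integer(tab)
    }
  }
  ord <- order(-out$n_patients, out$locus, out$junction_aa, out$v_call)
  out <- cbind(out[ord, , drop = FALSE], counts[ord, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "level") <- attr(clones, "level")
  out
}

#' Shared paired-chain clonotypes across patients
#'
#' Groups complete cells into clonotypes: same heavy V and J (call-set
#' intersection at the chosen level), identical heavy CDR3 amino acids,
#' same light locus, V and J, and identical light CDR3 amino acids. For
#' complete cells carrying one supernumerary chain class (e.g. one heavy,
#' two lights) every heavy-light pairing is a candidate, but a cell is
#' counted at most once per clonotype group. Only productive chains with a
#' defined junction participate. Groups spanning at least `min_patients`
#' distinct patients are returned.
#'
#' @param cells a [CellSet-class].
#' @param min_patients minimum number of distinct patients.
#' @param level `"allele"` or `"gene"` matching level.
#' @return data.frame with one row per shared clonotype: `clonotype_id`,
#'   `n_patients`, `patients`, `n_cells`, heavy V/D/J and CDR3, light
#'   V/J and CDR3 (unions over members); cell assignments in
#'   `attr(, "members")`.
#' @export
findSharedClonotypes <- function(cells, min_patients = 2,
                                 level = c("allele", "gene")) {
  level <- match.arg(level)
  stopifnot(is(cells, "CellSet"))
  info <- cellInfo(cells)
  rec <- chainRecords(cells)
  usable <- rec$productive & nzchar(rec$junction_aa)
  rec <- rec[usable, , drop = FALSE]

  pairings <- list()
  for (i in which(info$completeness == "complete")) {
    sel <- rec$patient_id == info$patient_id[i] &
      rec$cell_id == info$cell_id[i]
    heavies <- which(sel & rec$locus == "IGH")
    lights <- which(sel & rec$locus != "IGH")
    if (!length(heavies) || !length(lights)) next
    for (h in heavies) for (l in lights) {
      pairings[[length(pairings) + 1L]] <- list(
        patient_id = info$patient_id[i], cell_id = info$cell_id[i],
        h = rec[h, ], l = rec[l, ])
    }
  }
  empty <- data.frame(clonotype_id = character(), n_patients = integer(),
                      patients = character(), n_cells = integer(),
                      heavy_v = character(), heavy_d = character(),
                      heavy_j = character(), heavy_cdr3 = character(),
                      light_v = character(), light_j = character(),
                      light_cdr3 = character(), stringsAsFactors = FALSE)
  if (!length(pairings)) {
    attr(empty, "members") <- data.frame(clonotype_id = character(),
                                         patient_id = character(),
                                         cell_id = character(),
                                         stringsAsFactors = FALSE)
    return(empty)
  }
  h_v <- .callSetsAtLevel(vapply(pairings, function(p) p$h$v_call, ""), level)
  h_j <- .callSetsAtLevel(vapply(pairings, function(p) p$h$j_call, ""), level)
  l_v <- .callSetsAtLevel(vapply(pairings, function(p) p$l$v_call, ""), level)
  l_j <- .callSetsAtLevel(vapply(pairings, function(p) p$l$j_call, ""), level)
  bucket <- paste(vapply(pairings, function(p) p$h$cdr3_aa, ""),
                  vapply(pairings, function(p) p$l$cdr3_aa, ""),
                  vapply(pairings, function(p) p$l$locus, ""), sep = "\r")
  group <- integer(length(pairings))
  gmax <- 0L
  for (b in unique(bucket)) {
    idx <- which(bucket == b)
    grp <- .closeByIntersection(list(h_v[idx], h_j[idx], l_v[idx], l_j[idx]))
    group[idx] <- gmax + match(grp, unique(grp))
    gmax <- max(group)
  }
  rows <- list(); mem <- list()
  for (g in unique(group)) {
    m <- which(group == g)
    cell_keys <- unique(vapply(m, function(i) {
      paste(pairings[[i]]$patient_id, pairings[[i]]$cell_id, sep = "\r")
    }, ""))
    pats <- sort(unique(vapply(m, function(i) pairings[[i]]$patient_id, "")))
    if (length(pats) < min_patients) next
    un <- function(f, part) {
      joinCalls(list(sort(unique(unlist(
        splitCalls(vapply(m, function(i) pairings[[i]][[part]][[f]], "")))))))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      n_patients = length(pats), patients = paste(pats, collapse = ","),
      n_cells = length(cell_keys),
      heavy_v = un("v_call", "h"), heavy_d = un("d_call", "h"),
      heavy_j = un("j_call", "h"),
      heavy_cdr3 = pairings[[m[1]]]$h$cdr3_aa,
      light_v = un("v_call", "l"), light_j = un("j_call", "l"),
      light_cdr3 = pairings[[m[1]]]$l$cdr3_aa, stringsAsFactors = FALSE)
    ck <- do.call(rbind, strsplit(cell_keys, "\r"))
    mem[[length(mem) + 1L]] <- data.frame(patient_id = ck[, 1],
                                          cell_id = ck[, 2],
                                          stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty[, -1]
  ord <- order(-out$n_patients, out$heavy_cdr3, out$light_cdr3)
  out <- out[ord, , drop = FALSE]
  mem <- mem[ord]
  out <- cbind(clonotype_id = sprintf("CT%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  members <- if (length(mem)) {
    do.call(rbind, lapply(seq_along(mem), function(i) {
      cbind(clonotype_id = out$clonotype_id[i], mem[[i]],
            stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(clonotype_id = character(), patient_id = character(),
               cell_id = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- rownames(members) <- NULL
  attr(out, "members") <- members
  attr(out, "level") <- level
  out
}

#' Search a repertoire for a CDR3 amino-acid sequence
#'
#' Hamming-distance search (equal length required) of a target CDR3
#' against a repertoire: a clonotype table from [readClonotypeTable()], a
#' chain-record data.frame with a `cdr3_aa` column, or a bare character
#' vector. The target is normalised to the internal anchor-free convention
#' first, so MiXCR-style `C...W/F` strings can be passed directly.
#'
#' @param target_cdr3_aa single CDR3 amino-acid string.
#' @param repertoire data.frame with `cdr3_aa` (and optionally
#'   `sequence_id`) or character vector of CDR3s.
#' @param max_mismatch maximum Hamming distance (default 0 = exact).
#' @return data.frame of hits: `index`, `id`, `cdr3_aa`, `distance`;
#'   zero rows when the target is not found.
#' @export
searchCdr3 <- function(target_cdr3_aa, repertoire, max_mismatch = 0) {
  if (max_mismatch < 0) stop("max_mismatch must be >= 0")
  stopifnot(length(target_cdr3_aa) == 1)
  target <- normalizeCdr3(target_cdr3_aa)
  if (is.data.frame(repertoire)) {
    cdr3 <- repertoire$cdr3_aa
    ids <- if ("sequence_id" %in% names(repertoire)) repertoire$sequence_id
           else rownames(repertoire)
  } else {
    cdr3 <- as.character(repertoire)
    ids <- if (is.null(names(repertoire))) as.character(seq_along(cdr3))
           else names(repertoire)
  }
  same_len <- !is.na(cdr3) & nchar(cdr3) == nchar(target)
  dist <- rep(NA_integer_, length(cdr3))
  if (any(same_len)) {
    tchars <- strsplit(target, "")[[1]]
    dist[same_len] <- vapply(strsplit(cdr3[same_len], ""),
                             function(x) sum(x != tchars), integer(1))
  }
  hit <- which(!is.na(dist) & dist <= max_mismatch)
  data.frame(index = hit, id = ids[hit], cdr3_aa = cdr3[hit],
             distance = dist[hit], stringsAsFactors = FALSE)
}

#' Build comparable clone keys
#'
#' Canonical string keys `(V set | J set | CDR3)` for overlap comparisons
#' between cohorts, with calls collapsed to the requested level and sorted
#' so that key equality is well defined. Works on clone tables from
#' [clusterClones()] and on normalised clonotype tables from
#' [readClonotypeTable()].
#'
#' @param x data.frame with `v_call`, `j_call` and `cdr3_aa` columns.
#' @param level `"allele"` or `"gene"`.
#' @return character vector of keys with the level in `attr(, "level")`.
#' @export
cloneKeys <- function(x, level = c("allele", "gene")) {
  level <- match.arg(level)
  v <- vapply(.callSetsAtLevel(x$v_call, level),
              function(s) paste(sort(s), collapse = ","), "")
  j <- vapply(.callSetsAtLevel(x$j_call, level),
              function(s) paste(sort(s), collapse = ","), "")
  keys <- paste(v, j, x$cdr3_aa, sep = "|")
  attr(keys, "level") <- level
  keys
}

#' Clone-set overlap between two cohorts
#'
#' Venn counts of unique clone keys: present only in A, only in B, and
#' shared. Keys must have been built at the same matching level.
#'
#' @param a,b character key vectors from [cloneKeys()].
#' @return list with `a_only`, `b_only`, `shared` and the shared keys.
#' @export
overlapCounts <- function(a, b) {
  la <- attr(a, "level"); lb <- attr(b, "level")
  if (!is.null(la) && !is.null(lb) && !identical(la, lb))
    stop("mixed key levels: ", la, " vs ", lb)
  a <- unique(as.character(a)); b <- unique(as.character(b))
  shared <- intersect(a, b)
  list(a_only = length(setdiff(a, b)), b_only = length(setdiff(b, a)),
       shared = length(shared), shared_keys = shared)
}
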