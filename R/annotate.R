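## Native V(D)J annotation: segment assignment cascade (V first, then J 3'
## of V, then D strictly between them on heavy chains), junction/CDR3
## extraction from the conserved anchors, productivity classification and
## germline mutation counting.

#' Annotation parameters
#'
#' @param v_min_score minimum local alignment score for a V assignment;
#'   queries below it are unannotatable.
#' @param j_min_score minimum score for a J assignment.
#' @param d_min_score minimum score for a D assignment (heavy chains).
#' @param min_d_length minimum aligned (gap-free) columns for a D call.
#' @param tie_margin score margin within which segment hits are reported as
#'   tied multi-calls (0 = exact ties only).
#' @param try_reverse_complement also try the reverse complement of each
#'   query and keep the orientation with the better V score.
#' @param rc_skip_score forward V score at or above which the reverse
#'   orientation cannot win and is not computed (a full-length V match
#'   scores ~2x the V length; half of that is already unreachable by a
#'   reverse-complement read).
#' @param scoring alignment scoring scheme, see [defaultAlignScoring()].
#' @return named list of parameters for [annotateVdj()].
#' @export
annotationParams <- function(v_min_score = 50, j_min_score = 20,
                             d_min_score = 10, min_d_length = 5,
                             tie_margin = 0, try_reverse_complement = TRUE,
                             rc_skip_score = 300,
                             scoring = defaultAlignScoring()) {
  list(v_min_score = v_min_score, j_min_score = j_min_score,
       d_min_score = d_min_score, min_d_length = min_d_length,
       tie_margin = tie_margin,
       try_reverse_complement = try_reverse_complement,
       rc_skip_score = rc_skip_score, scoring = scoring)
}

#' Productivity of a rearrangement
#'
#' A rearrangement is productive (functional) when its junction is in frame
#' (length a multiple of 3) and the translated V-through-J region contains
#' no stop codon. Records with an undefined junction are non-productive.
#'
#' @param junction_nt junction nucleotide string (`""` when undefined).
#' @param region_aa optional translated V-start-to-J-end amino-acid string
#'   checked for stops in addition to the junction itself.
#' @return logical vector.
#' @export
classifyProductive <- function(junction_nt, region_aa = NULL) {
  junction_nt <- as.character(junction_nt)
  ok <- !is.na(junction_nt) & nzchar(junction_nt) &
    nchar(junction_nt) %% 3 == 0
  ok[ok] <- !grepl("*", translateNt(junction_nt[ok]), fixed = TRUE)
  if (!is.null(region_aa)) {
    has_stop <- grepl("*", region_aa, fixed = TRUE)
    ok <- ok & !has_stop
  }
  ok
}

## ties within tie_margin of the top score, names sorted lexicographically
.tiedCalls <- function(hits, tie_margin) {
  if (nrow(hits) == 0) return(character())
  top <- max(hits$score)
  sort(hits$segment[hits$score >= top - tie_margin])
}

.emptyRecord <- function() {
  data.frame(sequence_id = character(), patient_id = character(),
             cell_id = character(), locus = character(),
             v_call = character(), d_call = character(), j_call = character(),
             junction = character(), junction_aa = character(),
             cdr3_aa = character(), productive = logical(),
             v_mutation_count = integer(),
             v_germline_aligned_length = integer(), mutation_rate = numeric(),
             cdr3_shm = integer(), rev_comp = logical(),
             v_score = numeric(), j_score = numeric(),
             junction_start = integer(), junction_end = integer(),
             v_q_start = integer(), v_q_end = integer(),
             j_q_start = integer(), j_q_end = integer(),
             d_q_start = integer(), d_q_end = integer(),
             sequence = character(), stringsAsFactors = FALSE)
}

.annotateOne <- function(seq_nt, db, params) {
  anch <- anchorInfo(db)
  vsegs <- germlineSegments(db, segment_type = "V")
  if (length(vsegs) == 0) return(NULL)

  vhits <- alignSegment(seq_nt, vsegs, scoring = params$scoring)
  query <- seq_nt
  rev_comp <- FALSE
  ## the reverse orientation can only win when the forward V hit is weak,
  ## so skip it once the forward score is decisive
  if (isTRUE(params$try_reverse_complement) &&
      max(vhits$score) < params$rc_skip_score) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq_nt)))
    rhits <- alignSegment(rc, vsegs, scoring = params$scoring)
    if (max(rhits$score) > max(vhits$score)) {
      vhits <- rhits
      query <- rc
      rev_comp <- TRUE
    }
  }

  if (max(vhits$score) < params$v_min_score) return(NULL)
  v_call <- .tiedCalls(vhits, params$tie_margin)
  top_v <- v_call[1]
  vhit <- vhits[vhits$segment == top_v, ][1, ]
  locus <- anch$locus[match(top_v, anch$allele_id)]

  ## J: only 3' of the V span
  j_call <- character(); jhit <- NULL; j_score <- NA_real_
  jsegs <- germlineSegments(db, locus = locus, segment_type = "J")
  j_off <- vhit$q_end
  if (length(jsegs) && j_off < nchar(query)) {
    jsub <- substr(query, j_off + 1, nchar(query))
    jh <- alignSegment(jsub, jsegs, scoring = params$scoring)
    jh$q_start <- jh$q_start + j_off
    jh$q_end <- jh$q_end + j_off
    jh <- jh[jh$score >= params$j_min_score, , drop = FALSE]
    if (nrow(jh)) {
      j_call <- .tiedCalls(jh, params$tie_margin)
      jhit <- jh[jh$segment == j_call[1], ][1, ]
      j_score <- jhit$score
    }
  }

  ## D (heavy only): strictly between the V and J spans
  d_call <- character(); dhit <- NULL
  if (locus == "IGH" && !is.null(jhit)) {
    dsegs <- germlineSegments(db, locus = "IGH", segment_type = "D")
    d_from <- vhit$q_end + 1
    d_to <- jhit$q_start - 1
    if (length(dsegs) && d_to - d_from + 1 >= params$min_d_length) {
      dsub <- substr(query, d_from, d_to)
      dh <- alignSegment(dsub, dsegs, scoring = params$scoring)
      dh$q_start <- dh$q_start + d_from - 1
      dh$q_end <- dh$q_end + d_from - 1
      dh <- dh[dh$score >= params$d_min_score &
                 dh$aligned_length >= params$min_d_length, , drop = FALSE]
      if (nrow(dh)) {
        d_call <- .tiedCalls(dh, params$tie_margin)
        dhit <- dh[dh$segment == d_call[1], ][1, ]
      }
    }
  }

  ## junction from the conserved anchors
  cys_s <- anch$cys_codon_start[match(top_v, anch$allele_id)]
  junction <- ""; junction_aa <- ""; j_start <- NA_integer_; j_end <- NA_integer_
  if (!is.null(jhit)) {
    jm_s <- anch$j_motif_start[match(jhit$segment, anch$allele_id)]
    cys_q <- .mapSegPosToQuery(vhit, cys_s)
    jm_q_end <- .mapSegPosToQuery(jhit, jm_s + 2L)
    if (!is.na(cys_q) && !is.na(jm_q_end) && cys_q < jm_q_end &&
        cys_q + 2 <= nchar(query) &&
        identical(translateNt(substr(query, cys_q, cys_q + 2)), "C")) {
      j_start <- cys_q
      j_end <- jm_q_end
      junction <- substr(query, j_start, j_end)
      if (nchar(junction) %% 3 == 0) junction_aa <- translateNt(junction)
    }
  }

  ## productivity over the translated V-start..J-end region, in the frame
  ## anchored on the junction (equivalently the germline V frame)
  productive <- FALSE
  if (nzchar(junction) && nchar(junction) %% 3 == 0) {
    reg_from <- j_start - 3L * ((j_start - vhit$q_start) %/% 3L)
    reg_to <- if (!is.null(jhit)) jhit$q_end else j_end
    region_aa <- translateNt(substr(query, reg_from, reg_to))
    productive <- classifyProductive(junction, region_aa)
  }

  ## mutation counting on the V alignment, junction region excluded
  ## (the germline side of the junction starts at the cys codon)
  cols <- .alignmentColumns(vhit)
  pre <- !is.na(cols$s_pos) & !is.na(cols$q_pos) & cols$s_pos < cys_s
  v_len <- sum(pre)
  v_mut <- sum(pre & cols$s_char != cols$q_char)
  ## junction-region mismatches against the V/J germline overlap, reported
  ## separately (never folded into mutation_rate: the N region has no
  ## germline counterpart)
  cdr3_shm <- sum(!is.na(cols$s_pos) & !is.na(cols$q_pos) &
                    cols$s_pos >= cys_s & cols$s_char != cols$q_char)
  if (!is.null(jhit) && !is.na(j_end)) {
    jm_s <- anch$j_motif_start[match(jhit$segment, anch$allele_id)]
    jcols <- .alignmentColumns(jhit)
    cdr3_shm <- cdr3_shm +
      sum(!is.na(jcols$s_pos) & !is.na(jcols$q_pos) &
            jcols$s_pos <= jm_s + 2L & jcols$s_char != jcols$q_char)
  }

  data.frame(sequence_id = NA_character_, patient_id = NA_character_,
             cell_id = NA_character_, locus = locus,
             v_call = joinCalls(list(v_call)),
             d_call = joinCalls(list(d_call)),
             j_call = joinCalls(list(j_call)),
             junction = junction, junction_aa = junction_aa,
             cdr3_aa = junctionToCdr3(junction_aa),
             productive = productive,
             v_mutation_count = as.integer(v_mut),
             v_germline_aligned_length = as.integer(v_len),
             mutation_rate = if (v_len > 0) v_mut / v_len else NA_real_,
             cdr3_shm = as.integer(cdr3_shm),
             rev_comp = rev_comp,
             v_score = vhit$score, j_score = j_score,
             junction_start = j_start, junction_end = j_end,
             v_q_start = vhit$q_start, v_q_end = vhit$q_end,
             j_q_start = if (is.null(jhit)) NA_integer_ else jhit$q_start,
             j_q_end = if (is.null(jhit)) NA_integer_ else jhit$q_end,
             d_q_start = if (is.null(dhit)) NA_integer_ else dhit$q_start,
             d_q_end = if (is.null(dhit)) NA_integer_ else dhit$q_end,
             sequence = query, stringsAsFactors = FALSE)
}

#' Assign V(D)J segments and extract junctions for a set of reads
#'
#' For each query the best-scoring V allele (over both orientations when
#' `try_reverse_complement` is set) fixes the orientation and locus; J is
#' searched only 3' of the V span, and D (heavy chains only) strictly
#' between the V and J spans with a minimum aligned length. Exact score
#' ties are reported as comma-separated multi-calls in lexicographic
#' order. The junction is cut from the query between the positions the V
#' 2nd-CYS codon and the end of the J \[W|F\] codon map to; records whose
#' anchors fail to map (or whose mapped cys codon no longer translates to
#' C) keep empty junction fields and classify non-productive. V-region
#' mutations are counted over aligned columns 5' of the cys codon;
#' junction-region mismatches against the V/J germline overlap are
#' reported separately as `cdr3_shm`.
#'
#' Queries with no V hit at or above `v_min_score` are unannotatable: they
#' are excluded from the result, listed in `attr(, "unannotated")`, and
#' counted in the run message.
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet] of
#'   reads; names become `sequence_id`.
#' @param db a [GermlineDb-class].
#' @param params see [annotationParams()].
#' @param patient_id,cell_id optional per-read metadata vectors (recycled
#'   if length 1).
#' @param verbose emit a message with annotated / unannotatable /
#'   non-productive counts.
#' @return data.frame of AIRR-style chain records (one row per annotated
#'   read) with alignment spans and scores as extension columns.
#' @export
annotateVdj <- function(seqs, db, params = annotationParams(),
                        patient_id = NULL, cell_id = NULL, verbose = TRUE) {
  if (is(seqs, "DNAStringSet")) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  if (!is.null(patient_id)) patient_id <- rep_len(patient_id, length(seqs))
  if (!is.null(cell_id)) cell_id <- rep_len(cell_id, length(seqs))

  rows <- vector("list", length(seqs))
  unannotated <- character()
  for (i in seq_along(seqs)) {
    rec <- .annotateOne(seqs[[i]], db, params)
    if (is.null(rec)) {
      unannotated <- c(unannotated, names(seqs)[i])
      next
    }
    rec$sequence_id <- names(seqs)[i]
    if (!is.null(patient_id)) rec$patient_id <- patient_id[i]
    if (!is.null(cell_id)) rec$cell_id <- cell_id[i]
    rows[[i]] <- rec
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- .emptyRecord()
  rownames(out) <- NULL
  if (verbose) {
    message(sprintf("annotated %d/%d reads (%d unannotatable, %d non-productive)",
                    nrow(out), length(seqs), length(unannotated),
                    sum(!out$productive)))
  }
  attr(out, "unannotated") <- unannotated
  out
}
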