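## Local alignment of a query read against germline segments.
## The alignment engine is Biostrings::pairwiseAlignment (local, affine
## gaps); a gap of length L costs gap_open + L * gap_extend.

#' Default alignment scoring scheme
#'
#' Match +2, mismatch -2, gap open 5, gap extend 1 (penalties positive),
#' the conventional parameters for immunoglobulin segment annotation at
#' this scale.
#'
#' @return named list with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @export
defaultAlignScoring <- function() {
  list(match = 2, mismatch = -2, gap_open = 5, gap_extend = 1)
}

#' Align a query against germline segments (local alignment)
#'
#' Computes the optimal local alignment of `query` against each segment
#' under the given scoring scheme and reports, per segment, the score, the
#' aligned spans on query and segment (1-based, closed), the number of
#' mismatched aligned columns (gaps excluded) and the number of aligned
#' (gap-free) columns. The gapped aligned strings are kept so that segment
#' coordinates (e.g. conserved anchors) can be mapped onto the query.
#'
#' @param query a single nucleotide sequence (character or DNAString).
#' @param segs named [Biostrings::DNAStringSet] or named character vector
#'   of segment sequences.
#' @param scoring scoring scheme, see [defaultAlignScoring()].
#' @param min_score drop hits scoring below this (default: keep all).
#' @return data.frame with one row per segment hit: `segment`, `score`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `mismatches`,
#'   `aligned_length`, `s_aln`, `q_aln`; sorted by decreasing score then
#'   segment name.
#' @export
alignSegment <- function(query, segs, scoring = defaultAlignScoring(),
                         min_score = NULL) {
  query <- as.character(query)
  if (length(query) != 1 || is.na(query) || !nzchar(query))
    stop("query must be a single non-empty sequence")
  if (!is(segs, "DNAStringSet")) segs <- Biostrings::DNAStringSet(segs)
  if (length(segs) == 0) {
    return(data.frame(segment = character(), score = numeric(),
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      mismatches = integer(), aligned_length = integer(),
                      s_aln = character(), q_aln = character(),
                      stringsAsFactors = FALSE))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                                  mismatch = scoring$mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(segs, Biostrings::DNAString(query),
                                       type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = scoring$gap_open,
                                       gapExtension = scoring$gap_extend)
  s_aln <- as.character(Biostrings::pattern(aln))
  q_aln <- as.character(Biostrings::subject(aln))
  both_nt <- mapply(function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    sum(ca != "-" & cb != "-")
  }, s_aln, q_aln, USE.NAMES = FALSE)
  out <- data.frame(
    segment = names(segs),
    score = Biostrings::score(aln),
    q_start = Biostrings::start(Biostrings::subject(aln)),
    q_end = Biostrings::end(Biostrings::subject(aln)),
    s_start = Biostrings::start(Biostrings::pattern(aln)),
    s_end = Biostrings::end(Biostrings::pattern(aln)),
    mismatches = Biostrings::nmismatch(aln),
    aligned_length = as.integer(both_nt),
    s_aln = s_aln, q_aln = q_aln,
    stringsAsFactors = FALSE)
  if (!is.null(min_score)) out <- out[out$score >= min_score, , drop = FALSE]
  out <- out[order(-out$score, out$segment), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## per-column view of one alignment row: segment position, query position
## and characters, NA where the other side has a gap
.alignmentColumns <- function(hit) {
  s <- strsplit(hit$s_aln, "")[[1]]
  q <- strsplit(hit$q_aln, "")[[1]]
  s_pos <- q_pos <- rep(NA_integer_, length(s))
  s_pos[s != "-"] <- seq(hit$s_start, hit$s_end)
  q_pos[q != "-"] <- seq(hit$q_start, hit$q_end)
  data.frame(s_pos = s_pos, q_pos = q_pos, s_char = s, q_char = q,
             stringsAsFactors = FALSE)
}

## map a segment coordinate to the query through one alignment row;
## NA when outside the aligned span or opposite a gap
.mapSegPosToQuery <- function(hit, s_pos) {
  if (is.na(s_pos) || s_pos < hit$s_start || s_pos > hit$s_end)
    return(NA_integer_)
  cols <- .alignmentColumns(hit)
  q <- cols$q_pos[match(s_pos, cols$s_pos)]
  if (length(q) != 1) NA_integer_ else q
}
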