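#' Parse IMGT-style immunoglobulin allele names
#'
#' Decomposes names such as `"IGHV1-18*04"` into locus, segment type, family,
#' gene and allele. The family is the locus/segment prefix plus the leading
#' digit block (`"IGHV1"`), the gene adds any `-` suffix (`"IGHV1-18"`), and
#' the allele is the two-digit block after `"*"` (absent when the name carries
#' no allele designation).
#'
#' @param name character vector of allele names.
#' @return A data.frame with columns `name`, `locus`, `segment_type`,
#'   `family`, `gene`, `allele` (`NA` when absent), one row per input.
#' @examples
#' parseAlleleName(c("IGHV1-18*04", "IGLV2-11*01", "IGHJ3"))
#' @export
parseAlleleName <- function(name) {
  if (length(name) == 0) {
    return(data.frame(name = character(), locus = character(),
                      segment_type = character(), family = character(),
                      gene = character(), allele = character(),
                      stringsAsFactors = FALSE))
  }
  rx <- "^(IG[HKL])([VDJ])([0-9]+)((?:-[0-9A-Za-z]+)*)(?:\\*([0-9]+))?$"
  ok <- grepl(rx, name)
  if (any(!ok)) {
    stop("malformed allele name(s): ", paste(unique(name[!ok]), collapse = ", "),
         " (expected IMGT-style, e.g. \"IGHV1-18*04\")")
  }
  locus <- sub(rx, "\\1", name)
  type <- sub(rx, "\\2", name)
  fam_digit <- sub(rx, "\\3", name)
  gene_suffix <- sub(rx, "\\4", name)
  allele <- sub(rx, "\\5", name)
  allele[allele == ""] <- NA_character_
  family <- paste0(locus, type, fam_digit)
  data.frame(name = name, locus = locus, segment_type = type,
             family = family, gene = paste0(family, gene_suffix),
             allele = allele, stringsAsFactors = FALSE)
}

#' Reassemble an allele name from its parsed components
#'
#' Inverse of [parseAlleleName()]: `gene` plus `"*"` plus `allele` when an
#' allele designation is present, otherwise the bare gene name.
#'
#' @param parsed data.frame as returned by [parseAlleleName()].
#' @return character vector of allele names.
#' @export
formatAlleleName <- function(parsed) {
  ifelse(is.na(parsed$allele), parsed$gene,
         paste0(parsed$gene, "*", parsed$allele))
}

#' Collapse allele names to a coarser level
#'
#' @param name character vector of IMGT-style allele names.
#' @param level `"allele"` (unchanged), `"gene"` (strip the `*NN` allele
#'   designation) or `"family"` (locus + segment type + leading digit block).
#' @return character vector at the requested level.
#' @examples
#' collapseAllele("IGHV1-18*04", "gene")    # "IGHV1-18"
#' collapseAllele("IGHV1-18*04", "family")  # "IGHV1"
#' @export
collapseAllele <- function(name, level = c("allele", "gene", "family")) {
  level <- match.arg(level)
  if (level == "allele") return(name)
  p <- parseAlleleName(name)
  if (level == "gene") p$gene else p$family
}

## split / join comma-separated multi-calls (AIRR convention)
splitCalls <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ","), function(v) v[nzchar(v)])
}

joinCalls <- function(x) vapply(x, paste, "", collapse = ",")
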