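#' Translate nucleotide sequences with the standard genetic code
#'
#' Vectorised translation; trailing partial codons are dropped, stop codons
#' translate to `"*"`, codons containing characters outside ACGT to `"X"`,
#' and the empty string translates to the empty string.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of amino-acid sequences.
#' @examples
#' translateNt("TGTGCGAGA")  # "CAR"
#' @export
translateNt <- function(x) {
  vapply(as.character(x), function(s) {
    n <- nchar(s)
    if (is.na(s) || n < 3) return("")
    n <- n - n %% 3
    codons <- substring(s, seq(1, n, 3), seq(3, n, 3))
    aa <- Biostrings::GENETIC_CODE[codons]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, "", USE.NAMES = FALSE)
}

## fixed codon choice per residue, for constructing nucleotide fixtures and
## planted clone junctions from amino-acid strings
.REV_CODON <- c(A = "GCC", R = "CGG", N = "AAC", D = "GAC", C = "TGT",
                Q = "CAG", E = "GAG", G = "GGC", H = "CAC", I = "ATC",
                L = "CTG", K = "AAG", M = "ATG", F = "TTC", P = "CCC",
                S = "TCC", T = "ACC", W = "TGG", Y = "TAC", V = "GTG")

#' Deterministic reverse translation
#'
#' Maps each amino acid to one fixed codon (the same codon every call), so
#' that amino-acid-level fixtures and planted junctions can be rendered as
#' nucleotides reproducibly. Not an optimisation over real codon usage.
#'
#' @param aa character vector of amino-acid sequences (20 standard residues).
#' @return character vector of nucleotide sequences.
#' @examples
#' translateNt(revTranslate("CARVGSKYGFETFDIW")) == "CARVGSKYGFETFDIW"
#' @export
revTranslate <- function(aa) {
  vapply(as.character(aa), function(s) {
    if (is.na(s) || !nzchar(s)) return("")
    res <- strsplit(s, "")[[1]]
    bad <- setdiff(res, names(.REV_CODON))
    if (length(bad)) stop("cannot reverse-translate residue(s): ",
                          paste(bad, collapse = ", "))
    paste(.REV_CODON[res], collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Junction to CDR3 conversion
#'
#' The junction runs from the conserved 2nd-CYS of the V segment through the
#' conserved W/F of the J segment inclusive; the CDR3 is the junction minus
#' those two anchor residues. Strings shorter than 3 give `""`.
#'
#' @param junction_aa character vector of junction amino-acid strings.
#' @return character vector of CDR3 amino-acid strings.
#' @examples
#' junctionToCdr3("CARVGSKYGFETFDIW")  # "ARVGSKYGFETFDI"
#' @export
junctionToCdr3 <- function(junction_aa) {
  n <- nchar(junction_aa)
  out <- ifelse(!is.na(junction_aa) & n >= 3, substr(junction_aa, 2, n - 1), "")
  out[is.na(junction_aa)] <- ""
  out
}

#' Normalise a MiXCR-style CDR3 string to the internal convention
#'
#' MiXCR-style clone tables print the CDR3 with the conserved anchors
#' included (leading C, trailing W or F). The internal convention strips
#' both anchors; strings that do not carry the `C ... [W|F]` pattern are
#' returned unchanged, which makes the operation idempotent.
#'
#' @param cdr3 character vector of CDR3 amino-acid strings.
#' @return character vector of anchor-stripped CDR3 strings.
#' @examples
#' normalizeCdr3("CARDNWGPDYW")  # "ARDNWGPDY"
#' normalizeCdr3("ARDNWGPDY")    # unchanged
#' @export
normalizeCdr3 <- function(cdr3) {
  cdr3 <- as.character(cdr3)
  has_anchors <- !is.na(cdr3) & nchar(cdr3) >= 3 &
    substr(cdr3, 1, 1) == "C" &
    substr(cdr3, nchar(cdr3), nchar(cdr3)) %in% c("W", "F")
  cdr3[has_anchors] <- substr(cdr3[has_anchors], 2, nchar(cdr3[has_anchors]) - 1)
  cdr3
}
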