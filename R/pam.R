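## SNP-mediated PAM gain/loss classification for allele-specific editing
##
## A substitution can create or destroy the protospacer adjacent motif a Cas
## enzyme requires. Allele-specific cleavage exploits exactly such SNPs: a
## PAM present only on the expanded chromosome (gained there, or lost from
## the normal chromosome) lets a guide cut one allele.

.IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

.checkIupac <- function(motifs) {
  bad <- motifs[grepl(sprintf("[^%s]", paste(names(.IUPAC), collapse = "")),
                      motifs)]
  if (length(bad))
    stop("non-IUPAC character in PAM motif(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(motifs)
}

## does a concrete sequence match an IUPAC motif exactly (equal length)?
.iupacMatches <- function(seq, motif) {
  if (nchar(seq) != nchar(motif)) return(FALSE)
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(motif, "")[[1]]
  all(vapply(seq_along(p), function(i) s[i] %in% .IUPAC[[p[i]]],
             logical(1)))
}

#' Default PAM rule table
#'
#' High-efficiency PAM motifs for the six CRISPR enzymes screened at the
#' huntingtin locus, in IUPAC notation: wild-type SpCas9 recognises NGG and
#' (less efficiently, but still effectively) NAG; the engineered variants
#' SpCas9_VQR (NGAN and NGNG), SpCas9_EQR (NGAG, NGCG) and SpCas9_VRER
#' (NGCG) follow their published PAM depletion profiles with the
#' high-efficiency boundary at a post-selection PAM depletion value below
#' 0.2 (5-fold depletion); SaCas9 recognises NNGRRT and AsCpf1 the T-rich
#' TTTN. Users with their own depletion measurements can substitute a
#' custom table (columns enzyme, motif, efficiency).
#'
#' @return data.frame with columns enzyme, motif, efficiency.
#' @examples
#' defaultPamRules()
#' @export
defaultPamRules <- function() {
  rules <- data.frame(
    enzyme = c("SpCas9", "SpCas9",
               "SpCas9_VQR", "SpCas9_VQR",
               "SpCas9_EQR", "SpCas9_EQR",
               "SpCas9_VRER",
               "SaCas9",
               "AsCpf1"),
    motif = c("NGG", "NAG",
              "NGAN", "NGNG",
              "NGAG", "NGCG",
              "NGCG",
              "NNGRRT",
              "TTTN"),
    efficiency = "high",
    stringsAsFactors = FALSE)
  .checkIupac(rules$motif)
  rules
}

#' Read a PAM rule table from TSV
#'
#' @param path TSV with columns enzyme, motif, efficiency ("high" or
#'   "low").
#' @return validated data.frame.
#' @export
readPamRules <- function(path) {
  rules <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("enzyme", "motif", "efficiency") %in% names(rules)))
  rules$motif <- toupper(rules$motif)
  .checkIupac(rules$motif)
  if (!all(rules$efficiency %in% c("high", "low")))
    stop("efficiency must be 'high' or 'low'", call. = FALSE)
  if (anyDuplicated(rules[, c("enzyme", "motif")]))
    stop("duplicated (enzyme, motif) row", call. = FALSE)
  rules
}

.bracket <- function(seq, at) {
  paste0(substr(seq, 1, at - 1), "[", substr(seq, at, at), "]",
         substr(seq, at + 1, nchar(seq)))
}

#' Classify the PAM effect of a substitution SNP
#'
#' Enumerates, for every enzyme and both strands, all motif-length windows
#' overlapping the SNP and compares the reference and alternative sequence
#' at each window position: a window where the reference matches a
#' high-efficiency PAM while the alternative matches no high- or
#' low-efficiency PAM of the same enzyme is a loss; the symmetric case is a
#' gain. Matched motifs are reported in bracket notation (the SNP base
#' bracketed, written in the orientation of the matching strand; "negative"
#' means the motif lies on the reverse-complement strand). Swapping the
#' reference and alternative alleles turns every gain into a loss and vice
#' versa.
#'
#' @param position 1-based SNP position on \code{ampliconRef}.
#' @param refBase,altBase reference and alternative base (must differ).
#' @param ampliconRef reference sequence containing the SNP.
#' @param rules PAM rule table (default \code{\link{defaultPamRules}}).
#' @param snpId identifier recorded with each effect.
#' @return data.frame with columns snp, enzyme, effect ("gain"/"loss"),
#'   ref_motif, alt_motif, strand ("positive"/"negative"); zero rows when
#'   the SNP touches no PAM.
#' @examples
#' # a G>C inside an NGG protospacer-adjacent motif destroys it
#' classifyPamEffect(6, "G", "C", "ATATTGGTATA")
#' @export
classifyPamEffect <- function(position, refBase, altBase, ampliconRef,
                              rules = defaultPamRules(), snpId = "snp") {
  ampliconRef <- .checkDna(ampliconRef, "ampliconRef")
  refBase <- toupper(refBase); altBase <- toupper(altBase)
  stopifnot(position >= 1, position <= nchar(ampliconRef),
            refBase != altBase,
            refBase %in% c("A", "C", "G", "T"),
            altBase %in% c("A", "C", "G", "T"))
  if (substr(ampliconRef, position, position) != refBase)
    stop("reference base at position ", position, " is not ", refBase,
         call. = FALSE)
  .checkIupac(rules$motif)

  radius <- max(nchar(rules$motif)) - 1L
  lo <- max(1L, position - radius)
  hi <- min(nchar(ampliconRef), position + radius)
  refWin <- substr(ampliconRef, lo, hi)
  altWin <- refWin
  at <- position - lo + 1L
  substr(altWin, at, at) <- altBase
  W <- nchar(refWin)

  out <- NULL
  for (enz in unique(rules$enzyme)) {
    high <- rules$motif[rules$enzyme == enz & rules$efficiency == "high"]
    any_ <- rules$motif[rules$enzyme == enz]
    for (strand in c("positive", "negative")) {
      sRef <- if (strand == "positive") refWin else revComp(refWin)
      sAlt <- if (strand == "positive") altWin else revComp(altWin)
      sAt <- if (strand == "positive") at else W - at + 1L
      for (len in unique(nchar(any_))) {
        loOff <- max(1L, sAt - len + 1L)
        hiOff <- min(sAt, W - len + 1L)
        if (hiOff < loOff) next
        for (off in loOff:hiOff) {
          refSub <- substr(sRef, off, off + len - 1L)
          altSub <- substr(sAlt, off, off + len - 1L)
          hiLen <- high[nchar(high) == len]
          refHigh <- any(vapply(hiLen, .iupacMatches, logical(1),
                                seq = refSub))
          altHigh <- any(vapply(hiLen, .iupacMatches, logical(1),
                                seq = altSub))
          refAny <- any(vapply(any_[nchar(any_) == len], .iupacMatches,
                               logical(1), seq = refSub))
          altAny <- any(vapply(any_[nchar(any_) == len], .iupacMatches,
                               logical(1), seq = altSub))
          effect <- if (refHigh && !altAny) "loss"
                    else if (altHigh && !refAny) "gain"
                    else NA_character_
          if (!is.na(effect))
            out <- rbind(out, data.frame(
              snp = snpId, enzyme = enz, effect = effect,
              ref_motif = .bracket(refSub, sAt - off + 1L),
              alt_motif = .bracket(altSub, sAt - off + 1L),
              strand = strand, stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(out))
    out <- data.frame(snp = character(0), enzyme = character(0),
                      effect = character(0), ref_motif = character(0),
                      alt_motif = character(0), strand = character(0),
                      stringsAsFactors = FALSE)
  unique(out)
}
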