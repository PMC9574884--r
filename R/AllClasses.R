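#' @import methods
NULL

#' LocusModel: a two-repeat amplicon locus
#'
#' Describes an amplicon carrying two adjacent tandem repeats: a left flank,
#' a first repeat motif (CAG at the canonical huntingtin exon-1 locus), an
#' interstitial linker, a second motif (CCG), and a right flank. The model is
#' the template factory for both joint repeat quantification and read
#' simulation.
#'
#' @slot leftFlank,rightFlank character; flanking amplicon sequence. Flanks of
#'   at least 50 bp are recommended for reliable anchoring of the repeat
#'   region.
#' @slot motif1,motif2 character; the two repeat units (non-empty, ACGT).
#' @slot interstitial character; sequence between the two repeat tracts (may
#'   be empty).
#' @slot chrom character; optional chromosome name for reporting.
#' @slot coords integer of length 0 or 2; optional 1-based inclusive genomic
#'   interval for reporting.
#' @export
setClass("LocusModel", representation(
  leftFlank = "character", motif1 = "character", interstitial = "character",
  motif2 = "character", rightFlank = "character",
  chrom = "character", coords = "integer"))

setValidity("LocusModel", function(object) {
  msg <- character(0)
  for (s in c("leftFlank", "motif1", "motif2", "rightFlank"))
    if (nchar(slot(object, s)) == 0L)
      msg <- c(msg, paste0(s, " must be non-empty"))
  for (s in c("leftFlank", "motif1", "interstitial", "motif2", "rightFlank"))
    if (grepl("[^ACGTN]", slot(object, s)))
      msg <- c(msg, paste0(s, " has characters outside {ACGTN}"))
  if (length(object@coords) == 2L && object@coords[1] > object@coords[2])
    msg <- c(msg, "coords must satisfy start <= end")
  if (length(msg)) msg else TRUE
})

#' Construct a LocusModel
#'
#' @param leftFlank,motif1,interstitial,motif2,rightFlank DNA strings; see
#'   \linkS4class{LocusModel}.
#' @param chrom,coords optional genomic coordinates (1-based inclusive) for
#'   reporting.
#' @return a \linkS4class{LocusModel}.
#' @examples
#' loc <- LocusModel(strrep("ACTG", 20), "CAG", "CAACAGCCGCCA", "CCG",
#'                   strrep("TGCA", 20))
#' loc
#' @export
LocusModel <- function(leftFlank, motif1, interstitial, motif2, rightFlank,
                       chrom = character(0), coords = integer(0)) {
  obj <- new("LocusModel",
             leftFlank = .checkDna(leftFlank, "leftFlank"),
             motif1 = .checkDna(motif1, "motif1", allow_n = FALSE),
             interstitial = toupper(interstitial),
             motif2 = .checkDna(motif2, "motif2", allow_n = FALSE),
             rightFlank = .checkDna(rightFlank, "rightFlank"),
             chrom = as.character(chrom), coords = as.integer(coords))
  if (min(nchar(obj@leftFlank), nchar(obj@rightFlank)) < 50L)
    warning("flanks shorter than 50 bp may anchor the repeat region poorly")
  obj
}

#' AlignmentResult: outcome of a pairwise alignment
#'
#' @slot score integer alignment score under the configured scheme.
#' @slot querySpan,targetSpan integer length-2, 0-based half-open intervals on
#'   the (possibly reverse-complemented) query and on the target.
#' @slot nMatches integer; identical aligned bases.
#' @slot orientation "forward" or "reverse-complement" (orientation of the
#'   query that produced the reported alignment; spans refer to that strand).
#' @slot cigar character CIGAR string (M/I/D; I = query base over target gap).
#' @export
setClass("AlignmentResult", representation(
  score = "integer", querySpan = "integer", targetSpan = "integer",
  nMatches = "integer", orientation = "character", cigar = "character"))

#' MappingConfidence: Phred-scaled placement confidence
#'
#' @slot mapq integer Phred-scaled mapping quality (0 on ties, capped at 60).
#' @slot bestScore,secondScore integer best and runner-up candidate scores.
#' @export
setClass("MappingConfidence", representation(
  mapq = "integer", bestScore = "integer", secondScore = "integer"))

#' AlleleGroup: one phased allele
#'
#' @slot label "allele1" or "allele2".
#' @slot mean numeric length-2 fitted Gaussian mean (m, n).
#' @slot covariance 2x2 covariance matrix.
#' @slot readIds character; reads assigned to the allele (after filtering).
#' @slot repeatEstimate integer length-2 modal (m, n) of the assigned reads.
#' @slot role "normal", "expanded", or "unassigned".
#' @export
setClass("AlleleGroup", representation(
  label = "character", mean = "numeric", covariance = "matrix",
  readIds = "character", repeatEstimate = "integer", role = "character"))

#' PhasingResult: diploid phasing of per-read repeat profiles
#'
#' @slot groups list of one or two \linkS4class{AlleleGroup} objects.
#' @slot discardedOutliers read ids removed by the 3-standard-deviation rule.
#' @slot discardedLowProbability read ids outside the 95\% equi-probability
#'   surface of their assigned Gaussian component.
#' @slot qcPass logical; FALSE when only one component was selected or any
#'   allele has fewer than the minimum read count.
#' @slot qcReason character explanation when QC fails ("" otherwise).
#' @export
setClass("PhasingResult", representation(
  groups = "list", discardedOutliers = "character",
  discardedLowProbability = "character", qcPass = "logical",
  qcReason = "character"))

setValidity("PhasingResult", function(object) {
  if (!length(object@groups) %in% 1:2)
    return("groups must contain one or two AlleleGroup objects")
  if (!all(vapply(object@groups, is, logical(1), "AlleleGroup")))
    return("groups must be AlleleGroup objects")
  TRUE
})

#' BarcodeManifest: dual-barcode sample addressing
#'
#' Sample identity is encoded combinatorially: the ordered pair of a forward
#' and a backward barcode addresses one sample. Each barcode is recognised
#' together with the anchor, the stretch of amplicon sequence immediately
#' adjacent to it, so that barcode matching is pinned to the correct position
#' of the read.
#'
#' @slot forward,backward named character vectors of barcode sequences (names
#'   are barcode ids, unique within each side).
#' @slot samples data.frame with columns sample, fwd_id, rev_id.
#' @slot anchorForward,anchorBackward anchor sequences (default length 256 in
#'   the simulator; any non-empty sequence is accepted).
#' @export
setClass("BarcodeManifest", representation(
  forward = "character", backward = "character", samples = "data.frame",
  anchorForward = "character", anchorBackward = "character"))

setValidity("BarcodeManifest", function(object) {
  msg <- character(0)
  if (is.null(names(object@forward)) || anyDuplicated(names(object@forward)) ||
      anyDuplicated(object@forward))
    msg <- c(msg, "forward barcodes must be uniquely named and unique")
  if (is.null(names(object@backward)) ||
      anyDuplicated(names(object@backward)) || anyDuplicated(object@backward))
    msg <- c(msg, "backward barcodes must be uniquely named and unique")
  need <- c("sample", "fwd_id", "rev_id")
  if (!all(need %in% names(object@samples)))
    msg <- c(msg, "samples needs columns sample, fwd_id, rev_id")
  else {
    key <- paste(object@samples$fwd_id, object@samples$rev_id)
    if (anyDuplicated(key)) msg <- c(msg, "duplicated barcode pair in samples")
    if (!all(object@samples$fwd_id %in% names(object@forward)) ||
        !all(object@samples$rev_id %in% names(object@backward)))
      msg <- c(msg, "sample map refers to unknown barcode ids")
  }
  if (nchar(object@anchorForward) == 0L || nchar(object@anchorBackward) == 0L)
    msg <- c(msg, "anchors must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Construct a BarcodeManifest
#'
#' @param forward,backward named character vectors of barcode sequences.
#' @param samples data.frame with columns sample, fwd_id, rev_id.
#' @param anchorForward,anchorBackward amplicon sequence immediately adjacent
#'   to the forward and backward barcode.
#' @return a \linkS4class{BarcodeManifest}.
#' @export
BarcodeManifest <- function(forward, backward, samples, anchorForward,
                            anchorBackward) {
  new("BarcodeManifest", forward = toupper(forward),
      backward = toupper(backward),
      samples = as.data.frame(samples, stringsAsFactors = FALSE),
      anchorForward = .checkDna(anchorForward, "anchorForward"),
      anchorBackward = .checkDna(anchorBackward, "anchorBackward"))
}
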