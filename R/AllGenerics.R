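#' @rdname AlignmentResult-class
#' @param x,object an object.
#' @param ... further arguments (unused).
#' @export
setGeneric("alnScore", function(x, ...) standardGeneric("alnScore"))

#' @rdname MappingConfidence-class
#' @export
setGeneric("mapq", function(x, ...) standardGeneric("mapq"))

#' @rdname PhasingResult-class
#' @export
setGeneric("alleleGroups", function(x, ...) standardGeneric("alleleGroups"))

#' @rdname PhasingResult-class
#' @export
setGeneric("qcPass", function(x, ...) standardGeneric("qcPass"))

#' @rdname AlleleGroup-class
#' @export
setGeneric("repeatEstimate", function(x, ...)
  standardGeneric("repeatEstimate"))

#' @rdname AlleleGroup-class
#' @export
setGeneric("alleleRole", function(x, ...) standardGeneric("alleleRole"))

#' @rdname AlleleGroup-class
#' @export
setGeneric("readIds", function(x, ...) standardGeneric("readIds"))

#' @rdname LocusModel-class
#' @param m,n repeat-unit counts for the first and second motif.
#' @export
setGeneric("locusTemplate", function(x, m, n, ...)
  standardGeneric("locusTemplate"))

#' @rdname AlignmentResult-class
#' @export
setMethod("alnScore", "AlignmentResult", function(x, ...) x@score)

#' @rdname MappingConfidence-class
#' @export
setMethod("mapq", "MappingConfidence", function(x, ...) x@mapq)

#' @rdname PhasingResult-class
#' @export
setMethod("alleleGroups", "PhasingResult", function(x, ...) x@groups)

#' @rdname PhasingResult-class
#' @export
setMethod("qcPass", "PhasingResult", function(x, ...) x@qcPass)

#' @rdname AlleleGroup-class
#' @export
setMethod("repeatEstimate", "AlleleGroup", function(x, ...) x@repeatEstimate)

#' @rdname AlleleGroup-class
#' @export
setMethod("alleleRole", "AlleleGroup", function(x, ...) x@role)

#' @rdname AlleleGroup-class
#' @export
setMethod("readIds", "AlleleGroup", function(x, ...) x@readIds)

#' Amplicon template with given repeat counts
#'
#' Concatenates left flank, \code{m} copies of motif1, the interstitial
#' linker, \code{n} copies of motif2 and the right flank.
#'
#' @rdname LocusModel-class
#' @export
setMethod("locusTemplate", "LocusModel", function(x, m, n, ...) {
  stopifnot(m >= 0, n >= 0)
  paste0(x@leftFlank, strrep(x@motif1, m), x@interstitial,
         strrep(x@motif2, n), x@rightFlank)
})

setMethod("show", "LocusModel", function(object) {
  cat("LocusModel:", nchar(object@leftFlank), "bp flank | (",
      object@motif1, ")m | ", object@interstitial, " | (", object@motif2,
      ")n | ", nchar(object@rightFlank), " bp flank\n", sep = "")
  if (length(object@coords) == 2L)
    cat("  coords: ", object@chrom, ":", object@coords[1], "-",
        object@coords[2], "\n", sep = "")
})

setMethod("show", "AlignmentResult", function(object) {
  cat("AlignmentResult: score ", object@score, ", ", object@nMatches,
      " matches, query [", object@querySpan[1], ",", object@querySpan[2],
      ") target [", object@targetSpan[1], ",", object@targetSpan[2], ") ",
      object@orientation, "\n", sep = "")
})

setMethod("show", "MappingConfidence", function(object) {
  cat("MappingConfidence: mapq ", object@mapq, " (best ", object@bestScore,
      ", second ", object@secondScore, ")\n", sep = "")
})

setMethod("show", "AlleleGroup", function(object) {
  cat(object@label, " (", object@role, "): estimate (",
      object@repeatEstimate[1], ", ", object@repeatEstimate[2], "), ",
      length(object@readIds), " reads\n", sep = "")
})

setMethod("show", "PhasingResult", function(object) {
  cat("PhasingResult:", length(object@groups), "allele group(s),",
      if (object@qcPass) "QC pass" else paste0("QC fail (", object@qcReason,
                                               ")"), "\n")
  for (g in object@groups) show(g)
  cat("  discarded:", length(object@discardedOutliers), "outlier(s),",
      length(object@discardedLowProbability), "low-probability read(s)\n")
})

setMethod("show", "BarcodeManifest", function(object) {
  cat("BarcodeManifest:", length(object@forward), "forward x",
      length(object@backward), "backward barcodes,",
      nrow(object@samples), "samples; anchors",
      nchar(object@anchorForward), "/", nchar(object@anchorBackward), "bp\n")
})
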