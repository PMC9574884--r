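## joint quantification of two adjacent repeats:
## decoy-based bound estimation, then exhaustive template-grid refinement

#' Estimate repeat-count bounds for one motif from one read
#'
#' Fast bound estimation. The upper bound comes from a local alignment of
#' the read against a decoy reference of \code{decoyUnits} tandem motif
#' copies (both orientations): the number of decoy repeat units covered by
#' the alignment footprint, rounded up, plus a safety margin of 3 units
#' (alignment tolerance can inflate the footprint, basecall deletions can
#' deflate it). The lower bound is the longest run of exact consecutive
#' motif copies anywhere in the read (all phases, both orientations), minus
#' a margin of 1. A read with no positive-scoring decoy alignment yields
#' (0, 0).
#'
#' @param read DNA string.
#' @param motif repeat unit (non-empty).
#' @param decoyUnits decoy length in repeat units (default 1000). Decoys
#'   longer than twice the read are truncated; a local alignment footprint
#'   cannot extend further, so the result is unchanged.
#' @param scoring alignment scoring scheme.
#' @param minScore minimum decoy alignment score to accept repeat signal;
#'   below it the read yields (0, 0) for this motif. Default: two clean
#'   motif copies, enough to reject the single-base matches any sequence
#'   produces against a pure-repeat decoy. \code{\link{quantifySample}}
#'   applies a stricter floor when flagging reads with no repeat signal at
#'   all.
#' @return integer vector \code{c(lower, upper)}.
#' @examples
#' loc <- exampleLocus()
#' rd <- alleleTemplate(loc, 20, 7)
#' estimateRepeatBounds(rd, "CAG")
#' @export
estimateRepeatBounds <- function(read, motif, decoyUnits = 1000L,
                                 scoring = defaultScoring(),
                                 minScore = 2L * nchar(motif)) {
  read <- .checkDna(read, "read")
  motif <- .checkDna(motif, "motif", allow_n = FALSE)
  k <- nchar(motif)
  units <- min(decoyUnits, ceiling(2 * nchar(read) / k) + 2L)
  decoy <- strrep(motif, units)
  a <- alignPair(read, decoy, mode = "local", scoring = scoring,
                 bothStrands = TRUE)
  if (alnScore(a) < max(1L, minScore)) return(c(lower = 0L, upper = 0L))
  span <- a@targetSpan[2] - a@targetSpan[1]
  upper <- as.integer(ceiling(span / k)) + 3L
  run <- max(cpp_longest_exact_run(read, motif),
             cpp_longest_exact_run(revComp(read), motif))
  lower <- max(0L, run - 1L)
  lower <- min(lower, upper)
  c(lower = lower, upper = upper)
}

.orientReadToLocus <- function(read, locus, scoring) {
  f <- alnScore(alignPair(locus@leftFlank, read, mode = "local",
                          scoring = scoring, bothStrands = FALSE)) +
       alnScore(alignPair(locus@rightFlank, read, mode = "local",
                          scoring = scoring, bothStrands = FALSE))
  rc <- revComp(read)
  r <- alnScore(alignPair(locus@leftFlank, rc, mode = "local",
                          scoring = scoring, bothStrands = FALSE)) +
       alnScore(alignPair(locus@rightFlank, rc, mode = "local",
                          scoring = scoring, bothStrands = FALSE))
  if (r > f) list(seq = rc, orientation = "reverse-complement")
  else list(seq = read, orientation = "forward")
}

#' Joint refinement of both repeat counts over the template grid
#'
#' Scores every template left_flank + motif1^m + interstitial + motif2^n +
#' right_flank for (m, n) on the bounds grid against the read (semi-global:
#' template fully consumed, read ends free; better strand). The exhaustive
#' grid is evaluated in row-major order with shared-prefix dynamic
#' programming, which is exact. The argmax (m, n) is the read's repeat
#' genotype; score ties break to the smallest m, then the smallest n.
#'
#' @param read DNA string.
#' @param locus a \linkS4class{LocusModel}.
#' @param bounds1,bounds2 integer \code{c(lower, upper)} for motif1 and
#'   motif2 (lower <= upper).
#' @param scoring alignment scoring scheme.
#' @param readId identifier stored in the result.
#' @return one-row data.frame: read_id, m, n, score, grid_evaluations.
#' @examples
#' loc <- exampleLocus()
#' jointRefine(alleleTemplate(loc, 17, 7), loc, c(10, 25), c(5, 12))
#' @export
jointRefine <- function(read, locus, bounds1, bounds2,
                        scoring = defaultScoring(), readId = "read") {
  read <- .checkDna(read, "read")
  if (bounds1[2] < bounds1[1] || bounds2[2] < bounds2[1])
    stop("degenerate grid: upper bound below lower bound", call. = FALSE)
  sc <- .checkScoring(scoring)
  orient <- .orientReadToLocus(read, locus, scoring)
  grid <- cpp_grid_scores(orient$seq, locus@leftFlank, locus@motif1,
                          locus@interstitial, locus@motif2,
                          locus@rightFlank,
                          as.integer(bounds1[1]), as.integer(bounds1[2]),
                          as.integer(bounds2[1]), as.integer(bounds2[2]),
                          sc$match, sc$mismatch, sc$gap_open, sc$gap_ext)
  # row-major argmax with strict improvement = smallest m, then smallest n
  best <- which(grid == max(grid), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  data.frame(read_id = readId,
             m = as.integer(bounds1[1] + best[["row"]] - 1L),
             n = as.integer(bounds2[1] + best[["col"]] - 1L),
             score = max(grid),
             grid_evaluations = length(grid),
             stringsAsFactors = FALSE)
}

#' Quantify both repeats for every read of a sample
#'
#' Two-step per-read estimation: fast decoy-based bounds for each motif,
#' then exhaustive joint refinement on the (m, n) grid. A read with no
#' repeat signal for either motif (decoy alignment score below
#' \code{minScore}, so bounds (0, 0) on both) is reported as unquantified
#' and excluded from downstream phasing. When only one motif clears the
#' floor, bounds for the other are re-estimated permissively (any positive
#' alignment) so that a weak but genuine short tract still enters the grid.
#'
#' @param reads named character vector of read sequences (names are read
#'   ids), or a path to a FASTQ file.
#' @param locus a \linkS4class{LocusModel}.
#' @param decoyUnits decoy length for bound estimation.
#' @param scoring alignment scoring scheme.
#' @param minScore decoy score floor for declaring repeat signal; default 4
#'   motif lengths (around four clean repeat units).
#' @return list with \code{profiles} (data.frame: read_id, m, n, score,
#'   grid_evaluations) and \code{unquantified} (character read ids).
#' @examples
#' loc <- exampleLocus()
#' sim <- simulateDiploidReads(loc, list(m = 20, n = 7), list(m = 31, n = 10),
#'                             coverage = 3, errorRates = c(sub = 0, ins = 0,
#'                             del = 0), seed = 1)
#' quantifySample(sim$reads, loc)$profiles
#' @export
quantifySample <- function(reads, locus, decoyUnits = 1000L,
                           scoring = defaultScoring(),
                           minScore = 4L * nchar(locus@motif1)) {
  if (length(reads) == 1L && is.character(reads) && file.exists(reads) &&
      is.null(names(reads))) {
    x <- .readFastq(reads)
    reads <- setNames(as.character(x), names(x))
  }
  stopifnot(length(reads) >= 1L)
  if (is.null(names(reads)))
    names(reads) <- paste0("read", seq_along(reads))
  profiles <- vector("list", length(reads))
  unq <- character(0)
  for (i in seq_along(reads)) {
    id <- names(reads)[i]
    rd <- reads[[i]]
    b1 <- estimateRepeatBounds(rd, locus@motif1, decoyUnits, scoring,
                               minScore = minScore)
    b2 <- estimateRepeatBounds(rd, locus@motif2, decoyUnits, scoring,
                               minScore = minScore)
    if (b1[2] == 0L && b2[2] == 0L) {
      unq <- c(unq, id)
      next
    }
    if (b1[2] == 0L)
      b1 <- estimateRepeatBounds(rd, locus@motif1, decoyUnits, scoring)
    if (b2[2] == 0L)
      b2 <- estimateRepeatBounds(rd, locus@motif2, decoyUnits, scoring)
    profiles[[i]] <- jointRefine(rd, locus, b1, b2, scoring, readId = id)
  }
  profiles <- do.call(rbind, profiles[!vapply(profiles, is.null,
                                              logical(1))])
  rownames(profiles) <- NULL
  list(profiles = profiles, unquantified = unq)
}
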