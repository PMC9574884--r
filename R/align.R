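## core pairwise-alignment contract consumed by every other module

#' Default alignment scoring scheme
#'
#' Match +1, mismatch -2, gap open -2, gap extend -1; a gap of length L costs
#' open + L * extend. The scheme is edit-distance-like and deliberately
#' tolerant of the indel-dominated error profile of nanopore reads. N is
#' scored as a mismatch against every base.
#'
#' @return named list with elements match, mismatch, gap_open, gap_ext.
#' @examples
#' defaultScoring()
#' @export
defaultScoring <- function() {
  list(match = 1L, mismatch = -2L, gap_open = -2L, gap_ext = -1L)
}

.checkScoring <- function(scoring) {
  stopifnot(is.list(scoring),
            all(c("match", "mismatch", "gap_open", "gap_ext") %in%
                  names(scoring)))
  lapply(scoring, as.integer)
}

#' Pairwise alignment of two DNA sequences
#'
#' Affine-gap dynamic-programming alignment. \code{mode = "local"} is
#' Smith-Waterman; \code{mode = "semi-global"} consumes the query end to end
#' while both ends of the target are free (the mode used to align repeat
#' templates and barcode probes against reads). By default the query is also
#' tried as its reverse complement and the better orientation is reported;
#' amplicon reads occur on both strands.
#'
#' @param query,target DNA strings over {A,C,G,T,N}; both non-empty.
#' @param mode "local" or "semi-global".
#' @param scoring scoring scheme, see \code{\link{defaultScoring}}.
#' @param bothStrands try the reverse complement of the query as well
#'   (default TRUE); ties prefer the forward orientation.
#' @return an \linkS4class{AlignmentResult}. Spans are 0-based half-open;
#'   query coordinates refer to the reported orientation.
#' @examples
#' alnScore(alignPair("CAGCAG", "CAGCAG"))       # 6 matches, score 6
#' alignPair("ACGTACGT", "TTACGTACGTTT", mode = "semi-global")
#' @export
alignPair <- function(query, target, mode = c("local", "semi-global"),
                      scoring = defaultScoring(), bothStrands = TRUE) {
  mode <- match.arg(mode)
  query <- .checkDna(query, "query")
  target <- .checkDna(target, "target")
  sc <- .checkScoring(scoring)

  run <- function(q) cpp_align(q, target, mode, sc$match, sc$mismatch,
                               sc$gap_open, sc$gap_ext)
  fwd <- run(query)
  best <- fwd
  orientation <- "forward"
  if (isTRUE(bothStrands)) {
    rev <- run(revComp(query))
    if (rev$score > fwd$score) {
      best <- rev
      orientation <- "reverse-complement"
    }
  }
  new("AlignmentResult", score = as.integer(best$score),
      querySpan = as.integer(best$query_span),
      targetSpan = as.integer(best$target_span),
      nMatches = as.integer(best$n_matches),
      orientation = orientation, cigar = as.character(best$cigar))
}

#' Mapping confidence from competing alignment candidates
#'
#' Phred-scaled confidence that the best-scoring candidate is the correct
#' placement, computed from the gap between the best and second-best scores:
#' \code{mapq = min(60, round(60 * (best - second) / best))}. Ties give 0
#' (total ambiguity); a single candidate has no competitor
#' (\code{second = 0}) and receives the cap when its score is positive. The
#' formula is monotone in the score gap and permutation-invariant in the
#' candidate list.
#'
#' @param candidates numeric vector of scores, or a list of
#'   \linkS4class{AlignmentResult} objects.
#' @param cap maximum mapq (default 60).
#' @return a \linkS4class{MappingConfidence}.
#' @examples
#' mapq(mapqOf(c(40, 40)))   # 0
#' mapq(mapqOf(40))          # 60
#' mapq(mapqOf(c(40, 20)))   # 30
#' @export
mapqOf <- function(candidates, cap = 60L) {
  if (is.list(candidates))
    candidates <- vapply(candidates, alnScore, numeric(1))
  if (length(candidates) == 0L)
    stop("candidates must be non-empty", call. = FALSE)
  s <- sort(as.numeric(candidates), decreasing = TRUE)
  best <- s[1]
  second <- if (length(s) >= 2L) s[2] else 0
  q <- if (best <= 0) 0L
       else if (best == second) 0L
       else min(as.integer(cap), as.integer(round(cap * (best - second) /
                                                    best)))
  new("MappingConfidence", mapq = as.integer(q), bestScore = as.integer(best),
      secondScore = as.integer(second))
}
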