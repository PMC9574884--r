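## barcode design: candidate generation under sequence-composition
## constraints, reference screening, compatibility graph, clique selection

.maxHomopolymer <- function(seq) {
  max(rle(strsplit(seq, "")[[1]])$lengths)
}

## tandem repeat = some unit of length 1..max_unit repeated >= min_reps
## consecutive times spanning >= min_span bp
.hasTandemRepeat <- function(seq, max_unit = 8L, min_reps = 3L,
                             min_span = 9L) {
  n <- nchar(seq)
  for (u in seq_len(min(max_unit, n %/% min_reps))) {
    for (start in seq_len(n - min_reps * u + 1L)) {
      unit <- substr(seq, start, start + u - 1L)
      reps <- 1L
      p <- start + u
      while (p + u - 1L <= n && substr(seq, p, p + u - 1L) == unit) {
        reps <- reps + 1L
        p <- p + u
      }
      if (reps >= min_reps && reps * u >= min_span) return(TRUE)
    }
  }
  FALSE
}

.gcFraction <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  sum(chars %in% c("G", "C")) / length(chars)
}

#' Generate barcode candidates under composition constraints
#'
#' Rejection sampling of uniform random sequences that satisfy three
#' composition criteria: no homopolymer longer than 2 bp (TT is allowed, TTT
#' is not), no tandem repeat (no unit of length 1-8 repeated three or more
#' consecutive times spanning at least 9 bp), and GC content within
#' 40-60\%. Candidates are distinct.
#'
#' @param n number of candidates to return.
#' @param length barcode length in bp (16 and 32 are the typical choices;
#'   minimum 8).
#' @param seed integer seed for reproducibility.
#' @param gcRange numeric length-2 inclusive GC-fraction bounds.
#' @param maxHomopolymer maximum allowed homopolymer run.
#' @param maxAttempts sampling budget before declaring the constraint space
#'   exhausted.
#' @return data.frame with columns id, sequence, gc_fraction,
#'   max_homopolymer, has_tandem_repeat (always FALSE for retained
#'   candidates).
#' @examples
#' head(generateBarcodeCandidates(5, 16, seed = 1))
#' @export
generateBarcodeCandidates <- function(n, length = 16L, seed = NULL,
                                      gcRange = c(0.40, 0.60),
                                      maxHomopolymer = 2L,
                                      maxAttempts = 10000L * n) {
  stopifnot(n >= 1L, length >= 8L)
  .withSeed(seed, {
    seqs <- character(0)
    attempts <- 0L
    while (length(seqs) < n) {
      if (attempts >= maxAttempts)
        stop("candidate space exhausted after ", attempts, " attempts",
             call. = FALSE)
      attempts <- attempts + 1L
      s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                 collapse = "")
      gc <- .gcFraction(s)
      if (gc < gcRange[1] || gc > gcRange[2]) next
      if (.maxHomopolymer(s) > maxHomopolymer) next
      if (.hasTandemRepeat(s)) next
      if (s %in% seqs) next
      seqs <- c(seqs, s)
    }
    data.frame(id = paste0("BC", seq_len(n)), sequence = seqs,
               gc_fraction = vapply(seqs, .gcFraction, numeric(1),
                                    USE.NAMES = FALSE),
               max_homopolymer = vapply(seqs, .maxHomopolymer, numeric(1),
                                        USE.NAMES = FALSE),
               has_tandem_repeat = FALSE,
               stringsAsFactors = FALSE)
  })
}

#' Screen barcode candidates against a reference genome
#'
#' Removes any candidate whose best local alignment to either strand of the
#' reference covers more than \code{identityThreshold} of the barcode length
#' with identical bases. A barcode similar to genomic sequence risks
#' non-specific priming during the barcoded PCR.
#'
#' @param candidates data.frame as returned by
#'   \code{\link{generateBarcodeCandidates}} (columns id, sequence).
#' @param reference path to a FASTA file, or a named character vector of
#'   sequences.
#' @param identityThreshold proportion in (0, 1]; a candidate is removed when
#'   n_matches / barcode_length exceeds it (default 0.80).
#' @param scoring alignment scoring scheme.
#' @return the filtered candidate data.frame, with an added
#'   \code{max_identity} column.
#' @export
screenBarcodes <- function(candidates, reference, identityThreshold = 0.80,
                           scoring = defaultScoring()) {
  stopifnot(identityThreshold > 0, identityThreshold <= 1)
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    refs <- tryCatch(Biostrings::readDNAStringSet(reference),
                     error = function(e)
                       stop("cannot read reference FASTA '", reference,
                            "': ", conditionMessage(e), call. = FALSE))
    if (length(refs) == 0L)
      stop("reference FASTA '", reference, "' contains no sequences",
           call. = FALSE)
    refs <- as.character(refs)
  } else if (is.character(reference) && length(reference) >= 1L) {
    refs <- toupper(reference)
  } else {
    stop("reference must be a FASTA path or a character vector",
         call. = FALSE)
  }
  ident <- vapply(candidates$sequence, function(bc) {
    best <- 0
    for (r in refs) {
      a <- alignPair(bc, r, mode = "local", scoring = scoring,
                     bothStrands = TRUE)
      best <- max(best, a@nMatches / nchar(bc))
    }
    best
  }, numeric(1), USE.NAMES = FALSE)
  out <- candidates[ident <= identityThreshold, , drop = FALSE]
  out$max_identity <- ident[ident <= identityThreshold]
  rownames(out) <- NULL
  out
}

## shared exact word of >= word_size bases between a and b (one strand)
.sharedWord <- function(a, b, word_size) {
  ka <- unique(substring(a, seq_len(nchar(a) - word_size + 1L),
                         seq(word_size, nchar(a))))
  kb <- unique(substring(b, seq_len(nchar(b) - word_size + 1L),
                         seq(word_size, nchar(b))))
  any(ka %in% kb)
}

## seed-then-extend pairwise alignment predicate: TRUE when the two barcodes
## align (share an exact word of word_size that extends to a positive-scoring
## local alignment), on either strand of b
.barcodesAlign <- function(a, b, word_size = 6L,
                           scoring = defaultScoring()) {
  if (nchar(a) < word_size || nchar(b) < word_size) return(FALSE)
  for (bb in c(b, revComp(b))) {
    if (.sharedWord(a, bb, word_size) &&
        alnScore(alignPair(a, bb, mode = "local", scoring = scoring,
                           bothStrands = FALSE)) > 0L)
      return(TRUE)
  }
  FALSE
}

#' Build the barcode compatibility graph
#'
#' Nodes are barcodes; an edge connects two barcodes if and only if they have
#' no pairwise alignment on either strand (no exact shared word of
#' \code{wordSize} or longer bases seeding a positive-scoring local
#' extension). A clique in this graph is therefore a set of mutually
#' non-aligning barcodes.
#'
#' @param candidates data.frame with columns id and sequence (at least 2
#'   rows).
#' @param wordSize exact-word seed length (default 6).
#' @param scoring alignment scoring scheme used for seed extension.
#' @return an \code{igraph} undirected graph with vertex names equal to the
#'   candidate ids.
#' @export
buildCompatibilityGraph <- function(candidates, wordSize = 6L,
                                    scoring = defaultScoring()) {
  stopifnot(nrow(candidates) >= 2L)
  ids <- candidates$id
  seqs <- toupper(candidates$sequence)
  n <- length(ids)
  edges <- character(0)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (!.barcodesAlign(seqs[i], seqs[j], wordSize, scoring))
      edges <- c(edges, ids[i], ids[j])
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, n, name = ids)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  g
}

#' Select a mutually compatible barcode set by maximal-clique search
#'
#' A complete subgraph (clique) of the compatibility graph is a set of
#' barcodes in which no two barcodes align with each other. The search is
#' exact (branch and bound via igraph) at every size this package targets.
#'
#' @param graph compatibility graph from
#'   \code{\link{buildCompatibilityGraph}}.
#' @param k required set size (at least 2).
#' @return list with elements \code{found} (logical), \code{barcodes}
#'   (character ids of a clique of size >= k, empty when none exists),
#'   \code{size}, and \code{exact} (TRUE; the search enumerates maximum
#'   cliques exactly). Clique membership is verified against the graph before
#'   returning.
#' @export
findBarcodeSet <- function(graph, k) {
  stopifnot(k >= 2L)
  cl <- igraph::largest_cliques(graph)
  best <- if (length(cl)) {
    members <- lapply(cl, function(v) sort(names(v)))
    members[[order(vapply(members, paste, character(1),
                          collapse = ","))[1]]]
  } else character(0)
  if (length(best) < k)
    return(list(found = FALSE, barcodes = character(0), size = 0L,
                exact = TRUE))
  # post-hoc pairwise verification against the graph
  for (i in seq_len(length(best) - 1L)) for (j in seq(i + 1L, length(best)))
    if (!igraph::are_adjacent(graph, best[i], best[j]))
      stop("internal error: returned set is not a clique", call. = FALSE)
  list(found = TRUE, barcodes = best, size = length(best), exact = TRUE)
}

#' Number of samples addressable by combinatorial dual barcoding
#'
#' With \code{f} forward and \code{b} backward barcodes, the ordered pair of
#' barcodes addresses \code{f * b} samples (10 x 10 = 100; 24 x 24 = 576).
#'
#' @param nForward,nBackward barcode counts on each side.
#' @return integer multiplexing capacity.
#' @examples
#' multiplexCapacity(10, 10)
#' multiplexCapacity(24, 24)
#' @export
multiplexCapacity <- function(nForward, nBackward = nForward) {
  stopifnot(nForward >= 1L, nBackward >= 1L)
  as.integer(nForward) * as.integer(nBackward)
}
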