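## anchor-aware dual-barcode demultiplexing
##
## Random barcode-length matches occur readily inside noisy long reads, so a
## barcode is never matched alone: each probe is the barcode plus the anchor
## (the amplicon sequence immediately adjacent to it), aligned only within
## the read-end window where the construct places it.

.sideProbes <- function(manifest, side) {
  if (side == "forward")
    setNames(paste0(manifest@forward, manifest@anchorForward),
             names(manifest@forward))
  else
    setNames(paste0(manifest@anchorBackward, revComp(manifest@backward)),
             names(manifest@backward))
}

.sideAnchor <- function(manifest, side) {
  if (side == "forward") manifest@anchorForward else manifest@anchorBackward
}

## anchor-corrected scores of all candidate probes of one side against one
## oriented read. All candidates of a side share the anchor, so the raw
## probe scores differ only in the barcode contribution; subtracting the
## anchor-only score makes the Phred confidence reflect the barcode evidence
## rather than the shared anchor.
.sideScores <- function(readSeq, probes, anchorSeq, end, scoring,
                        windowPad = 100L) {
  plen <- max(nchar(probes))
  wlen <- min(nchar(readSeq), plen + windowPad)
  win <- if (end == "head") substr(readSeq, 1L, wlen)
         else substr(readSeq, nchar(readSeq) - wlen + 1L, nchar(readSeq))
  anchorScore <- alnScore(alignPair(anchorSeq, win, mode = "semi-global",
                                    scoring = scoring, bothStrands = FALSE))
  vapply(names(probes), function(id)
    alnScore(alignPair(probes[[id]], win, mode = "semi-global",
                       scoring = scoring, bothStrands = FALSE)) - anchorScore,
    numeric(1))
}

.orientedSideScores <- function(readSeq, manifest, scoring) {
  fwdProbes <- .sideProbes(manifest, "forward")
  bwdProbes <- .sideProbes(manifest, "backward")
  res <- list()
  for (o in c("forward", "reverse-complement")) {
    rs <- if (o == "forward") readSeq else revComp(readSeq)
    res[[o]] <- list(
      forward = .sideScores(rs, fwdProbes, .sideAnchor(manifest, "forward"),
                            "head", scoring),
      backward = .sideScores(rs, bwdProbes,
                             .sideAnchor(manifest, "backward"), "tail",
                             scoring))
  }
  res
}

#' Match one barcode side of a read
#'
#' Aligns every candidate probe (barcode plus adjacent anchor) of one side
#' semi-globally to the corresponding end window of the read, in both read
#' orientations, and scores the best candidate against its competitors with
#' \code{\link{mapqOf}}. Because every candidate of a side carries the same
#' anchor, the anchor-only alignment score of the window is subtracted from
#' each probe score first: the mapping quality then measures the barcode
#' evidence alone, while the anchor still pins the match to the correct
#' position.
#'
#' @param read read sequence (character).
#' @param side "forward" or "backward".
#' @param manifest a \linkS4class{BarcodeManifest}.
#' @param scoring alignment scoring scheme.
#' @return list with \code{id} (best barcode id or NA), \code{mapq},
#'   \code{score}, \code{orientation}; a read shorter than the probe is
#'   unassignable (\code{id} NA, \code{mapq} 0), not an error.
#' @export
matchBarcodeSide <- function(read, side = c("forward", "backward"),
                             manifest, scoring = defaultScoring()) {
  side <- match.arg(side)
  read <- .checkDna(read, "read")
  probes <- .sideProbes(manifest, side)
  if (nchar(read) <= max(nchar(probes)) - 50L || nchar(read) < 20L)
    return(list(id = NA_character_, mapq = 0L, score = NA_integer_,
                orientation = NA_character_))
  anchor <- .sideAnchor(manifest, side)
  end <- if (side == "forward") "head" else "tail"
  sc <- lapply(c("forward", "reverse-complement"), function(o) {
    rs <- if (o == "forward") read else revComp(read)
    .sideScores(rs, probes, anchor, end, scoring)
  })
  merged <- pmax(sc[[1]], sc[[2]])
  conf <- mapqOf(merged)
  best <- names(merged)[which.max(merged)]
  list(id = best, mapq = mapq(conf), score = max(merged),
       orientation = if (sc[[1]][best] >= sc[[2]][best]) "forward"
                     else "reverse-complement")
}

#' Demultiplex one read
#'
#' A read is assigned to a sample only when the barcodes on both sides are
#' confidently determined (mapping quality at least \code{mapqThreshold} on
#' each side), both sides agree on one orientation of the read, and the
#' (forward, backward) pair is present in the sample map. Any other outcome
#' leaves the read unassigned with the reason recorded.
#'
#' @param read read sequence (character).
#' @param manifest a \linkS4class{BarcodeManifest}.
#' @param mapqThreshold minimum per-side mapping quality (default 30).
#' @param scoring alignment scoring scheme.
#' @return list with fields \code{sample} (name or NA), \code{forward_id},
#'   \code{forward_mapq}, \code{backward_id}, \code{backward_mapq},
#'   \code{orientation}, \code{reason} ("assigned", "low_mapq",
#'   "unexpected_pair", or "too_short").
#' @export
demuxRead <- function(read, manifest, mapqThreshold = 30L,
                      scoring = defaultScoring()) {
  read <- .checkDna(read, "read")
  unass <- function(reason, o = NA_character_)
    list(sample = NA_character_, forward_id = NA_character_,
         forward_mapq = 0L, backward_id = NA_character_,
         backward_mapq = 0L, orientation = o, reason = reason)
  minProbe <- max(nchar(.sideProbes(manifest, "forward")),
                  nchar(.sideProbes(manifest, "backward")))
  if (nchar(read) <= minProbe - 50L || nchar(read) < 20L)
    return(unass("too_short"))

  byOrient <- .orientedSideScores(read, manifest, scoring)
  tot <- vapply(byOrient, function(x)
    max(x$forward) + max(x$backward), numeric(1))
  o <- names(byOrient)[which.max(tot)]
  fs <- byOrient[[o]]$forward
  bs <- byOrient[[o]]$backward
  fconf <- mapqOf(fs)
  bconf <- mapqOf(bs)
  fid <- names(fs)[which.max(fs)]
  bid <- names(bs)[which.max(bs)]
  res <- list(sample = NA_character_, forward_id = fid,
              forward_mapq = mapq(fconf), backward_id = bid,
              backward_mapq = mapq(bconf), orientation = o,
              reason = "low_mapq")
  if (mapq(fconf) < mapqThreshold || mapq(bconf) < mapqThreshold)
    return(res)
  hit <- manifest@samples$sample[manifest@samples$fwd_id == fid &
                                   manifest@samples$rev_id == bid]
  if (length(hit) != 1L) {
    res$reason <- "unexpected_pair"
    return(res)
  }
  res$sample <- hit
  res$reason <- "assigned"
  res
}

#' Demultiplex a FASTQ pool into per-sample files
#'
#' Every input read lands in exactly one output bin: a per-sample FASTQ or
#' unassigned.fastq. Duplicate read ids are processed as separate reads. A
#' summary table counts reads per sample and per failure reason.
#'
#' @param fastq path to the pooled FASTQ file.
#' @param manifest a \linkS4class{BarcodeManifest}.
#' @param outDir output directory (created if needed).
#' @param mapqThreshold minimum per-side mapping quality (default 30).
#' @param scoring alignment scoring scheme.
#' @return invisibly, a list with \code{assignments} (per-read data.frame)
#'   and \code{summary} (per-bin counts); both are also written as TSV.
#' @export
demuxRun <- function(fastq, manifest, outDir, mapqThreshold = 30L,
                     scoring = defaultScoring()) {
  x <- .readFastq(fastq)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seqs <- as.character(x)
  q <- S4Vectors::mcols(x)$qualities
  quals <- if (is.null(q)) vapply(nchar(seqs), strrep, character(1), x = "I")
           else as.character(q)
  ids <- if (is.null(names(x))) paste0("read", seq_along(x)) else names(x)

  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    a <- demuxRead(seqs[i], manifest, mapqThreshold, scoring)
    rows[[i]] <- data.frame(read_id = ids[i], sample = a$sample,
                            forward_id = a$forward_id,
                            forward_mapq = a$forward_mapq,
                            backward_id = a$backward_id,
                            backward_mapq = a$backward_mapq,
                            reason = a$reason, stringsAsFactors = FALSE)
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(0), sample = character(0),
               forward_id = character(0), forward_mapq = integer(0),
               backward_id = character(0), backward_mapq = integer(0),
               reason = character(0), stringsAsFactors = FALSE)
  bin <- ifelse(is.na(assignments$sample), "unassigned",
                assignments$sample)
  for (b in unique(bin)) {
    sel <- bin == b
    .writeFastq(setNames(seqs[sel], ids[sel]),
                file.path(outDir, paste0(b, ".fastq")), quals[sel])
  }
  smry <- as.data.frame(table(bin = bin, reason = assignments$reason),
                        stringsAsFactors = FALSE)
  smry <- smry[smry$Freq > 0, ]
  rownames(smry) <- NULL
  stopifnot(sum(smry$Freq) == length(seqs))    # read conservation
  write.table(assignments, file.path(outDir, "assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(smry, file.path(outDir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(assignments = assignments, summary = smry))
}
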