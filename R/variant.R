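## per-allele SNP consensus calling from a read pileup

#' Down-sample reads to a target coverage
#'
#' Uniform random subset without replacement whose total coverage
#' (sum of read lengths / amplicon length) does not exceed the target and is
#' maximal under that cap; a no-op when coverage is already below target.
#'
#' @param reads named character vector of read sequences.
#' @param targetCoverage coverage cap in fold (default 200).
#' @param ampliconLength amplicon length in bp.
#' @param seed integer seed (the subset is reproducible).
#' @return the selected subset of \code{reads}.
#' @examples
#' rds <- setNames(rep(strrep("ACGT", 25), 10), paste0("r", 1:10))
#' length(downsampleReads(rds, targetCoverage = 5, ampliconLength = 100,
#'                        seed = 1))
#' @export
downsampleReads <- function(reads, targetCoverage = 200L, ampliconLength,
                            seed = NULL) {
  stopifnot(ampliconLength > 0)
  budget <- targetCoverage * ampliconLength
  if (sum(nchar(reads)) <= budget) return(reads)
  .withSeed(seed, {
    ord <- sample(seq_along(reads))
    keep <- ord[cumsum(nchar(reads)[ord]) <= budget]
    reads[sort(keep)]
  })
}

## best-orientation alignment returning aligned (query, target) columns
.alignWithPairs <- function(read, ref, scoring) {
  sc <- .checkScoring(scoring)
  fwd <- cpp_align(read, ref, "local", sc$match, sc$mismatch, sc$gap_open,
                   sc$gap_ext)
  rc <- cpp_align(revComp(read), ref, "local", sc$match, sc$mismatch,
                  sc$gap_open, sc$gap_ext)
  if (rc$score > fwd$score) list(aln = rc, seq = revComp(read))
  else list(aln = fwd, seq = read)
}

#' Call per-allele SNPs by pileup consensus
#'
#' Aligns every read of one phased allele to the amplicon reference (local,
#' better orientation), builds a per-column pileup from the aligned bases,
#' and emits a substitution call wherever depth reaches \code{minDepth} and
#' the modal non-reference base accounts for at least
#' \code{homozygousFraction} of the column. Reads of a single allele are
#' haploid, so every true variant is homozygous within the allele; the
#' fraction threshold rejects noise columns. Insertions and deletions are
#' not called.
#'
#' @param reads named character vector of reads from one allele.
#' @param ampliconRef reference sequence of the amplicon.
#' @param minDepth minimum aligned depth at a column (default 50).
#' @param homozygousFraction minimum modal non-reference fraction (default
#'   0.7).
#' @param allele label recorded with each call ("normal" or "expanded").
#' @param scoring alignment scoring scheme.
#' @return data.frame with columns position (1-based on the reference),
#'   ref_base, alt_base, allele, depth, alt_fraction.
#' @export
callAlleleSnps <- function(reads, ampliconRef, minDepth = 50L,
                           homozygousFraction = 0.7, allele = "normal",
                           scoring = defaultScoring()) {
  ampliconRef <- .checkDna(ampliconRef, "ampliconRef")
  L <- nchar(ampliconRef)
  counts <- matrix(0L, nrow = 4L, ncol = L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (rd in reads) {
    hit <- .alignWithPairs(toupper(rd), ampliconRef, scoring)
    if (hit$aln$score <= 0 || length(hit$aln$qpos) == 0L) next
    bases <- strsplit(hit$seq, "")[[1]][hit$aln$qpos]
    ok <- bases %in% rownames(counts)
    idx <- cbind(match(bases[ok], rownames(counts)), hit$aln$tpos[ok])
    for (r in seq_len(nrow(idx)))
      counts[idx[r, 1], idx[r, 2]] <- counts[idx[r, 1], idx[r, 2]] + 1L
  }
  refBases <- strsplit(ampliconRef, "")[[1]]
  depth <- colSums(counts)
  calls <- NULL
  for (p in which(depth >= minDepth)) {
    rb <- refBases[p]
    if (!rb %in% rownames(counts)) next
    nonref <- counts[setdiff(rownames(counts), rb), p]
    alt <- names(nonref)[which.max(nonref)]
    af <- nonref[[alt]] / depth[p]
    if (af >= homozygousFraction)
      calls <- rbind(calls, data.frame(
        position = p, ref_base = rb, alt_base = alt, allele = allele,
        depth = as.integer(depth[p]), alt_fraction = af,
        stringsAsFactors = FALSE))
  }
  if (is.null(calls))
    calls <- data.frame(position = integer(0), ref_base = character(0),
                        alt_base = character(0), allele = character(0),
                        depth = integer(0), alt_fraction = numeric(0))
  rownames(calls) <- NULL
  calls
}

#' Write SNP calls as a minimal VCF
#'
#' Emits VCF v4.2 with CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO and
#' ALLELE/DP/AF INFO fields.
#'
#' @param calls data.frame from \code{\link{callAlleleSnps}}.
#' @param path output file.
#' @param chrom chromosome / contig name to report.
#' @return invisibly, the path.
#' @export
writeSnpVcf <- function(calls, path, chrom = "amplicon") {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=ampliphase"),
           paste0("##contig=<ID=", chrom, ">"),
           "##INFO=<ID=ALLELE,Number=1,Type=String,Description=\"Phased allele (normal or expanded)\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Aligned depth\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternative base fraction\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- if (nrow(calls)) sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\tALLELE=%s;DP=%d;AF=%.4f",
    chrom, calls$position, calls$ref_base, calls$alt_base, calls$allele,
    calls$depth, calls$alt_fraction) else character(0)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Amplicon length from 1-based inclusive genomic coordinates
#'
#' @param start,end 1-based inclusive interval bounds (start <= end).
#' @return length in bp (end - start + 1).
#' @examples
#' ampliconLength(3069608, 3075517)   # 5910
#' ampliconLength(3071119, 3079972)   # 8854
#' ampliconLength(3069608, 3079972)   # 10365
#' @export
ampliconLength <- function(start, end) {
  if (any(start > end)) stop("start must not exceed end", call. = FALSE)
  as.integer(end - start + 1)
}
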