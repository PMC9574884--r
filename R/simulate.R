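## ground-truthed simulator for dual-barcoded diploid repeat amplicons

#' A synthetic two-repeat example locus
#'
#' A huntingtin-exon-1-like locus model: CAG repeat tract, the natural
#' CAACAGCCGCCA linker, CCG repeat tract, and synthetic flanks (the flanks
#' are fixed arbitrary sequences, not genomic sequence). Useful for examples,
#' tests and simulations.
#'
#' @param flankLength flank length in bp (50-200; default 100).
#' @return a \linkS4class{LocusModel}.
#' @examples
#' exampleLocus()
#' @export
exampleLocus <- function(flankLength = 100L) {
  stopifnot(flankLength >= 50L, flankLength <= 200L)
  # fixed synthetic flanks (200 bp each), GC-balanced, repeat-free
  left <- paste0(
    "TCGATACGGAGCTTAGCCATGTCAGATCCGTTACGAGTCTGGCATTCGAACCTGATCGGT",
    "AGCATTCAGGCTAACGTTCGAGATCCATGGTTAGCCGATACGTCAGTTGCAATCGGATCC",
    "TAGCGTTCAAGCCTGATGGTACGATCCGATTAGCAGTCGATCCTGAGCATTGCGATACGG",
    "TCAGCATTGGACTTCGAGCC")
  right <- paste0(
    "GGCTTCGAATCGGATCATGCCTAGTTCGACATCGGTTAGCATCCGAATGCTTAGGATCGC",
    "ATTCGACCTAGGTTCAGCGATACCATGGATCGTTAGCCTAGCGATTCAGACGTTAGGCAT",
    "CCGATTAGCGTTCAGATCCGGATGCATTCGAGCTAACGGATCCATTAGCGACTTCGATGG",
    "ACCTAGTTCGCAATGCGGTC")
  LocusModel(leftFlank = substr(left, 201L - flankLength, 200L),
             motif1 = "CAG", interstitial = "CAACAGCCGCCA", motif2 = "CCG",
             rightFlank = substr(right, 1L, flankLength))
}

.checkSnps <- function(snps, locus) {
  if (is.null(snps) || nrow(as.data.frame(snps)) == 0L) return(NULL)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  stopifnot(all(c("region", "offset", "alt") %in% names(snps)))
  lens <- c(left = nchar(locus@leftFlank), inter = nchar(locus@interstitial),
            right = nchar(locus@rightFlank))
  for (r in seq_len(nrow(snps))) {
    reg <- snps$region[r]
    if (!reg %in% names(lens))
      stop("SNPs are restricted to the flanks and the interstitial linker; ",
           "got region '", reg, "'", call. = FALSE)
    if (snps$offset[r] < 1L || snps$offset[r] > lens[[reg]])
      stop("SNP offset ", snps$offset[r], " outside region '", reg, "'",
           call. = FALSE)
    if (!snps$alt[r] %in% c("A", "C", "G", "T"))
      stop("SNP alt must be a single base", call. = FALSE)
    refSeq <- switch(reg, left = locus@leftFlank,
                     inter = locus@interstitial, right = locus@rightFlank)
    if (substr(refSeq, snps$offset[r], snps$offset[r]) == snps$alt[r])
      stop("SNP alt at ", reg, ":", snps$offset[r],
           " equals the reference base", call. = FALSE)
  }
  snps
}

.applySnps <- function(seq, snps, region) {
  if (is.null(snps)) return(seq)
  for (r in which(snps$region == region))
    substr(seq, snps$offset[r], snps$offset[r]) <- snps$alt[r]
  seq
}

#' Template sequence of one allele, with optional planted SNPs
#'
#' @param locus a \linkS4class{LocusModel}.
#' @param m,n repeat-unit counts.
#' @param snps optional data.frame with columns region ("left", "inter",
#'   "right"), offset (1-based within the region) and alt base;
#'   substitutions only. A SNP placed inside a repeat tract is a
#'   configuration error.
#' @return template DNA string.
#' @export
alleleTemplate <- function(locus, m, n, snps = NULL) {
  snps <- .checkSnps(snps, locus)
  paste0(.applySnps(locus@leftFlank, snps, "left"),
         strrep(locus@motif1, m),
         .applySnps(locus@interstitial, snps, "inter"),
         strrep(locus@motif2, n),
         .applySnps(locus@rightFlank, snps, "right"))
}

#' Template coordinate of a planted SNP
#'
#' @inheritParams alleleTemplate
#' @param region,offset SNP location as in \code{\link{alleleTemplate}}.
#' @return 1-based position on the (m, n) template.
#' @export
snpTemplatePosition <- function(locus, m, n, region, offset) {
  base <- switch(region,
    left = 0L,
    inter = nchar(locus@leftFlank) + m * nchar(locus@motif1),
    right = nchar(locus@leftFlank) + m * nchar(locus@motif1) +
      nchar(locus@interstitial) + n * nchar(locus@motif2),
    stop("unknown region '", region, "'", call. = FALSE))
  as.integer(base + offset)
}

.checkErrorRates <- function(errorRates) {
  er <- c(sub = 0, ins = 0, del = 0)
  er[names(errorRates)] <- errorRates
  if (any(er < 0) || any(er > 0.2))
    stop("error rates must lie in [0, 0.2]", call. = FALSE)
  er
}

.qualityChar <- function(errorRates) {
  tot <- max(sum(errorRates), 1e-4)
  intToUtf8(min(40L, as.integer(round(-10 * log10(tot)))) + 33L)
}

## error process: one left-to-right pass of independent per-base events
.mutateReads <- function(seqs, errorRates) {
  vapply(seqs, cpp_mutate_seq, character(1),
         sub_rate = errorRates[["sub"]], ins_rate = errorRates[["ins"]],
         del_rate = errorRates[["del"]], USE.NAMES = FALSE)
}

#' Simulate reads from one diploid sample
#'
#' Draws \code{coverage} reads from each of the two allele templates,
#' applies a nanopore-like error process (independent per-base substitution,
#' insertion and deletion events in a single left-to-right pass) and flips
#' each read to the reverse strand with probability \code{flipProb}.
#'
#' @param locus a \linkS4class{LocusModel}.
#' @param allele1,allele2 lists with elements \code{m}, \code{n} and
#'   optionally \code{snps} (see \code{\link{alleleTemplate}}).
#' @param coverage reads per allele (default 100).
#' @param errorRates named numeric: per-base \code{sub}, \code{ins},
#'   \code{del} rates, each in [0, 0.2]. Default 1\% substitutions, 3\%
#'   insertions, 3\% deletions.
#' @param flipProb probability a read is emitted reverse-complemented.
#' @param seed integer seed; fixed seeds give byte-identical output.
#' @param idPrefix prefix for read identifiers.
#' @return list with \code{reads} (named character vector) and \code{truth}
#'   (data.frame: read_id, allele, m, n, orientation).
#' @examples
#' sim <- simulateDiploidReads(exampleLocus(), list(m = 20, n = 7),
#'                             list(m = 45, n = 10), coverage = 5, seed = 1)
#' sim$truth[1:3, ]
#' @export
simulateDiploidReads <- function(locus, allele1, allele2, coverage = 100L,
                                 errorRates = c(sub = 0.01, ins = 0.03,
                                                del = 0.03),
                                 flipProb = 0.5, seed = NULL,
                                 idPrefix = "read") {
  stopifnot(coverage >= 1L)
  er <- .checkErrorRates(errorRates)
  .withSeed(seed, {
    alleles <- list(allele1, allele2)
    reads <- character(0)
    truth <- NULL
    for (a in 1:2) {
      al <- alleles[[a]]
      tpl <- alleleTemplate(locus, al$m, al$n, al$snps)
      ids <- sprintf("%s_a%d_%03d", idPrefix, a, seq_len(coverage))
      rr <- .mutateReads(rep(tpl, coverage), er)
      flip <- runif(coverage) < flipProb
      rr[flip] <- revComp(rr[flip])
      names(rr) <- ids
      reads <- c(reads, rr)
      truth <- rbind(truth, data.frame(
        read_id = ids, allele = a, m = al$m, n = al$n,
        orientation = ifelse(flip, "reverse", "forward"),
        stringsAsFactors = FALSE))
    }
    list(reads = reads, truth = truth)
  })
}

#' Simulate a multiplexed pool of dual-barcoded samples
#'
#' Each read is the construct forward_barcode + forward_anchor + allele
#' template + backward_anchor + revcomp(backward_barcode), passed through the
#' error process and strand flip. The anchors come from the manifest, so the
#' pool is directly demultiplexable.
#'
#' @param samples list of per-sample configurations, each a list with
#'   \code{name}, \code{fwd_id}, \code{rev_id} (barcode ids present in the
#'   manifest), \code{allele1}, \code{allele2} (as in
#'   \code{\link{simulateDiploidReads}}) and optionally \code{coverage}.
#' @param locus a \linkS4class{LocusModel}.
#' @param manifest a \linkS4class{BarcodeManifest}.
#' @param coverage default reads per allele for samples that do not set one.
#' @inheritParams simulateDiploidReads
#' @param outDir optional directory; when given, writes pool.fastq,
#'   truth.tsv and truth.json there.
#' @return list with \code{reads}, \code{qualities}, \code{truth}
#'   (read-level ground truth including the sample), and \code{files} (paths,
#'   when \code{outDir} was used).
#' @export
simulatePool <- function(samples, locus, manifest, coverage = 100L,
                         errorRates = c(sub = 0.01, ins = 0.03, del = 0.03),
                         flipProb = 0.5, seed = NULL, outDir = NULL) {
  er <- .checkErrorRates(errorRates)
  .withSeed(seed, {
    reads <- character(0)
    truth <- NULL
    for (smp in samples) {
      cov <- if (is.null(smp$coverage)) coverage else smp$coverage
      fwd <- manifest@forward[[smp$fwd_id]]
      bwd <- manifest@backward[[smp$rev_id]]
      for (a in 1:2) {
        al <- smp[[paste0("allele", a)]]
        tpl <- paste0(fwd, manifest@anchorForward,
                      alleleTemplate(locus, al$m, al$n, al$snps),
                      manifest@anchorBackward, revComp(bwd))
        ids <- sprintf("%s_a%d_%03d", smp$name, a, seq_len(cov))
        rr <- .mutateReads(rep(tpl, cov), er)
        flip <- runif(cov) < flipProb
        rr[flip] <- revComp(rr[flip])
        names(rr) <- ids
        reads <- c(reads, rr)
        truth <- rbind(truth, data.frame(
          read_id = ids, sample = smp$name, allele = a, m = al$m, n = al$n,
          orientation = ifelse(flip, "reverse", "forward"),
          stringsAsFactors = FALSE))
      }
    }
    qual <- .qualityChar(er)
    qualities <- vapply(reads, function(s)
      strrep(qual, nchar(s)), character(1), USE.NAMES = FALSE)
    files <- NULL
    if (!is.null(outDir)) {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      fq <- file.path(outDir, "pool.fastq")
      .writeFastq(reads, fq, qualities)
      tsv <- file.path(outDir, "truth.tsv")
      write.table(truth, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
      js <- file.path(outDir, "truth.json")
      jsonlite::write_json(truth, js, dataframe = "rows")
      files <- c(fastq = fq, truth_tsv = tsv, truth_json = js)
    }
    list(reads = reads, qualities = qualities, truth = truth, files = files)
  })
}

#' Build a simulation-ready barcode manifest
#'
#' Generates forward and backward barcode panels (composition-constrained,
#' mutually non-aligning via the compatibility graph) plus fixed synthetic
#' anchor sequences, and addresses samples combinatorially.
#'
#' @param nSamples number of samples to address (a near-square grid of
#'   barcode pairs is used).
#' @param barcodeLength barcode length (default 32; longer barcodes tolerate
#'   5' trimming better than 16-mers).
#' @param anchorLength anchor length (default 256).
#' @param seed integer seed.
#' @return a \linkS4class{BarcodeManifest}.
#' @export
simManifest <- function(nSamples, barcodeLength = 32L, anchorLength = 256L,
                        seed = 1L) {
  nf <- ceiling(sqrt(nSamples))
  nb <- ceiling(nSamples / nf)
  .withSeed(seed, {
    cands <- generateBarcodeCandidates(4L * (nf + nb), barcodeLength)
    g <- buildCompatibilityGraph(cands)
    setres <- findBarcodeSet(g, nf + nb)
    ids <- if (setres$found) setres$barcodes else cands$id
    if (length(ids) < nf + nb)
      stop("could not assemble ", nf + nb, " mutually compatible barcodes",
           call. = FALSE)
    seqs <- cands$sequence[match(ids, cands$id)]
    fwd <- setNames(seqs[seq_len(nf)], paste0("F", seq_len(nf)))
    bwd <- setNames(seqs[nf + seq_len(nb)], paste0("B", seq_len(nb)))
    grid <- expand.grid(fwd_id = names(fwd), rev_id = names(bwd),
                        stringsAsFactors = FALSE)[seq_len(nSamples), ]
    samples <- data.frame(sample = sprintf("S%02d", seq_len(nSamples)),
                          grid, stringsAsFactors = FALSE)
    anchors <- randomDnaInternal(2L, anchorLength)
    BarcodeManifest(fwd, bwd, samples, anchors[1], anchors[2])
  })
}

randomDnaInternal <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Simulate a phased cohort for haplotype and editability accounting
#'
#' Plants per-chromosome-class haplotypes at exact frequencies (largest
#' remainder rounding of \code{freq * n}), pairs normal and expanded
#' chromosomes by a seeded permutation, and returns the phased genotype
#' table together with the exact haplotype frequencies realised.
#'
#' @param nIndividuals cohort size.
#' @param haplotypes named list of 0/1 indicator vectors over the SNP panel
#'   (1 = alternative allele). The all-reference haplotype plays the role of
#'   Hap1.
#' @param freqNormal,freqExpanded named numeric frequencies (summing to 1)
#'   over \code{names(haplotypes)} for the normal and expanded chromosome
#'   class.
#' @param panel character vector of SNP identifiers (length of every
#'   indicator vector).
#' @param seed integer seed.
#' @return list with \code{genotypes} (long data.frame: individual, snp,
#'   normal, expanded), \code{hapNormal}, \code{hapExpanded} (assigned
#'   haplotype name per individual), and \code{realizedFreq} (per class).
#' @export
simulateCohort <- function(nIndividuals, haplotypes, freqNormal,
                           freqExpanded, panel, seed = NULL) {
  stopifnot(abs(sum(freqNormal) - 1) < 1e-9,
            abs(sum(freqExpanded) - 1) < 1e-9,
            all(names(freqNormal) %in% names(haplotypes)),
            all(names(freqExpanded) %in% names(haplotypes)),
            all(vapply(haplotypes, length, integer(1)) == length(panel)))
  exactCounts <- function(freq) {
    raw <- freq * nIndividuals
    cnt <- floor(raw)
    rem <- nIndividuals - sum(cnt)
    if (rem > 0) {
      up <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[up] <- cnt[up] + 1
    }
    cnt
  }
  .withSeed(seed, {
    cn <- exactCounts(freqNormal)
    ce <- exactCounts(freqExpanded)
    hapN <- sample(rep(names(freqNormal), cn))
    hapE <- sample(rep(names(freqExpanded), ce))
    geno <- do.call(rbind, lapply(seq_len(nIndividuals), function(i) {
      data.frame(individual = sprintf("I%03d", i), snp = panel,
                 normal = haplotypes[[hapN[i]]],
                 expanded = haplotypes[[hapE[i]]],
                 stringsAsFactors = FALSE)
    }))
    list(genotypes = geno, hapNormal = hapN, hapExpanded = hapE,
         realizedFreq = list(
           normal = table(hapN) / nIndividuals,
           expanded = table(hapE) / nIndividuals))
  })
}
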