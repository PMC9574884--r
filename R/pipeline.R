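## end-to-end orchestration with a shared config, per-stage seeds and a
## provenance record

#' Default pipeline configuration
#'
#' Thresholds default to the values used throughout the workflow: barcode
#' mapping quality 30, minimum 50 reads per allele, expansion threshold 36
#' repeat units, 200x down-sampling before SNP calling, pileup depth 50
#' with homozygous fraction 0.7, reference-identity screen 0.80, seed word
#' size 6, and the chi-square 95\% surface cutoff for read filtering. One
#' global seed fans out to per-stage derived seeds, so each stage is
#' individually reproducible.
#'
#' @param outDir output directory.
#' @param seed global integer seed.
#' @param ... overrides for any listed field.
#' @return named list.
#' @export
pipelineConfig <- function(outDir, seed = 1L, ...) {
  cfg <- list(outDir = outDir, seed = as.integer(seed),
              min_mapq = 30L, min_reads = 50L, expansion_threshold = 36L,
              target_coverage = 200L, identity = 0.80, word_size = 6L,
              chi2_cutoff = qchisq(0.95, 2), homozygous_fraction = 0.7,
              min_depth = 50L, decoy_units = 1000L,
              coverage = 100L,
              error_rates = c(sub = 0.01, ins = 0.03, del = 0.03))
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

.stageDir <- function(config, stage, force) {
  d <- file.path(config$outDir, stage)
  if (dir.exists(d) && length(list.files(d)) > 0 && !force)
    stop("output for stage '", stage, "' already exists in ", d,
         "; re-run with force = TRUE", call. = FALSE)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

.needFile <- function(path, stage) {
  if (!file.exists(path))
    stop("stage '", stage, "' is missing its input: ", path, call. = FALSE)
  path
}

## template position -> locus region coordinate; repeat-tract positions are
## not comparable across alleles and return NULL
.positionToRegion <- function(locus, m, n, pos) {
  l1 <- nchar(locus@leftFlank)
  r1 <- m * nchar(locus@motif1)
  li <- nchar(locus@interstitial)
  r2 <- n * nchar(locus@motif2)
  if (pos <= l1) return(list(region = "left", offset = pos))
  pos <- pos - l1
  if (pos <= r1) return(NULL)
  pos <- pos - r1
  if (pos <= li) return(list(region = "inter", offset = pos))
  pos <- pos - li
  if (pos <= r2) return(NULL)
  list(region = "right", offset = pos - r2)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order on one multiplexed pool:
#' \code{simulate} (optional; builds a ground-truthed pool),
#' \code{demux}, \code{quantify}, \code{phase}, \code{call} (per-allele SNP
#' consensus), \code{pam}, \code{haplotypes}, and \code{editability}. Each
#' stage reads the previous stage's declared outputs from
#' \code{config$outDir} and appends a summary to the run report; a
#' provenance JSON with the effective configuration, seed and package
#' version is written at the start.
#'
#' @param config list from \code{\link{pipelineConfig}}; for the simulate
#'   stage it must carry \code{locus}, \code{manifest} and \code{samples}
#'   (see \code{\link{simulatePool}}), otherwise \code{locus},
#'   \code{manifest} and \code{fastq}.
#' @param stages ordered subset of the stage names above.
#' @param force overwrite existing stage outputs.
#' @return invisibly, a list with per-stage summaries.
#' @export
runPipeline <- function(config,
                        stages = c("simulate", "demux", "quantify",
                                   "phase", "call", "pam", "haplotypes",
                                   "editability"),
                        force = FALSE) {
  known <- c("simulate", "demux", "quantify", "phase", "call", "pam",
             "haplotypes", "editability")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown stage name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(
    package = "ampliphase",
    version = as.character(utils::packageVersion("ampliphase")),
    seed = config$seed, stages = stages,
    thresholds = config[setdiff(names(config),
                                c("locus", "manifest", "samples"))])
  jsonlite::write_json(prov, file.path(config$outDir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report <- list()
  log <- function(stage, ...) {
    line <- sprintf("[%s] %s", stage, paste0(...))
    message(line)
    cat(line, "\n", file = file.path(config$outDir, "run_report.txt"),
        append = TRUE)
  }

  for (stage in stages) {
    if (stage == "simulate") {
      d <- .stageDir(config, "simulate", force)
      pool <- simulatePool(config$samples, config$locus, config$manifest,
                           coverage = config$coverage,
                           errorRates = config$error_rates,
                           seed = .deriveSeed(config$seed, "simulate"),
                           outDir = d)
      config$fastq <- pool$files[["fastq"]]
      report$simulate <- list(reads = nrow(pool$truth))
      log(stage, nrow(pool$truth), " reads simulated")
    } else if (stage == "demux") {
      d <- .stageDir(config, "demux", force)
      fq <- .needFile(config$fastq %||%
                        file.path(config$outDir, "simulate", "pool.fastq"),
                      stage)
      res <- demuxRun(fq, config$manifest, d,
                      mapqThreshold = config$min_mapq)
      report$demux <- res$summary
      nAssigned <- sum(res$assignments$reason == "assigned")
      log(stage, nAssigned, "/", nrow(res$assignments), " reads assigned")
    } else if (stage == "quantify") {
      d <- .stageDir(config, "quantify", force)
      demuxDir <- file.path(config$outDir, "demux")
      fqs <- list.files(demuxDir, pattern = "\\.fastq$", full.names = TRUE)
      fqs <- fqs[basename(fqs) != "unassigned.fastq"]
      if (!length(fqs)) stop("stage 'quantify' found no demultiplexed ",
                             "FASTQ in ", demuxDir, call. = FALSE)
      for (fq in fqs) {
        smp <- sub("\\.fastq$", "", basename(fq))
        q <- quantifySample(fq, config$locus,
                            decoyUnits = config$decoy_units)
        write.table(q$profiles, file.path(d, paste0(smp, ".profiles.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        writeLines(q$unquantified,
                   file.path(d, paste0(smp, ".unquantified.txt")))
        log(stage, smp, ": ", nrow(q$profiles), " profiles, ",
            length(q$unquantified), " unquantified")
      }
      report$quantify <- length(fqs)
    } else if (stage == "phase") {
      d <- .stageDir(config, "phase", force)
      profs <- list.files(file.path(config$outDir, "quantify"),
                          pattern = "\\.profiles\\.tsv$", full.names = TRUE)
      if (!length(profs)) stop("stage 'phase' found no profiles",
                               call. = FALSE)
      for (pf in profs) {
        smp <- sub("\\.profiles\\.tsv$", "", basename(pf))
        prof <- read.delim(pf, stringsAsFactors = FALSE)
        res <- phaseSample(prof,
                           seed = .deriveSeed(config$seed,
                                              paste0("phase_", smp)),
                           chi2Cutoff = config$chi2_cutoff,
                           minReads = config$min_reads,
                           expansionThreshold = config$expansion_threshold)
        groups <- alleleGroups(res)
        for (g in groups)
          writeLines(readIds(g),
                     file.path(d, sprintf("%s.%s.reads.txt", smp,
                                          g@label)))
        jsonlite::write_json(list(
          sample = smp, qc_pass = qcPass(res), qc_reason = res@qcReason,
          n_outliers = length(res@discardedOutliers),
          n_low_probability = length(res@discardedLowProbability),
          alleles = lapply(groups, function(g) list(
            label = g@label, role = alleleRole(g),
            m = repeatEstimate(g)[1], n = repeatEstimate(g)[2],
            mean = g@mean, covariance = g@covariance,
            n_reads = length(readIds(g))))),
          file.path(d, paste0(smp, ".phase.json")), auto_unbox = TRUE,
          digits = NA)
        log(stage, smp, ": QC ", if (qcPass(res)) "pass" else
          paste0("fail (", res@qcReason, ")"),
          "; discarded ", length(res@discardedOutliers), " outliers, ",
          length(res@discardedLowProbability), " low-probability")
      }
      report$phase <- length(profs)
    } else if (stage == "call") {
      d <- .stageDir(config, "call", force)
      phaseDir <- file.path(config$outDir, "phase")
      js <- list.files(phaseDir, pattern = "\\.phase\\.json$",
                       full.names = TRUE)
      if (!length(js)) stop("stage 'call' found no phasing results",
                            call. = FALSE)
      genoRows <- list()
      for (jf in js) {
        ph <- jsonlite::read_json(jf, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
        smp <- ph$sample
        if (!isTRUE(ph$qc_pass)) next
        fq <- .needFile(file.path(config$outDir, "demux",
                                  paste0(smp, ".fastq")), stage)
        x <- .readFastq(fq)
        reads <- setNames(as.character(x), sub(" .*", "", names(x)))
        for (al in ph$alleles) {
          idsFile <- file.path(phaseDir, sprintf("%s.%s.reads.txt", smp,
                                                 al$label))
          ids <- intersect(readLines(idsFile), names(reads))
          tpl <- locusTemplate(config$locus, al$m, al$n)
          sel <- downsampleReads(reads[ids],
                                 targetCoverage = config$target_coverage,
                                 ampliconLength = nchar(tpl),
                                 seed = .deriveSeed(config$seed,
                                                    paste0(smp, al$role)))
          calls <- callAlleleSnps(sel, tpl, minDepth = config$min_depth,
                                  homozygousFraction =
                                    config$homozygous_fraction,
                                  allele = al$role)
          writeSnpVcf(calls, file.path(d, sprintf("%s.%s.vcf", smp,
                                                  al$role)))
          if (nrow(calls)) {
            reg <- lapply(calls$position, .positionToRegion,
                          locus = config$locus, m = al$m, n = al$n)
            keep <- !vapply(reg, is.null, logical(1))
            calls <- calls[keep, , drop = FALSE]
            reg <- reg[keep]
            calls$key <- vapply(seq_along(reg), function(i)
              sprintf("%s:%d:%s>%s", reg[[i]]$region, reg[[i]]$offset,
                      calls$ref_base[i], calls$alt_base[i]), character(1))
          } else calls$key <- character(0)
          genoRows[[paste(smp, al$label)]] <-
            data.frame(sample = smp, role = al$role,
                       key = if (nrow(calls)) calls$key else NA_character_,
                       stringsAsFactors = FALSE)
          log(stage, smp, " ", al$role, ": ", nrow(calls), " SNP call(s)")
        }
      }
      geno <- if (length(genoRows)) do.call(rbind, genoRows) else
        data.frame(sample = character(0), role = character(0),
                   key = character(0), stringsAsFactors = FALSE)
      rownames(geno) <- NULL
      write.table(geno, file.path(d, "allele_snps.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      report$call <- nrow(geno)
    } else if (stage == "pam") {
      d <- .stageDir(config, "pam", force)
      snpFile <- .needFile(file.path(config$outDir, "call",
                                     "allele_snps.tsv"), stage)
      geno <- read.delim(snpFile, stringsAsFactors = FALSE)
      keys <- unique(geno$key)
      keys <- keys[!is.na(keys) & nzchar(keys)]
      eff <- NULL
      for (k in keys) {
        parts <- strsplit(k, "[:>]")[[1]]
        regionSeq <- switch(parts[1], left = config$locus@leftFlank,
                            inter = config$locus@interstitial,
                            right = config$locus@rightFlank)
        off <- as.integer(parts[2])
        # classify in a template context so flanking sequence is real
        tpl <- locusTemplate(config$locus, 1, 1)
        pos <- snpTemplatePosition(config$locus, 1, 1, parts[1], off)
        eff <- rbind(eff, classifyPamEffect(pos, parts[3], parts[4], tpl,
                                            snpId = k))
      }
      if (is.null(eff)) eff <- classifyPamEffect(2, "G", "A", "TGGTT")[0, ]
      write.table(eff, file.path(d, "pam_effects.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      report$pam <- nrow(eff)
      log(stage, nrow(eff), " PAM effect row(s) across ", length(keys),
          " SNP(s)")
    } else if (stage == "haplotypes" || stage == "editability") {
      d <- .stageDir(config, stage, force)
      snpFile <- .needFile(file.path(config$outDir, "call",
                                     "allele_snps.tsv"), stage)
      geno <- read.delim(snpFile, stringsAsFactors = FALSE)
      panel <- sort(unique(geno$key[!is.na(geno$key) & nzchar(geno$key)]))
      samples <- unique(geno$sample)
      long <- do.call(rbind, lapply(samples, function(s) {
        data.frame(individual = s, snp = panel,
                   normal = as.integer(panel %in%
                     geno$key[geno$sample == s & geno$role == "normal"]),
                   expanded = as.integer(panel %in%
                     geno$key[geno$sample == s & geno$role == "expanded"]),
                   stringsAsFactors = FALSE)
      }))
      if (stage == "haplotypes") {
        if (!length(panel)) {
          log(stage, "no SNPs; single reference haplotype")
          report$haplotypes <- 0L
        } else {
          res <- assembleHaplotypes(long, panel)
          write.table(res$table, file.path(d, "haplotypes.tsv"),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          write.table(res$assignments,
                      file.path(d, "haplotype_assignments.tsv"),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          report$haplotypes <- nrow(res$table)
          log(stage, nrow(res$table), " haplotype(s) across ",
              length(samples), " sample(s)")
        }
      } else {
        effFile <- .needFile(file.path(config$outDir, "pam",
                                       "pam_effects.tsv"), stage)
        eff <- read.delim(effFile, stringsAsFactors = FALSE)
        if (!nrow(eff) || !length(panel)) {
          log(stage, "no PAM-effect SNP; nobody editable")
          report$editability <- 0
        } else {
          rep_ <- editabilityReport(long, setNames(eff[, c("snp",
                                                           "effect")],
                                                   c("snp", "effect")))
          write.table(rep_$perSnp, file.path(d, "editability_per_snp.tsv"),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          write.table(rep_$perIndividual,
                      file.path(d, "editability_per_individual.tsv"),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          report$editability <- rep_$anyFraction
          log(stage, sprintf("%.1f%% of samples editable via >=1 SNP",
                             100 * rep_$anyFraction))
        }
      }
    }
  }
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
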