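test_that("zero-error simulation emits exact template copies", {
  loc <- exampleLocus()
  sim <- simulateDiploidReads(loc, list(m = 20, n = 7), list(m = 45, n = 10),
                              coverage = 5,
                              errorRates = c(sub = 0, ins = 0, del = 0),
                              seed = 1)
  t1 <- alleleTemplate(loc, 20, 7)
  t2 <- alleleTemplate(loc, 45, 10)
  for (i in seq_along(sim$reads)) {
    tr <- sim$truth[i, ]
    tpl <- if (tr$allele == 1) t1 else t2
    rd <- sim$reads[[i]]
    if (tr$orientation == "reverse") rd <- revComp(rd)
    expect_identical(rd, tpl)
  }
})

test_that("empirical edit distance tracks the configured error rates", {
  loc <- exampleLocus()
  rates <- c(sub = 0.01, ins = 0.03, del = 0.03)
  sim <- simulateDiploidReads(loc, list(m = 20, n = 7), list(m = 45, n = 10),
                              coverage = 50, errorRates = rates,
                              flipProb = 0, seed = 2)
  t1 <- alleleTemplate(loc, 20, 7)
  t2 <- alleleTemplate(loc, 45, 10)
  dists <- vapply(seq_along(sim$reads), function(i) {
    tpl <- if (sim$truth$allele[i] == 1) t1 else t2
    utils::adist(sim$reads[[i]], tpl) / nchar(tpl)
  }, numeric(1))
  expect_equal(mean(dists), sum(rates), tolerance = 0.2)
})

test_that("simulation is byte-identical under a fixed seed", {
  loc <- exampleLocus()
  man <- simManifest(2, anchorLength = 64, seed = 3)
  samples <- lapply(1:2, function(i) {
    row <- man@samples[i, ]
    list(name = row$sample, fwd_id = row$fwd_id, rev_id = row$rev_id,
         allele1 = list(m = 20, n = 7), allele2 = list(m = 40, n = 7))
  })
  d1 <- tempfile(); d2 <- tempfile()
  simulatePool(samples, loc, man, coverage = 3, seed = 11, outDir = d1)
  simulatePool(samples, loc, man, coverage = 3, seed = 11, outDir = d2)
  expect_identical(readLines(file.path(d1, "pool.fastq")),
                   readLines(file.path(d2, "pool.fastq")))
})

test_that("SNPs cannot be planted inside a repeat tract", {
  loc <- exampleLocus()
  expect_error(alleleTemplate(loc, 20, 7,
                              data.frame(region = "repeat1", offset = 2,
                                         alt = "A")),
               "restricted")
  expect_error(alleleTemplate(loc, 20, 7,
                              data.frame(region = "left", offset = 9999,
                                         alt = "A")),
               "outside")
})

test_that("the full pipeline recovers simulated ground truth end to end", {
  loc <- exampleLocus()
  man <- simManifest(3, anchorLength = 128, seed = 4)
  truthAlleles <- list(c(18, 7), c(22, 10), c(27, 7))
  expandedAlleles <- list(c(42, 7), c(50, 10), c(44, 7))
  # a loss-type SNP on the left flank, phased to the expanded allele
  snpOff <- 30L
  refB <- substr(loc@leftFlank, snpOff, snpOff)
  altB <- setdiff(c("A", "C", "G", "T"), refB)[1]
  samples <- lapply(1:3, function(i) {
    row <- man@samples[i, ]
    list(name = row$sample, fwd_id = row$fwd_id, rev_id = row$rev_id,
         allele1 = list(m = truthAlleles[[i]][1], n = truthAlleles[[i]][2]),
         allele2 = list(m = expandedAlleles[[i]][1],
                        n = expandedAlleles[[i]][2],
                        snps = data.frame(region = "left",
                                          offset = snpOff, alt = altB)))
  })
  out <- tempfile("pipeline")
  cfg <- pipelineConfig(out, seed = 9, locus = loc, manifest = man,
                        samples = samples, coverage = 80L,
                        min_reads = 50L)
  rep <- runPipeline(cfg)

  # demux: every read assigned to its true sample
  truth <- read.delim(file.path(out, "simulate", "truth.tsv"))
  asg <- read.delim(file.path(out, "demux", "assignments.tsv"))
  m <- merge(truth, asg, by = "read_id")
  expect_gte(mean(m$sample.x == m$sample.y, na.rm = TRUE), 0.99)

  # phasing: every sample passes QC with both alleles within +-1 unit
  for (i in 1:3) {
    smp <- man@samples$sample[i]
    ph <- jsonlite::read_json(file.path(out, "phase",
                                        paste0(smp, ".phase.json")),
                              simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
    expect_true(isTRUE(ph$qc_pass), info = smp)
    roles <- vapply(ph$alleles, `[[`, character(1), "role")
    est <- vapply(ph$alleles, function(a) c(a$m, a$n), numeric(2))
    expect_setequal(roles, c("normal", "expanded"))
    expect_lte(abs(est[1, roles == "normal"] - truthAlleles[[i]][1]), 1)
    expect_lte(abs(est[1, roles == "expanded"] - expandedAlleles[[i]][1]),
               1)
    expect_equal(est[2, roles == "normal"], truthAlleles[[i]][2])
  }

  # SNP calls: the planted expanded-allele SNP found in every sample,
  # nothing on the normal alleles
  geno <- read.delim(file.path(out, "call", "allele_snps.tsv"))
  key <- sprintf("left:%d:%s>%s", snpOff, refB, altB)
  expect_equal(sum(geno$key == key & geno$role == "expanded",
                   na.rm = TRUE), 3L)
  expect_equal(sum(!is.na(geno$key) & geno$role == "normal"), 0L)

  # editability: the loss/gain classification of the planted SNP decides
  eff <- read.delim(file.path(out, "pam", "pam_effects.tsv"))
  perInd <- read.delim(file.path(out, "editability",
                                 "editability_per_individual.tsv"))
  if (any(eff$effect == "gain")) {
    expect_true(all(perInd$editable))   # alt on expanded = gain editable
  } else {
    expect_false(any(perInd$editable))  # loss-type needs alt on normal
  }

  # re-run without force refuses; unknown stage errors
  expect_error(runPipeline(cfg, stages = "demux"), "force")
  expect_error(runPipeline(cfg, stages = "frobnicate"), "unknown stage")
  expect_true(file.exists(file.path(out, "provenance.json")))
})
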