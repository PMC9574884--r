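effKey <- function(d) paste(d$enzyme, d$effect, d$strand, d$ref_motif,
                            d$alt_motif)

test_that("down-sampling caps coverage and is reproducible", {
  rds <- setNames(rep(strrep("ACGT", 100), 400), paste0("r", 1:400))
  kept <- downsampleReads(rds, targetCoverage = 200, ampliconLength = 400,
                          seed = 1)
  expect_length(kept, 200L)                     # 400 reads -> 200 kept
  below <- downsampleReads(rds[1:150], targetCoverage = 200,
                           ampliconLength = 400, seed = 1)
  expect_length(below, 150L)                    # below target: no-op
  expect_identical(names(kept),
                   names(downsampleReads(rds, 200, 400, seed = 1)))
  expect_false(identical(names(kept),
                         names(downsampleReads(rds, 200, 400, seed = 2))))
})

test_that("pileup caller recovers planted per-allele SNPs exactly", {
  loc <- exampleLocus(flankLength = 80)
  snps <- data.frame(region = c("left", "inter", "right"),
                     offset = c(21, 5, 40))
  regSeq <- c(left = loc@leftFlank, inter = loc@interstitial,
              right = loc@rightFlank)
  snps$alt <- vapply(seq_len(nrow(snps)), function(i)
    setdiff(c("A", "C", "G", "T"),
            substr(regSeq[[snps$region[i]]], snps$offset[i],
                   snps$offset[i]))[1], character(1))
  ref <- alleleTemplate(loc, 20, 7)        # reference without SNPs
  sim <- simulateDiploidReads(loc, list(m = 20, n = 7, snps = snps),
                              list(m = 20, n = 7, snps = snps),
                              coverage = 50,
                              errorRates = c(sub = 0.01, ins = 0, del = 0),
                              flipProb = 0.5, seed = 20)
  calls <- callAlleleSnps(sim$reads, ref, minDepth = 50,
                          allele = "expanded")
  truthPos <- vapply(seq_len(nrow(snps)), function(i)
    snpTemplatePosition(loc, 20, 7, snps$region[i], snps$offset[i]),
    integer(1))
  expect_setequal(calls$position, truthPos)
  expect_equal(calls$alt_base[order(calls$position)],
               snps$alt[order(truthPos)])
  expect_true(all(calls$allele == "expanded"))

  # error-free reads without planted SNPs: zero calls
  clean <- simulateDiploidReads(loc, list(m = 20, n = 7),
                                list(m = 20, n = 7), coverage = 30,
                                errorRates = c(sub = 0, ins = 0, del = 0),
                                seed = 21)
  expect_equal(nrow(callAlleleSnps(clean$reads, ref, minDepth = 50)), 0L)

  # depth guard: 40x coverage cannot reach minDepth 50
  low <- simulateDiploidReads(loc, list(m = 20, n = 7, snps = snps[1, ]),
                              list(m = 20, n = 7, snps = snps[1, ]),
                              coverage = 20,
                              errorRates = c(sub = 0, ins = 0, del = 0),
                              seed = 22)
  expect_equal(nrow(callAlleleSnps(low$reads, ref, minDepth = 50)), 0L)
})

test_that("VCF output round-trips the calls", {
  calls <- data.frame(position = c(21L, 130L), ref_base = c("A", "G"),
                      alt_base = c("T", "A"),
                      allele = c("normal", "expanded"),
                      depth = c(80L, 95L), alt_fraction = c(0.98, 0.91))
  path <- tempfile(fileext = ".vcf")
  writeSnpVcf(calls, path)
  lines <- readLines(path)
  expect_equal(sum(!startsWith(lines, "#")), 2L)
  expect_match(lines[1], "VCFv4.2")
  body <- strsplit(lines[!startsWith(lines, "#")][1], "\t")[[1]]
  expect_equal(body[c(2, 4, 5)], c("21", "A", "T"))
  expect_match(body[8], "ALLELE=normal;DP=80")
})

test_that("classifier resolves canonical PAM gain and loss cases", {
  # SpCas9 NGG destroyed on the negative strand (TG[G] -> TG[C])
  eff <- classifyPamEffect(6, "C", "G", "AAAAACCAAAAAA")
  spc <- eff[eff$enzyme == "SpCas9" & eff$strand == "negative", ]
  expect_equal(spc$effect, "loss")
  expect_equal(spc$ref_motif, "TG[G]")
  expect_equal(spc$alt_motif, "TG[C]")

  # SaCas9 NNGRRT destroyed (TC[G]AGT -> TC[A]AGT)
  eff16 <- classifyPamEffect(9, "G", "A", "TATTATTCGAGTTATTA")
  sa <- eff16[eff16$enzyme == "SaCas9", ]
  expect_equal(sa$effect, "loss")
  expect_equal(sa$strand, "positive")
  expect_equal(sa$ref_motif, "TC[G]AGT")
  expect_equal(sa$alt_motif, "TC[A]AGT")

  # AsCpf1 TTTN destroyed on the negative strand (TT[T]T -> TT[C]T)
  eff17 <- classifyPamEffect(6, "A", "G", "TATTAAAAATTAT")
  cp <- eff17[eff17$enzyme == "AsCpf1", ]
  expect_true(all(cp$effect == "loss"))
  expect_true(all(cp$strand == "negative"))
  expect_true("TT[T]T" %in% cp$ref_motif)

  # both alleles carry an NGG at the same window: no SpCas9 effect
  effBoth <- classifyPamEffect(2, "G", "A", "TGGTT")
  expect_equal(nrow(effBoth[effBoth$enzyme == "SpCas9", ]), 0L)
})

test_that("the 19-SNP regression fixture reproduces every tabulated cell", {
  ctx <- read.delim(system.file("extdata",
                                "snp_pam_synthetic_contexts.tsv",
                                package = "ampliphase"),
                    stringsAsFactors = FALSE)
  expd <- read.delim(system.file("extdata",
                                 "snp_pam_expected_effects.tsv",
                                 package = "ampliphase"),
                     stringsAsFactors = FALSE)
  expect_equal(nrow(ctx), 19L)
  for (i in seq_len(nrow(ctx))) {
    s <- ctx$snp[i]
    eff <- classifyPamEffect(ctx$position[i], ctx$ref[i], ctx$alt[i],
                             ctx$context[i], snpId = s)
    want <- expd[expd$snp == s, ]
    # every tabulated cell (enzyme, effect, strand, motifs) is reproduced
    expect_true(all(effKey(want) %in% effKey(eff)), info = s)
    if (nrow(want) == 0L) {
      expect_equal(nrow(eff), 0L, info = s)   # the "no effect" rows
    } else {
      # extras are confined to enzymes the table does not list at this
      # SNP, plus additional poly-T AsCpf1 loss offsets at SNP17
      extra <- eff[!effKey(eff) %in% effKey(want), , drop = FALSE]
      onTab <- extra[extra$enzyme %in% want$enzyme, , drop = FALSE]
      if (s == "SNP17") onTab <- onTab[onTab$enzyme != "AsCpf1", ,
                                       drop = FALSE]
      expect_equal(nrow(onTab), 0L, info = s)
    }
  }
})

test_that("swapping ref and alt converts gains to losses and back", {
  ctx <- read.delim(system.file("extdata",
                                "snp_pam_synthetic_contexts.tsv",
                                package = "ampliphase"),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ctx))) {
    fwd <- classifyPamEffect(ctx$position[i], ctx$ref[i], ctx$alt[i],
                             ctx$context[i])
    swapCtx <- ctx$context[i]
    substr(swapCtx, ctx$position[i], ctx$position[i]) <- ctx$alt[i]
    rev <- classifyPamEffect(ctx$position[i], ctx$alt[i], ctx$ref[i],
                             swapCtx)
    flip <- function(x) ifelse(x == "gain", "loss", "gain")
    expect_setequal(
      paste(fwd$enzyme, flip(fwd$effect), fwd$strand, fwd$alt_motif,
            fwd$ref_motif),
      paste(rev$enzyme, rev$effect, rev$strand, rev$ref_motif,
            rev$alt_motif))
  }
  expect_error(classifyPamEffect(2, "G", "A", "TGGTT",
                                 rules = data.frame(enzyme = "x",
                                                    motif = "NQG",
                                                    efficiency = "high")),
               "IUPAC")
})

test_that("amplicon lengths follow 1-based inclusive arithmetic", {
  expect_equal(ampliconLength(3069608, 3075517), 5910L)
  expect_equal(ampliconLength(3071119, 3079972), 8854L)
  expect_equal(ampliconLength(3069608, 3079972), 10365L)
  expect_error(ampliconLength(10, 9), "start")
})
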