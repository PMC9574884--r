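demoManifest <- function(nSamples = 4, seed = 2, anchorLength = 128L) {
  simManifest(nSamples, barcodeLength = 32L, anchorLength = anchorLength,
              seed = seed)
}

demoSamples <- function(manifest, alleles = list(c(20, 7), c(45, 10))) {
  lapply(seq_len(nrow(manifest@samples)), function(i) {
    row <- manifest@samples[i, ]
    list(name = row$sample, fwd_id = row$fwd_id, rev_id = row$rev_id,
         allele1 = list(m = alleles[[1]][1], n = alleles[[1]][2]),
         allele2 = list(m = alleles[[2]][1], n = alleles[[2]][2]))
  })
}

noErr <- c(sub = 0, ins = 0, del = 0)

test_that("an error-free read yields its true barcode at the mapq cap", {
  man <- demoManifest()
  loc <- exampleLocus()
  pool <- simulatePool(demoSamples(man), loc, man, coverage = 1,
                       errorRates = noErr, flipProb = 0, seed = 3)
  rd <- pool$reads[[1]]
  truthSample <- pool$truth$sample[1]
  truthRow <- man@samples[man@samples$sample == truthSample, ]
  f <- matchBarcodeSide(rd, "forward", man)
  b <- matchBarcodeSide(rd, "backward", man)
  expect_equal(f$id, truthRow$fwd_id)
  expect_equal(b$id, truthRow$rev_id)
  expect_equal(f$mapq, 60L)
  expect_equal(b$mapq, 60L)
})

test_that("reads with randomised barcode regions are unassignable", {
  man <- demoManifest()
  loc <- exampleLocus()
  tpl <- alleleTemplate(loc, 20, 7)
  set.seed(4)
  passed <- 0L
  for (i in seq_len(100)) {
    rd <- paste0(randomDna(1, 32), man@anchorForward, tpl,
                 man@anchorBackward, revComp(randomDna(1, 32)))
    a <- demuxRead(rd, man)
    if (a$reason == "assigned") passed <- passed + 1L
  }
  expect_equal(passed, 0L)
})

test_that("near-identical competing barcodes give the frozen mapq gap", {
  loc <- exampleLocus()
  anchor <- substr(alleleTemplate(loc, 20, 7), 1, 128)
  bc1 <- "ACGTTGCAACGGATAGTGCATCACGTTGACTG"
  bc2 <- bc1
  substr(bc2, 16, 16) <- "T"   # single-base difference
  man <- BarcodeManifest(setNames(c(bc1, bc2), c("F1", "F2")),
                         setNames("TGCACTTGGATCCATAACGGTTCAGTGCAATC", "B1"),
                         data.frame(sample = "S1", fwd_id = "F1",
                                    rev_id = "B1"),
                         anchor, anchor)
  rd <- paste0(bc1, anchor, strrep("CAG", 30), anchor,
               revComp("TGCACTTGGATCCATAACGGTTCAGTGCAATC"))
  f <- matchBarcodeSide(rd, "forward", man)
  expect_equal(f$id, "F1")
  # anchor-corrected scores: exact barcode scores +32, the 1-bp competitor
  # loses one match and pays one mismatch -> 29; frozen formula value:
  expect_equal(f$mapq, min(60L, as.integer(round(60 * (32 - 29) / 32))))
})

test_that("assignment needs both sides confident and a known pair", {
  man <- demoManifest()
  loc <- exampleLocus()
  pool <- simulatePool(demoSamples(man), loc, man, coverage = 1,
                       errorRates = noErr, flipProb = 0, seed = 5)
  rd <- pool$reads[[1]]
  a <- demuxRead(rd, man)
  expect_equal(a$reason, "assigned")
  expect_equal(a$sample, pool$truth$sample[1])

  # corrupt the backward barcode only
  rd2 <- paste0(substr(rd, 1, nchar(rd) - 32), revComp(randomDna(1, 32)))
  a2 <- demuxRead(rd2, man)
  expect_equal(a2$reason, "low_mapq")
  expect_gte(a2$forward_mapq, 30L)
  expect_lt(a2$backward_mapq, 30L)

  # a confidently matched pair that is absent from the sample map
  man2 <- man
  man2@samples <- man@samples[-2, , drop = FALSE]
  missingPair <- man@samples[2, ]
  rd3 <- pool$reads[pool$truth$sample == missingPair$sample][[1]]
  a3 <- demuxRead(rd3, man2)
  expect_equal(a3$reason, "unexpected_pair")
})

test_that("raising the mapq threshold never increases assignments", {
  man <- demoManifest()
  loc <- exampleLocus()
  pool <- simulatePool(demoSamples(man), loc, man, coverage = 3, seed = 6)
  counts <- vapply(c(0L, 30L, 55L), function(th)
    sum(vapply(pool$reads, function(r)
      demuxRead(r, man, mapqThreshold = th)$reason == "assigned",
      logical(1))), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("demuxRun conserves reads and recovers the simulated pool", {
  man <- demoManifest()
  loc <- exampleLocus()
  outPool <- tempfile("pool")
  pool <- simulatePool(demoSamples(man), loc, man, coverage = 5,
                       errorRates = noErr, seed = 7, outDir = outPool)
  outDemux <- tempfile("demux")
  res <- demuxRun(pool$files[["fastq"]], man, outDemux)

  # conservation: every read in exactly one bin
  expect_equal(sum(res$summary$Freq), nrow(pool$truth))
  written <- list.files(outDemux, pattern = "\\.fastq$")
  nOut <- sum(vapply(file.path(outDemux, written), function(f)
    length(Biostrings::readDNAStringSet(f, format = "fastq")), integer(1)))
  expect_equal(nOut, nrow(pool$truth))

  # error-free pool: per-sample counts equal the simulator ground truth
  got <- res$assignments$sample[match(pool$truth$read_id,
                                      res$assignments$read_id)]
  expect_equal(got, pool$truth$sample)

  # duplicate ids are processed as separate reads
  fq2 <- tempfile(fileext = ".fastq")
  .l <- readLines(pool$files[["fastq"]])
  writeLines(c(.l[1:4], .l[1:4]), fq2)
  res2 <- demuxRun(fq2, man, tempfile("dup"))
  expect_equal(sum(res2$summary$Freq), 2L)
})

test_that("an empty FASTQ demultiplexes to empty outputs", {
  fq <- tempfile(fileext = ".fastq")
  file.create(fq)
  out <- tempfile("empty")
  res <- demuxRun(fq, demoManifest(), out)
  expect_equal(nrow(res$assignments), 0L)
  expect_equal(sum(res$summary$Freq), 0L)
})

test_that("cross-sample misassignment is rare under the error model", {
  man <- demoManifest(nSamples = 6, seed = 8)
  loc <- exampleLocus()
  pool <- simulatePool(demoSamples(man), loc, man, coverage = 10, seed = 9)
  wrong <- 0L
  assigned <- 0L
  for (i in seq_along(pool$reads)) {
    a <- demuxRead(pool$reads[[i]], man)
    if (a$reason == "assigned") {
      assigned <- assigned + 1L
      if (a$sample != pool$truth$sample[i]) wrong <- wrong + 1L
    }
  }
  expect_gt(assigned, 0.8 * length(pool$reads))
  expect_lt(wrong / max(assigned, 1), 0.01)
})
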