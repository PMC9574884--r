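simProfiles <- function(centers, sizes, sdev = 1, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(sizes), function(k) {
    data.frame(
      read_id = sprintf("c%d_%03d", k, seq_len(sizes[k])),
      m = round(stats::rnorm(sizes[k], centers[[k]][1], sdev)),
      n = round(stats::rnorm(sizes[k], centers[[k]][2], sdev / 2)),
      truth = k)
  }))
}

test_that("3-SD outlier rule removes exactly the planted extreme read", {
  prof <- data.frame(read_id = paste0("r", 1:101),
                     m = c(rep(20, 100), 200),
                     n = rep(7, 101))
  # direct computation confirms exceedance for the planted value only
  dev <- abs(prof$m - mean(prof$m)) / sd(prof$m)
  expect_true(dev[101] > 3)
  expect_true(all(dev[1:100] <= 3))
  out <- removeOutliers(prof)
  expect_equal(out$removed$read_id, "r101")

  # identical profiles: sd = 0 removes nothing
  same <- data.frame(read_id = paste0("s", 1:10), m = 20, n = 7)
  expect_equal(nrow(removeOutliers(same)$removed), 0L)

  # deviations at 2 sd are kept
  prof2 <- data.frame(read_id = paste0("t", 1:20),
                      m = c(rep(18, 10), rep(22, 10)), n = 7)
  expect_equal(nrow(removeOutliers(prof2)$removed), 0L)
})

test_that("jittered BIC selects the diploid component count", {
  two <- simProfiles(list(c(20, 7), c(45, 7)), c(100, 100), seed = 2)
  expect_equal(selectComponentCount(two, seed = 1), 2L)

  one <- simProfiles(list(c(20, 7)), 200, seed = 3)
  expect_equal(selectComponentCount(one, seed = 1), 1L)

  # integer-rounded single cluster must not overfit to N = 2
  set.seed(12)
  degenerate <- data.frame(read_id = paste0("d", 1:150),
                           m = round(stats::rnorm(150, 20, 0.8)),
                           n = round(stats::rnorm(150, 7, 0.5)))
  expect_equal(selectComponentCount(degenerate, seed = 4), 1L)

  tiny <- simProfiles(list(c(20, 7)), 3, seed = 5)
  expect_warning(N <- selectComponentCount(tiny, seed = 1), "too few")
  expect_equal(N, 1L)
})

test_that("model selection agrees with mclust BIC on jitter-free data", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  # continuous (already jittered) data: our BIC ranking should match the
  # independent mclust implementation of a 2-component VVV mixture
  set.seed(8)
  for (sep in list(c(20, 45), c(20, 20))) {
    X <- rbind(cbind(stats::rnorm(80, sep[1], 1), stats::rnorm(80, 7, 0.6)),
               cbind(stats::rnorm(80, sep[2], 1), stats::rnorm(80, 7, 0.6)))
    bic <- mclust::mclustBIC(X, G = 1:2, modelNames = "VVV",
                             verbose = FALSE)
    mcG <- as.integer(which.max(bic[, "VVV"]))   # mclust BIC: larger wins
    prof <- data.frame(read_id = seq_len(nrow(X)), m = X[, 1], n = X[, 2])
    ours <- selectComponentCount(prof, seed = 1)
    expect_equal(ours, mcG, info = paste(sep, collapse = "/"))
  }
})

test_that("mixture fit separates alleles and applies the 95% surface", {
  prof <- simProfiles(list(c(20, 7), c(45, 10)), c(100, 100), seed = 6)
  res <- fitAndAssign(prof, 2L, seed = 1)
  expect_true(qcPass(res))
  g <- alleleGroups(res)
  expect_equal(length(g), 2L)
  # assignment accuracy against the generator truth
  ids1 <- prof$read_id[prof$truth == 1]
  ids2 <- prof$read_id[prof$truth == 2]
  expect_true(all(readIds(g[[1]]) %in% ids1))
  expect_true(all(readIds(g[[2]]) %in% ids2))
  expect_equal(repeatEstimate(g[[1]]), c(20L, 7L))
  expect_equal(repeatEstimate(g[[2]]), c(45L, 10L))

  # every discarded read is farther from its component than any kept one
  X <- cbind(prof$m, prof$n)
  for (k in 1:2) {
    d2 <- stats::mahalanobis(X, g[[k]]@mean, g[[k]]@covariance)
    kept <- prof$read_id %in% readIds(g[[k]])
    disc <- prof$read_id %in% res@discardedLowProbability &
      (if (k == 1) prof$truth == 1 else prof$truth == 2)
    if (any(disc))
      expect_gt(min(d2[disc]), max(d2[kept]))
  }
})

test_that("QC flags single-component and under-covered samples", {
  prof <- simProfiles(list(c(20, 7), c(45, 7)), c(49, 100), seed = 7)
  res <- fitAndAssign(prof, 2L, seed = 1)
  expect_false(qcPass(res))
  expect_match(res@qcReason, "less than 50 reads")

  one <- simProfiles(list(c(20, 7)), 120, seed = 8)
  res1 <- fitAndAssign(one, 1L, seed = 1)
  expect_false(qcPass(res1))
  expect_match(res1@qcReason, "single allele")
})

test_that("a read at squared Mahalanobis distance 9 is discarded", {
  prof <- simProfiles(list(c(20, 7), c(45, 7)), c(80, 80), sdev = 1,
                      seed = 9)
  res0 <- fitAndAssign(prof, 2L, seed = 1)
  g1 <- alleleGroups(res0)[[1]]
  # plant a read at d2 = 9 from component 1 along its first eigenvector
  ev <- eigen(g1@covariance)
  dirv <- ev$vectors[, 1]
  pt <- g1@mean + sqrt(9 * ev$values[1]) * dirv
  expect_equal(unname(stats::mahalanobis(rbind(pt), g1@mean,
                                         g1@covariance)), 9,
               tolerance = 1e-6)
  prof2 <- rbind(prof, data.frame(read_id = "planted", m = pt[1], n = pt[2],
                                  truth = 1))
  res <- fitAndAssign(prof2, 2L, seed = 1)
  expect_true("planted" %in% res@discardedLowProbability)
})

test_that("roles follow the 36-unit expansion threshold", {
  mk <- function(m1, m2) {
    prof <- simProfiles(list(c(m1, 7), c(m2, 7)), c(80, 80), seed = 10)
    assignRoles(fitAndAssign(prof, 2L, seed = 1))
  }
  roles <- function(res) vapply(alleleGroups(res), alleleRole, character(1))
  expect_equal(roles(mk(20, 45)), c("normal", "expanded"))
  expect_equal(roles(mk(34, 43)), c("normal", "expanded"))  # hardest case
  expect_equal(roles(mk(20, 30)), c("normal", "normal"))
})

test_that("phasing is deterministic and jitter only affects selection", {
  prof <- simProfiles(list(c(20, 7), c(45, 10)), c(100, 100), seed = 11)
  r1 <- phaseSample(prof, seed = 5)
  r2 <- phaseSample(prof, seed = 5)
  expect_identical(r1, r2)

  # different jitter seed, same selected N, same fit seed -> same assignment
  N_a <- selectComponentCount(prof, seed = 1)
  N_b <- selectComponentCount(prof, seed = 99)
  expect_equal(N_a, N_b)
  f1 <- fitAndAssign(prof, N_a, seed = 7)
  f2 <- fitAndAssign(prof, N_b, seed = 7)
  expect_identical(f1, f2)
})
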