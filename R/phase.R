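## diploid allele phasing of per-read (m, n) repeat profiles:
## 3-SD outlier pruning, jitter-stabilized BIC model selection, GMM fit,
## 95% equi-probability filtering, QC

.profileMatrix <- function(profiles) {
  stopifnot(is.data.frame(profiles), all(c("m", "n") %in% names(profiles)))
  cbind(m = as.numeric(profiles$m), n = as.numeric(profiles$n))
}

#' Remove repeat-size outlier reads
#'
#' Single-pass, per-dimension rule: a profile is removed when its m (or n)
#' deviates from the mean by more than three standard deviations of that
#' dimension. A zero-variance dimension removes nothing.
#'
#' @param profiles data.frame with columns read_id, m, n.
#' @param nSd deviation threshold in standard deviations (default 3).
#' @return list with \code{kept} and \code{removed} (both data.frames).
#' @export
removeOutliers <- function(profiles, nSd = 3) {
  stopifnot(nrow(profiles) >= 2L)
  X <- .profileMatrix(profiles)
  keep <- rep(TRUE, nrow(X))
  for (d in 1:2) {
    s <- sd(X[, d])
    if (s > 0) keep <- keep & abs(X[, d] - mean(X[, d])) <= nSd * s
  }
  list(kept = profiles[keep, , drop = FALSE],
       removed = profiles[!keep, , drop = FALSE])
}

## log density of a bivariate Gaussian
.dmvnorm2 <- function(X, mu, S) {
  Si <- solve(S)
  dt <- determinant(S, logarithm = TRUE)$modulus
  d <- sweep(X, 2, mu)
  q <- rowSums((d %*% Si) * d)
  as.numeric(-0.5 * (2 * log(2 * pi) + dt + q))
}

.regularize <- function(S, eps) {
  S <- (S + t(S)) / 2
  S + diag(eps, 2)
}

.clusterCov <- function(Xi) {
  if (nrow(Xi) < 2L) matrix(0, 2, 2) else cov(Xi) * (nrow(Xi) - 1) / nrow(Xi)
}

.logsumexp2 <- function(lg) {
  mx <- pmax(lg[, 1], lg[, 2])
  mx + log(exp(lg[, 1] - mx) + exp(lg[, 2] - mx))
}

## full-covariance Gaussian mixture via EM; 2-means initialization with
## multiple restarts, ridge regularization of the covariances
.fitGmm <- function(X, N, nstart = 10L, eps = 1e-3, maxiter = 200L,
                    tol = 1e-8) {
  n <- nrow(X)
  if (N == 1L) {
    mu <- colMeans(X)
    S <- .regularize(cov(X) * (n - 1) / n, eps)
    ll <- sum(.dmvnorm2(X, mu, S))
    return(list(N = 1L, weights = 1, means = list(mu), covs = list(S),
                loglik = ll, nParams = 5L))
  }
  best <- NULL
  for (r in seq_len(nstart)) {
    km <- tryCatch(
      suppressWarnings(kmeans(jitter(X, amount = 1e-6), centers = 2L)),
      error = function(e) NULL)
    z <- if (is.null(km)) sample(rep(1:2, length.out = n)) else km$cluster
    if (length(unique(z)) < 2L) z[seq_len(n) %% 2L == 0L] <- 2L
    w <- tabulate(z, 2) / n
    mu <- lapply(1:2, function(k) colMeans(X[z == k, , drop = FALSE]))
    S <- lapply(1:2, function(k)
      .regularize(.clusterCov(X[z == k, , drop = FALSE]), eps))
    ll_old <- -Inf
    for (it in seq_len(maxiter)) {
      lg <- vapply(1:2, function(k)
        log(w[k]) + .dmvnorm2(X, mu[[k]], S[[k]]), numeric(n))
      lse <- .logsumexp2(lg)
      ll <- sum(lse)
      resp <- exp(lg - lse)
      nk <- pmax(colSums(resp), 1e-8)
      w <- nk / n
      for (k in 1:2) {
        mu[[k]] <- colSums(X * resp[, k]) / nk[k]
        d <- sweep(X, 2, mu[[k]])
        S[[k]] <- .regularize(crossprod(d * resp[, k], d) / nk[k], eps)
      }
      if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
      ll_old <- ll
    }
    if (is.null(best) || ll > best$loglik)
      best <- list(N = 2L, weights = w, means = mu, covs = S, loglik = ll,
                   nParams = 11L)
  }
  best
}

.bic <- function(fit, n) -2 * fit$loglik + fit$nParams * log(n)

#' Select the number of allele components (1 or 2)
#'
#' The sample is diploid, so the (m, n) profiles follow a mixture of one or
#' two Gaussians. Because integer-rounded repeat sizes defeat BIC (a
#' zero-width cluster has unbounded density), uniform noise in (-0.5, 0.5)
#' is added to every m and n before model selection; one shared jittered
#' dataset is scored for N = 1 and N = 2 and the smaller BIC wins (ties
#' favour N = 1). The jitter is used only here: the final fit runs on the
#' original integers.
#'
#' @param profiles data.frame with columns m, n (at least 2 rows).
#' @param seed integer seed for the jitter and the fit initialization.
#' @param minProfiles below this many profiles (the N = 2 parameter count
#'   plus one) model selection is skipped and N = 1 returned with a
#'   warning.
#' @return integer 1 or 2.
#' @export
selectComponentCount <- function(profiles, seed = NULL, minProfiles = 12L) {
  stopifnot(nrow(profiles) >= 2L)
  X <- .profileMatrix(profiles)
  if (nrow(X) < minProfiles) {
    warning("too few profiles (", nrow(X), ") for 2-component selection; ",
            "returning N = 1")
    return(1L)
  }
  .withSeed(seed, {
    Xj <- X + runif(length(X), -0.5, 0.5)
    b1 <- .bic(.fitGmm(Xj, 1L), nrow(Xj))
    b2 <- .bic(.fitGmm(Xj, 2L), nrow(Xj))
    if (b2 < b1) 2L else 1L
  })
}

.modalPair <- function(m, n) {
  key <- paste(m, n)
  tab <- table(key)
  cand <- names(tab)[tab == max(tab)]
  parts <- do.call(rbind, strsplit(cand, " "))
  ord <- order(as.integer(parts[, 1]), as.integer(parts[, 2]))
  as.integer(parts[ord[1], ])
}

#' Fit the Gaussian mixture and assign reads to alleles
#'
#' Fits an N-component full-covariance Gaussian mixture to the original
#' integer (m, n) profiles, assigns each read to its maximum-responsibility
#' component, and discards reads outside the 95\% equi-probability surface
#' of their component (squared Mahalanobis distance above the chi-square
#' 0.95 quantile with 2 degrees of freedom, about 5.991). QC fails when
#' only one component was selected or any allele retains fewer than
#' \code{minReads} reads.
#'
#' @param profiles data.frame with columns read_id, m, n (outliers already
#'   removed; see \code{\link{removeOutliers}}).
#' @param N number of components from \code{\link{selectComponentCount}}.
#' @param seed integer seed for EM initialization restarts.
#' @param chi2Cutoff squared-Mahalanobis cutoff (default
#'   \code{qchisq(0.95, 2)}).
#' @param minReads minimum reads per allele for QC (default 50).
#' @param eps ridge added to singular covariance diagonals.
#' @return a \linkS4class{PhasingResult} (roles unassigned; see
#'   \code{\link{assignRoles}}).
#' @export
fitAndAssign <- function(profiles, N, seed = NULL,
                         chi2Cutoff = qchisq(0.95, 2), minReads = 50L,
                         eps = 1e-3) {
  stopifnot(N %in% 1:2, nrow(profiles) >= 1L)
  X <- .profileMatrix(profiles)
  .withSeed(seed, {
    fit <- .fitGmm(X, as.integer(N), eps = eps)
    if (N == 1L) {
      comp <- rep(1L, nrow(X))
    } else {
      lg <- matrix(vapply(1:2, function(k)
        log(fit$weights[k]) + .dmvnorm2(X, fit$means[[k]], fit$covs[[k]]),
        numeric(nrow(X))), ncol = 2)
      comp <- max.col(lg, ties.method = "first")
    }
    d2 <- vapply(seq_len(nrow(X)), function(i)
      mahalanobis(X[i, , drop = FALSE], fit$means[[comp[i]]],
                  fit$covs[[comp[i]]]), numeric(1))
    keep <- d2 <= chi2Cutoff
    lowp <- profiles$read_id[!keep]

    # order components by mean m so allele1 is the smaller repeat
    ord <- order(vapply(fit$means, `[`, numeric(1), 1))
    groups <- list()
    for (gi in seq_len(N)) {
      k <- ord[gi]
      sel <- keep & comp == k
      est <- if (any(sel)) .modalPair(profiles$m[sel], profiles$n[sel])
             else c(NA_integer_, NA_integer_)
      groups[[gi]] <- new("AlleleGroup", label = paste0("allele", gi),
                          mean = fit$means[[k]],
                          covariance = fit$covs[[k]],
                          readIds = profiles$read_id[sel],
                          repeatEstimate = est, role = "unassigned")
    }
    sizes <- vapply(groups, function(g) length(g@readIds), integer(1))
    qc <- TRUE
    reason <- ""
    if (N == 1L) {
      qc <- FALSE
      reason <- "single allele detected"
    } else if (any(sizes < minReads)) {
      qc <- FALSE
      reason <- sprintf("allele with less than %d reads", minReads)
    }
    new("PhasingResult", groups = groups, discardedOutliers = character(0),
        discardedLowProbability = as.character(lowp), qcPass = qc,
        qcReason = reason)
  })
}

#' Label alleles as normal or expanded
#'
#' With two allele groups, the group with the larger modal repeat count of
#' the first motif is labelled expanded when its estimate reaches
#' \code{expansionThreshold} repeat units (36 at the huntingtin locus;
#' alleles of 35 or fewer units are normal); otherwise both groups are
#' normal.
#'
#' @param result a \linkS4class{PhasingResult} with two groups.
#' @param expansionThreshold repeat units (default 36).
#' @return the result with group roles filled in.
#' @export
assignRoles <- function(result, expansionThreshold = 36L) {
  groups <- result@groups
  if (length(groups) == 2L) {
    m1 <- groups[[1]]@repeatEstimate[1]
    m2 <- groups[[2]]@repeatEstimate[1]
    larger <- if (!is.na(m1) && !is.na(m2) && m1 > m2) 1L else 2L
    for (gi in 1:2) {
      est <- groups[[gi]]@repeatEstimate[1]
      groups[[gi]]@role <-
        if (gi == larger && !is.na(est) && est >= expansionThreshold)
          "expanded" else "normal"
    }
  }
  result@groups <- groups
  result
}

#' Phase one sample end to end
#'
#' Convenience orchestration: outlier removal, jittered model selection,
#' mixture fit with equi-probability filtering, QC, and role assignment.
#'
#' @inheritParams fitAndAssign
#' @param seed integer seed driving jitter and EM initialization.
#' @param expansionThreshold see \code{\link{assignRoles}}.
#' @param nSd outlier threshold, see \code{\link{removeOutliers}}.
#' @return a \linkS4class{PhasingResult}.
#' @examples
#' prof <- data.frame(read_id = paste0("r", 1:120),
#'                    m = rep(c(20, 45), each = 60) + rep(c(0, 1), 60),
#'                    n = rep(c(7, 10), each = 60))
#' phaseSample(prof, seed = 1, minReads = 25)
#' @export
phaseSample <- function(profiles, seed = NULL,
                        chi2Cutoff = qchisq(0.95, 2), minReads = 50L,
                        expansionThreshold = 36L, nSd = 3, eps = 1e-3) {
  out <- removeOutliers(profiles, nSd = nSd)
  N <- selectComponentCount(out$kept, seed = .deriveSeed(seed, "select"))
  res <- fitAndAssign(out$kept, N, seed = .deriveSeed(seed, "fit"),
                      chi2Cutoff = chi2Cutoff, minReads = minReads,
                      eps = eps)
  res@discardedOutliers <- as.character(out$removed$read_id)
  assignRoles(res, expansionThreshold)
}
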