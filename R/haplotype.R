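## haplotype frequency tables and allele-specific editability accounting

#' Assemble haplotype frequency tables from phased genotypes
#'
#' Each QC-passed individual contributes one normal-class and one
#' expanded-class haplotype: the vector of alternative-allele indicators
#' over a fixed SNP panel. Haplotypes are keyed by that indicator vector;
#' frequencies are normalised within each chromosome class. The
#' all-reference haplotype (no SNP across the region) is labelled Hap1;
#' the remaining haplotypes are numbered by decreasing combined frequency.
#' An individual missing a genotype at any panel SNP is excluded with a
#' warning.
#'
#' @param genotypes long data.frame with columns individual, snp, normal,
#'   expanded (0 = reference, 1 = alternative; NA = missing).
#' @param panel character vector of SNP ids defining the haplotype (order
#'   fixes the indicator vector).
#' @return list with \code{table} (data.frame: haplotype, pattern,
#'   freq_normal, freq_expanded) and \code{assignments} (data.frame:
#'   individual, normal_hap, expanded_hap).
#' @export
assembleHaplotypes <- function(genotypes, panel) {
  stopifnot(all(c("individual", "snp", "normal", "expanded") %in%
                  names(genotypes)))
  genotypes <- genotypes[genotypes$snp %in% panel, , drop = FALSE]
  wide <- split(genotypes, genotypes$individual)
  pat <- lapply(wide, function(g) {
    idx <- match(panel, g$snp)
    if (anyNA(idx) || anyNA(g$normal[idx]) || anyNA(g$expanded[idx]))
      return(NULL)
    list(normal = paste(g$normal[idx], collapse = ""),
         expanded = paste(g$expanded[idx], collapse = ""))
  })
  dropped <- names(pat)[vapply(pat, is.null, logical(1))]
  if (length(dropped))
    warning("excluded ", length(dropped),
            " individual(s) with missing panel genotypes: ",
            paste(head(dropped, 5), collapse = ", "))
  pat <- pat[!vapply(pat, is.null, logical(1))]
  if (!length(pat)) stop("no individual with complete panel genotypes",
                         call. = FALSE)
  normKeys <- vapply(pat, `[[`, character(1), "normal")
  expKeys <- vapply(pat, `[[`, character(1), "expanded")
  keys <- unique(c(normKeys, expKeys))
  fN <- table(factor(normKeys, levels = keys)) / length(normKeys)
  fE <- table(factor(expKeys, levels = keys)) / length(expKeys)
  ref <- strrep("0", length(panel))
  combined <- as.numeric(fN) + as.numeric(fE)
  ord <- order(keys != ref, -combined, keys)   # Hap1 first, then by freq
  keys <- keys[ord]
  tab <- data.frame(haplotype = paste0("Hap", seq_along(keys)),
                    pattern = keys,
                    freq_normal = as.numeric(fN[keys]),
                    freq_expanded = as.numeric(fE[keys]),
                    stringsAsFactors = FALSE)
  hapOf <- setNames(tab$haplotype, tab$pattern)
  list(table = tab,
       assignments = data.frame(individual = names(pat),
                                normal_hap = unname(hapOf[normKeys]),
                                expanded_hap = unname(hapOf[expKeys]),
                                stringsAsFactors = FALSE,
                                row.names = NULL))
}

#' Allele-specific editability accounting
#'
#' Two SNP classes can direct a double cut exclusively to the expanded
#' chromosome: loss-type SNPs, where the alternative allele destroys a PAM
#' (the individual is editable when the expanded chromosome keeps the
#' reference PAM and the normal chromosome carries the alternative), and
#' gain-type SNPs, where the alternative allele creates a PAM (editable
#' when the expanded chromosome carries the alternative). Homozygous sites
#' cut both chromosomes and are never editable. The report gives per-SNP
#' editable fractions, the four-way configuration breakdown (SNP on both
#' chromosomes / expanded only / normal only / neither), and the fraction
#' of individuals editable via at least one SNP.
#'
#' @param genotypes long data.frame with columns individual, snp, normal,
#'   expanded (phased 0/1 indicators; NA = unphased/missing, counted as
#'   indeterminate).
#' @param pamEffects data.frame with columns snp and effect ("gain" or
#'   "loss"; other rows ignored), e.g. from
#'   \code{\link{classifyPamEffect}}.
#' @return list with \code{perSnp} (data.frame: snp, type(s), editable
#'   fraction and configuration fractions), \code{perIndividual}
#'   (data.frame: individual, editable, via), and \code{anyFraction}.
#' @export
editabilityReport <- function(genotypes, pamEffects) {
  eff <- pamEffects[pamEffects$effect %in% c("gain", "loss"), , drop = FALSE]
  snps <- unique(eff$snp)
  if (!length(snps)) stop("no gain/loss PAM effect supplied", call. = FALSE)
  inds <- unique(genotypes$individual)
  editableMat <- matrix(FALSE, length(inds), length(snps),
                        dimnames = list(inds, snps))
  perSnp <- NULL
  for (s in snps) {
    types <- unique(eff$effect[eff$snp == s])
    g <- genotypes[genotypes$snp == s, , drop = FALSE]
    g <- g[match(inds, g$individual), , drop = FALSE]
    known <- !(is.na(g$normal) | is.na(g$expanded))
    lossOk <- "loss" %in% types & g$expanded == 0 & g$normal == 1
    gainOk <- "gain" %in% types & g$expanded == 1 & g$normal == 0
    ok <- known & (lossOk | gainOk)
    editableMat[, s] <- ok
    n <- sum(known)
    perSnp <- rbind(perSnp, data.frame(
      snp = s, types = paste(sort(types), collapse = "+"),
      frac_editable = sum(ok) / n,
      frac_both = sum(known & g$normal == 1 & g$expanded == 1) / n,
      frac_expanded_only = sum(known & g$normal == 0 & g$expanded == 1) / n,
      frac_normal_only = sum(known & g$normal == 1 & g$expanded == 0) / n,
      frac_neither = sum(known & g$normal == 0 & g$expanded == 0) / n,
      n_indeterminate = sum(!known), stringsAsFactors = FALSE))
  }
  anyEdit <- rowSums(editableMat) > 0
  perInd <- data.frame(
    individual = inds, editable = unname(anyEdit),
    via = vapply(seq_along(inds), function(i) {
      v <- colnames(editableMat)[editableMat[i, ]]
      if (length(v)) paste(v, collapse = ",") else ""
    }, character(1)), stringsAsFactors = FALSE, row.names = NULL)
  list(perSnp = perSnp, perIndividual = perInd,
       anyFraction = mean(anyEdit))
}
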