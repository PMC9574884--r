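---
title: "ampliphase: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ampliphase: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliphase)
```

# The problem

Repeat-expansion loci such as huntingtin (*HTT*) exon-1 carry two adjacent
tandem repeats — a disease-determining CAG tract followed, after a short
linker, by a CCG tract — flanked by sequence that may harbour SNPs usable
for allele-specific CRISPR editing: a substitution that creates a
protospacer adjacent motif (PAM) on the expanded chromosome, or destroys
one on the normal chromosome, lets a guide RNA direct cleavage to the
expanded allele only. Genotyping hundreds of samples for repeat sizes and
phased SNPs at once calls for multiplexed long-read amplicon sequencing:
dual-barcoded long-range PCR, nanopore sequencing of the pooled products,
demultiplexing, per-read joint repeat quantification, diploid phasing, and
per-allele consensus SNP calling. `ampliphase` implements that
computational workflow end to end, together with a ground-truthed read
simulator so that every stage is testable without any external data.

# Pairwise alignment core

All stages share one affine-gap dynamic-programming aligner (C++ via Rcpp)
with two modes: local (Smith–Waterman) and semi-global, in which the query
is consumed end to end while both ends of the target are free. The default
scoring is match +1, mismatch −2, gap open −2, gap extend −1, with a gap
of length $L$ costing $\mathrm{open} + L\cdot\mathrm{extend}$; the scheme
is deliberately edit-distance-like, which keeps it tolerant of the
indel-dominated nanopore error profile. `N` mismatches every base. Every
alignment is attempted on the query and its reverse complement, because
amplicon reads occur on both strands. The test suite checks the aligner
cell-for-cell against an independent quadratic-time R implementation on
hundreds of random string pairs.

Mapping confidence for a set of competing candidates is Phred-scaled from
the gap between the best and second-best scores,
$\mathrm{mapq} = \min(60,\ \mathrm{round}(60\,(s_1-s_2)/s_1))$, with ties
scoring 0 and a lone candidate receiving the cap. The formula is monotone
in the score gap, bounded, and permutation-invariant.

# Barcode design

Candidate barcodes are rejection-sampled uniform sequences constrained to
have no homopolymer longer than 2 bp, no tandem repeat, and GC content in
40–60%. "Tandem repeat" is operationalised as a unit of 1–8 bp repeated at
least three consecutive times spanning at least 9 bp — enough to forbid
PCR-slippage-prone structure without emptying the 16-bp sequence space.
Candidates aligning to a reference genome with more than 80% identical
bases (either strand) are screened out, since genome-similar barcodes risk
non-specific priming. Cross-compatibility is a graph problem: nodes are
barcodes, and an edge connects two barcodes only when they share no exact
word of 6 bp (either strand) that extends to a positive-scoring local
alignment; a clique is then a mutually non-aligning barcode set. The
clique search delegates to igraph's exact maximum-clique algorithm at all
input sizes; the greedy fallback one might use beyond a few thousand nodes
is unnecessary at the scales this package targets. Dual (combinatorial)
barcoding with $f$ forward and $b$ backward barcodes addresses $f \times
b$ samples — 100 with ten per side, 576 with twenty-four.

# Demultiplexing

A barcode is never matched alone: the probe is the barcode concatenated
with its anchor — the stretch of amplicon sequence (default 256 bp)
immediately adjacent to it — aligned semi-globally within the read-end
window (probe length + 100 bp) where the construct places it. The anchor
pins the match to the correct position; random barcode-length matches
inside a noisy long read otherwise occur readily.

Because every candidate probe of a side carries the same anchor, raw probe
scores differ only by the barcode contribution, and a best-vs-second ratio
computed on raw scores would be compressed toward zero by the shared
anchor (an exact barcode match would score mapq ≈ 14 and nothing would
ever clear the threshold of 30). The anchor-only alignment score of the
window is therefore subtracted from every candidate's score before the
Phred confidence is computed: the mapq then measures the barcode evidence
alone. An exact match with well-separated competitors scores 60; a
randomised barcode region scores 0.

A read is assigned to a sample only when (i) both sides reach mapq ≥ 30,
(ii) both sides agree on one orientation of the read, and (iii) the
(forward, backward) pair exists in the sample map; anything else is
recorded as unassigned with its reason. Reads are conserved: each input
read lands in exactly one output bin.

# Joint repeat quantification

Estimating two adjacent repeat counts jointly matters because the
boundary between the tracts is ambiguous base-by-base; scoring whole
two-repeat templates resolves it globally. Quantification is two-step:

1. **Bounds.** For each motif the read is aligned locally against a decoy
   of 1,000 tandem motif copies (both orientations). The upper bound is
   the decoy footprint in repeat units (rounded up) plus a margin of 3;
   the lower bound is the longest run of exact consecutive motif copies in
   the read, minus 1. The margins guard the argmax against footprint
   inflation by mismatch tolerance and deflation by basecall deletions.
   Decoys longer than twice the read are truncated — a local footprint
   cannot extend further, so results are unchanged. A read whose decoy
   score stays below a floor (four clean units by default in
   `quantifySample`) for *both* motifs carries no repeat signal and is
   reported as unquantified; if only one motif clears the floor, the other
   is re-estimated permissively so a weak but genuine short tract still
   enters the grid.
2. **Refinement.** Every template `left_flank + motif1^m + interstitial +
   motif2^n + right_flank` for $(m, n)$ in the bounds grid is scored
   against the read (semi-global: template fully consumed, read ends
   free; better strand, decided once per read from the flank alignments).
   The grid is exhaustive — no pruning — but grid templates share the
   prefix `left_flank + motif1^m`, so DP rows are checkpointed at
   repeat-unit boundaries instead of re-aligning every template; this is
   exact and several-fold faster. The argmax $(m, n)$ is the read's repeat
   genotype; ties break deterministically to the smallest $m$, then the
   smallest $n$. The tests verify the argmax against brute-force oracle
   scoring of every grid template.

# Allele phasing

Per-read $(m, n)$ profiles from a diploid sample follow a mixture of one
or two Gaussians. Phasing proceeds as:

1. **Outlier removal** — single pass, per dimension: a profile deviating
   from the mean by more than three standard deviations of $m$ or of $n$
   is removed (a zero-variance dimension removes nothing). Per-dimension
   matches the univariate phrasing of the rule; iterating the rule could
   cascade on heavy-tailed data and is deliberately avoided.
2. **Model selection** — integer-rounded repeat sizes defeat BIC, because
   a zero-width cluster has unbounded Gaussian density; uniform jitter in
   (−0.5, 0.5) is added to each $m$ and $n$ first. One shared jittered
   dataset is scored for $N = 1$ and $N = 2$ (humans are diploid, so
   larger $N$ is not considered) and the smaller BIC wins, ties favouring
   $N = 1$. With fewer than 12 profiles (the $N=2$ parameter count plus
   one) selection is skipped and $N = 1$ returned with a warning.
3. **Fit and filtering** — the mixture is refit on the original integers
   (the jitter only ever affects selection); full covariances, EM with
   2-means initialisation, ten restarts, best likelihood kept, and a
   ridge of $10^{-3}$ on covariance diagonals so that zero-variance
   dimensions (error-free data) stay well-posed. Reads go to their
   maximum-responsibility component; a read whose squared Mahalanobis
   distance to its component exceeds $\chi^2_{0.95}(2) \approx 5.991$
   lies outside the 95% equi-probability surface and is discarded.
4. **QC and roles** — a sample fails QC when only one component was
   selected or an allele retains fewer than 50 reads. With two groups, the
   one with the larger modal CAG estimate is labelled expanded when it
   reaches 36 repeat units; 35 or fewer is normal. The per-allele point
   estimate is the mode of the assigned integer $(m, n)$ pairs, not the
   Gaussian mean — repeat sizes are integers and the modal read stack is
   the natural estimator.

mclust serves as an independent cross-check of the BIC ranking in the
tests; the in-package EM exists because the prescribed initialisation,
restart and regularisation behaviour (and robustness to zero-variance
dimensions) must be under the package's control.

# SNP calling, PAM effects, haplotypes

Reads of each phased allele are down-sampled to 200× coverage and aligned
to the allele's own template; a per-column pileup yields calls where depth
reaches 50 and the modal non-reference base accounts for ≥ 70% of the
column. Reads of one allele are haploid, so true variants are homozygous
within the allele; the fraction threshold rejects noise columns. Indels
are not called — nanopore basecalls are least reliable in homopolymers,
and the substitution SNPs are what PAM analysis needs. Calls are emitted
as minimal VCF v4.2.

PAM gain/loss classification slides every motif-length window overlapping
the SNP on both strands and compares reference and alternative sequence at
the same window position: reference matches a high-efficiency PAM while
the alternative matches no high- or low-efficiency PAM of the same enzyme
— a loss; the symmetric case is a gain. The comparison is per window
occurrence, so one SNP can yield several rows for one enzyme and strand
(as in a poly-T run overlapping TTTN at several offsets), and gains and
losses on opposite strands of the same SNP are independent. The shipped
high-efficiency table is SpCas9 {NGG, NAG}, SpCas9_VQR {NGAN, NGNG},
SpCas9_EQR {NGAG, NGCG}, SpCas9_VRER {NGCG}, SaCas9 {NNGRRT}, AsCpf1
{TTTN} — sets consistent with published PAM depletion profiles of these
enzymes under the PPVD < 0.2 high-efficiency boundary, shipped together
with a 19-SNP regression fixture of synthetic contexts; users with their
own depletion measurements can substitute a TSV.

Haplotypes are indicator vectors over a fixed SNP panel, one per
chromosome class per individual; frequencies are normalised within class,
and the all-reference haplotype is labelled Hap1. Editability follows the
chromosome-configuration rule: a loss-type SNP edits an individual whose
expanded chromosome keeps the reference PAM while the normal chromosome
carries the alternative; a gain-type SNP edits when the alternative sits
on the expanded chromosome. Homozygous sites cut both chromosomes and
never qualify.

# The simulator

`simulateDiploidReads`/`simulatePool` emulate the study design: diploid
samples with two (CAG, CCG) alleles, optional heterozygous SNPs restricted
to the flanks and linker (the repeat tracts are excluded by validation),
dual barcodes plus 256-bp anchors, strand flips with probability 0.5, and
an error process of independent per-base substitution (1%), insertion
(3%) and deletion (3%) events applied in one left-to-right pass —
deletion dominance and indel-heaviness roughly matching nanopore R9
behaviour. Qualities are constant characters consistent with the total
error rate; no stage consumes them. What the simulator does *not* emulate:
homopolymer-length-dependent error, signal-level artefacts, chimeric
reads, coverage imbalance between alleles, and PCR slippage that changes
the true repeat count within a sample. Passing tests therefore demonstrate
correctness of the algorithms under a realistic error *rate*, not
robustness to every failure mode of real nanopore data.

The synthetic example locus (`exampleLocus()`) uses the CAG/CCG motifs and
the natural CAACAGCCGCCA linker with fixed arbitrary 100-bp flanks; flanks
of at least 50 bp are required for reliable anchoring of the repeat
region. The desk-scale study conditions used throughout the tests and the
acceptance script are 50–100 reads per allele and cohorts of up to 60
samples; these sizes make every property checkable in minutes on one core
while staying inside the regime the method is designed for (the QC rule
itself demands at least 50 reads per allele).

# Numerical and degenerate-input choices

* Alignment ties: forward orientation preferred; grid ties: smallest $m$,
  then smallest $n$; mapq ties: 0.
* Identical profiles (error-free data): covariance ridge keeps the
  mixture well-posed; the outlier rule removes nothing when the standard
  deviation is zero.
* Perfectly identical diploid clusters are statistically one component;
  a homozygous-by-state sample is reported as $N = 1$ and fails QC, which
  is the intended conservative behaviour for downstream SNP phasing.
* One global seed fans out to per-stage seeds (stage-name hashed, kept
  below $2^{31}$), so any stage can be re-run in isolation
  bit-identically.
* The empty FASTQ, a read shorter than the probe, a barcode pair missing
  from the sample map, and an unquantifiable read are all reported
  outcomes, not errors.

# Known limitations

Single-repeat loci are handled only as the degenerate grid; repeat
interruptions beyond the fixed interstitial sequence are not modelled;
indels and structural variants are not called; mosaicism (more than two
mixture components) is out of scope. The editability report presumes
correctly phased genotypes; unphased heterozygotes are counted separately
as indeterminate rather than resolved.
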