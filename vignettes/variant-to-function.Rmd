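---
title: "From GWAS loci to enhancer-modulating variants: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From GWAS loci to enhancer-modulating variants: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emvarkit)
```

# The problem and the pipeline

Genome-wide association studies localize trait signals to LD blocks, not to
causal base pairs, and almost never to the genes those base pairs regulate.
The experimental design this package supports attacks both gaps at once: a
massively parallel reporter assay (MPRA) measures, allele by allele, whether
each candidate SNP sits in sequence with enhancer activity and whether the
two alleles differ (an *enhancer-modulating variant*, EMVar); promoter-capture
Hi-C and eQTL catalogues then connect those variants to the genes they
plausibly regulate, per cell type. `emvarkit` implements every computational
step of that design as tested functions, along with generators that simulate
each input with known ground truth.

# MPRA library design

## Candidate selection

`select_candidates()` keeps, per GWAS lead, the lead itself plus every panel
variant that is biallelic, within 50 kb (boundary inclusive), in LD at
dosage r² strictly above 0.8, and common (MAF ≥ 0.05). r² is the squared
Pearson correlation of genotype dosages (0/1/2), pairwise-complete over
missing entries, with monomorphic comparisons returned as `NA` rather than a
number. We compute r² on dosages rather than phased haplotypes: reference
panels are typically distributed as genotypes, the two estimators agree
closely at these r² levels, and dosage r² is what imputation-based GWAS
actually propagate. A haplotype-based switch was considered and deliberately
not implemented; the panel structure is the generator's responsibility.
A variant qualifying for several leads is emitted once and carries every
locus tag, so downstream per-locus binning (`bin_emvars_to_loci()`) can
honour multi-membership.

## Oligo structure and barcode constraints

Each designed fragment is exactly 230 nt:

```
5'-ACTGGCCGCTTCACTG | enh (175 nt) | GGTACCTCTAGA | barcode (10 nt) | AGATCGGAAGAGCGTCG-3'
        16 nt                           12 nt                             17 nt
```

The 175-nt `enh` region is genomic context centred on the variant; 175 being
odd, we place 87 nt on each side with the allele substituted at the centre
(0-based index 87), always on the reference strand. The linker carries the
single intended KpnI (`GGTACC`) and XbaI (`TCTAGA`) sites used to open the
construct during cloning, so a barcode must not recreate either site
anywhere — `is_valid_barcode()` therefore screens the *assembled* context
(linker tail + barcode + 3' flank head), which also catches sites formed
across a junction; this is strictly stronger than screening the barcode in
isolation, and the explicit no-`TCT`-suffix rule is the special case of an
XbaI site formed against the 3' constant region. Homopolymer runs of three
or more are rejected within the barcode. Validity at reduced length (all
4^6 6-mers) is checked in the test suite against an independently written
brute-force checker that counts restriction-site occurrences in the full
assembled string.

Barcodes per allele default to 18 (configurable to 19, the upper end of the
designed range). The generator draws uniformly over A/C/G/T and
rejection-samples to distinctness, deterministically per seed.

# Quantification

Per-barcode activity contrasts RNA output against DNA input on the log2
scale after counts-per-million normalization:

\[ \text{activity} = \log_2(\text{RNA CPM} + c) - \log_2(\text{DNA CPM} + c) \]

with pseudocount \(c = 1\) by default. The activity definition is sometimes
printed as a log of a *difference* of CPMs; that form is undefined whenever
input meets or exceeds output and contradicts the log-fold-change usage of
the quantity everywhere downstream, so the ratio form is the default and the
literal difference form is available (`eq4_literal = TRUE`) purely for
auditing.

Two quantities are not recoverable from any published description and are
exposed as configuration with prominent defaults: the low-DNA barcode
threshold (default: raw DNA count ≥ 10, removal fraction logged) and the
quantile-normalization axis (default: across RNA replicate columns after
activity computation). Quantile normalization follows the classic recipe —
rank within column, replace by the cross-column mean of order statistics —
with ties assigned the mean of the reference values over their tied rank
span, which makes the transform well defined and exactly idempotent; the
implementation is cross-checked against `limma::normalizeQuantiles()` on
tie-free matrices in the tests.

# Enhancer and EMVar calling

## Tests and multiplicity

The engine is the Mann–Whitney U test (`stats::wilcox.test`): exact
rank-split enumeration when both groups are below 50 values and tie-free,
otherwise the tie-corrected normal approximation with continuity correction.
The suite verifies the exact path against exhaustive enumeration of all
rank splits for every group-size pair with \(n + m \le 12\).

Enhancer calling is one-sided (greater): the comparison group is, by
default, the pooled activity of every *other* tested barcode in the same
replicate — a self-normalizing empirical null that requires no designated
negative controls. The allele's own barcodes are excluded because the test
requires disjoint groups; with hundreds of elements the practical difference
from pooling everything is negligible, and a designated negative-control
barcode set is available via `null = "negctrl"`. Because this comparison
pits ~18 barcodes against thousands, the test always sits in the
normal-approximation regime; `call_enhancers()` therefore uses a vectorized
rank-sum path that reproduces `wilcox.test`'s approximate p-values exactly
(asserted to 1e-12 in the tests, ties included). Benjamini–Hochberg
correction is applied across tested alleles within each replicate.

Only elements with at least one consensus-significant enhancer allele enter
the allelic test (two-sided, ref barcodes vs alt barcodes, BH within
replicate across tested elements). Alleles with fewer than 5 barcodes after
filtering are reported *untested*, never failed.

## Replicate concordance

A call replicates when it is significant (q < α in that replicate) in at
least half of all technical replicates, or in at least one technical
replicate of every biological group. "Half" rounds up for odd counts — the
conservative reading of an ambiguous rule (with 5 technical replicates we
require 3) — and is enforced by an enumerated truth-table test.

## What the simulations show

The synthetic generator plants effects on the same scale the pipeline
estimates: DNA counts are negative-binomial with variance
\(\mu + \phi\mu^2\) (mean 100 per barcode, \(\phi = 0.1\) — typical of a
well-bottlenecked MPRA library), and RNA means condition on each barcode's
*realized* DNA count times \(2^{\Delta}\), since transcripts are produced
from the plasmid copies actually transfected; conditioning on the expected
mean instead would add DNA sampling noise to the planted signal and model a
different experiment. Non-enhancers are centred at activity 0.

At the documented audit scales (run in `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R`): under a global null of 500 elements × 18
barcodes × 5 technical replicates over 20 seeds, the fraction of elements
called EMVar with concordance stays below α plus three Monte-Carlo standard
deviations (in practice the enhancer gate drives it to ~0); planted 2-fold
EMVars at the same design are recovered in well over 90% of instances; and
power is monotone non-decreasing along a 3×3 grid of allelic effect
(0.5/1/1.5 log2) × barcodes per allele (6/12/18). These sizes were chosen so
the whole suite audits error control and power in tens of seconds on one
CPU while keeping Monte-Carlo error far from the asserted margins.

What passing these simulations does *not* show: real MPRA data carry
batch structure between biological replicates, barcode-specific synthesis
and PCR biases, and heavier-tailed dispersion than a single-\(\phi\)
negative binomial; the generator models none of these, so the audits
establish correctness of the rules and calibration under the stated model,
not performance guarantees on any particular dataset.

# Integration with cHi-C and eQTL evidence

Interactions are kept when their score exceeds 5 at *any* timepoint, both
anchors share a chromosome, and the anchors are within 1 Mb. Distance is
measured between anchor midpoints ("between loci" admits several readings;
midpoints are symmetric and insensitive to fragment size), with edge-to-edge
available by argument. The filter is idempotent by construction.

EMVar–promoter linking is a point-to-interval distance: 0 when the SNP falls
inside the distal fragment, otherwise the gap to the nearest covered base,
linked when ≤ 1000 bp (boundary inclusive: 999 and 1000 link, 1001 does
not). The implementation rides on `GenomicRanges::findOverlaps` over
window-expanded SNP points and is checked against a brute-force per-base
scan in the tests. All interval I/O is 0-based half-open (BED/BEDPE
convention); variant positions are 1-based (VCF convention).

Gene-support classes are a pure function of four evidence flags, applied
with strict precedence I > II > III > IV so each gene takes its highest
class:

| interacts | eQTL (matched tissue) | eQTL (other tissue) | class |
|-----------|----------------------|---------------------|-------|
| yes | yes | — | I |
| yes | no | yes | II |
| exactly one of {interacts, matched-eQTL} | | | III |
| no | no | yes | IV |

gated on expression > 1 TPM in at least one timepoint. The written
definitions of II and III overlap on "contact + other-tissue eQTL"; the
precedence resolution is this package's documented choice, enforced by an
exhaustive 16-combination truth-table test, and not asserted to be the only
defensible reading. The tissue→class map (which tissue names count as
matched) is data the caller supplies, not hard-coded names.

# Time-course analyses

## Normalization and filters

TMM scale factors go through `edgeR::calcNormFactors` (30% two-sided trim on
log-ratios, 5% on abundances, precision-weighted mean, factors centred to
product 1 — the method's published definition); the tests pin the behaviour
with a step-by-step reimplementation agreeing to 1e-8 and with the exact
fixed points (identical libraries → factors 1; a uniformly scaled column
carries no composition bias, so the planted scaling lands entirely in the
effective library size). Clustering uses the CPM < 1 in more-than-three
samples filter; the HSV input filter drops genes whose per-timepoint mean
TPM falls below 2 (log2 < 1) at any timepoint — we average TPM over
replicates first and then take log2, following the order in which the
quantities are defined.

## The HSV transformation

A feature's ordered profile \(C_t \ge 0\) (log2-normalized expression,
accessibility or interaction strength) maps to

\[ V = \max_t C_t, \qquad S = 1 - \frac{\min_t C_t}{V}, \qquad
   H = 60\left(2 + \frac{C_{\mathrm{first}} + C_{\mathrm{second}} - C_{\mathrm{last}} - V}{V\,S}\right)
   \cdot \operatorname{sign}(C_{\mathrm{second}} - C_{\mathrm{first}}) \]

so V is the peak level, S the maximal fold change, and H the pattern of
change. The hue formula is written for a four-point course in its original
form; we generalize the three anchors to (first, second, last) so 3-point
and longer courses are supported by the same code. Three degeneracies are
flagged rather than computed: all-zero profiles (`undefined`, V = 0), flat
profiles (`static`, S = 0), and a first-step tie \(C_2 = C_1\)
(`static-onset`, sign term singular). H is wrapped into [0, 360) by modulo —
the natural domain of a hue, though no range is pinned by the original
definition. (H, S) are invariant to positive scaling of the profile and V
is homogeneous of degree 1, both asserted as properties. For plotting, V
and S are additionally rank-scaled to [0, 1] (`(rank − 1)/(n − 1)`,
order-preserving, extremes attained).

`bin_patterns()` sectors hue into `360/n_bins`-degree bins, default 6: the
guide patterns in circular HSV displays are a graphical choice, so the bin
count is an argument, and 60° sectors are the coarsest binning that still
separates monotone-up from monotone-down archetypes in both directions.

## Fuzzy clustering

`cluster_timecourse()` clusters replicate-averaged, row-standardized
profiles with fuzzy c-means (`e1071::cmeans`, fuzzifier m = 2 — the standard
default, seeded initialization), then scores each individual replicate's
profile against the fitted centres with the standard membership formula so
the assignment rule can see per-replicate support. A gene is assigned to its
argmax cluster only when the averaged membership exceeds 0.3 and every
replicate's membership exceeds 0.2, both strict: a gene sitting exactly at a
threshold is unassigned. Whether hue/clustering should use replicate means
or per-replicate profiles is not fixed by the method; we default to
replicate means (which is also what the membership-averaging rule implies)
and keep per-replicate memberships available.

## ATAC peak harmonization

Peaks from all timepoints are merged into union loci under half-open overlap
semantics (touching intervals stay separate); within each locus the summit
of the highest-scoring peak becomes the centre of a fixed 1-kb interval
\([s - 500, s + 500)\). Missing summits fall back to interval midpoints with
a warning. Counts are conserved for disjoint peaks and output intervals are
exactly 1000 bp, both asserted.

# Synthetic data: what it emulates, and what it does not

* `simulate_genotypes()` builds LD by copy-with-flip on haplotypes: a proxy
  copies the lead's haplotypes and flips each allele with probability
  \(\varepsilon = (1 - \sqrt{r^2_{\mathrm{target}}})/2\), giving haplotype
  correlation ≈ \(1 - 2\varepsilon\). The construction is first-order, so
  realized r² runs slightly below target (≈ 0.88 for a 0.90 target at
  n = 500); the realized value is always computed and reported, never
  assumed. No recombination maps, allele-frequency spectra or population
  structure are modelled.
* `simulate_chic()` emits a labelled mix of interactions straddling every
  filter boundary (score, trans, 1 Mb) and can plant distal ends at an
  exact distance from an EMVar, which is how the 999/1001 bp boundary is
  exercised end to end. It does not model distance-decay of contact
  frequency.
* `simulate_timecourse()` draws genes from four archetypes (up, down,
  transient, flat) with negative-binomial noise, or deterministically
  (`noise = "none"`) for exact checks of the HSV formulas on constructed
  profiles.
* Sequencing-read simulation stops at barcode counts; read-level errors and
  UMI structure are out of scope, matching the pipeline's exact-match,
  no-rescue counting rule.

# Known limitations

* The enhancer null is empirical and pooled; if a large fraction of the
  library is active, the null is contaminated and calls become conservative.
  A designated negative-control set avoids this when available.
* Count-model alternatives (per-element negative-binomial GLMs) are not
  provided; the rank-based tests are the implemented contract.
* Differential-expression calling ahead of clustering is accepted from
  external tools; the package ships only a filter, not a DE model.
* Class III's inclusive/exclusive "or" and the II/III overlap are resolved
  by documented precedence, not by appeal to an authoritative definition.
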