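---
title: "Methods: quantifying genome erosion in bottlenecked populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying genome erosion in bottlenecked populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lynxerosion)
```

`lynxerosion` implements the comparative- and population-genomic analyses
used to characterize genomic erosion in a severely bottlenecked felid:
the Iberian lynx, contrasted with its sister species the Eurasian lynx
and with the domestic cat and tiger as outgroups. This vignette explains
the models, the parameters that matter, the synthetic-data generator used
to validate every stage, and the numerical choices made where the design
was genuinely open.

## Coordinate conventions

All coordinates inside the package are 0-based half-open. Conversions
happen only in the readers: VCF `POS` (1-based) and RepeatMasker `.out`
coordinates (1-based inclusive, `C` for minus strand) are translated on
input; BED passes through unchanged. A single convention eliminates
off-by-one drift between stages that exchange intervals.

## TE insertion calling with target-site-duplication validation

A species-specific TE insertion manifests, in a pairwise genome
alignment, as a gap: carrier-only sequence between two consecutive
aligned blocks that are adjacent on the partner genome. `find_gaps()`
emits such gaps when the carrier-side separation is within 50 bp - 20 kb
(excluding micro-indels and assembly gaps; the bounds are parameters)
and the partner-side separation is at most 10 bp. Negative partner-side
gaps down to -100 bp are allowed because a genuine insertion duplicates
its target site: the duplicated 15-25 bp aligns on both flanks, so the
neighboring blocks *overlap* on the partner side by the TSD length. The
same reasoning admits small carrier-side overlaps at partner-specific
insertions.

`call_te_insertion()` accepts a gap iff a single annotated repeat covers
at least 95% of the gap, at least 99% of that repeat lies inside the
gap, and a TSD is detected at the boundaries. When several repeats
qualify, the highest gap coverage wins (ties: longest, then leftmost).

TSD detection compares the window 25 bp outside / 15 bp inside the gap
start against the window 15 bp inside / 25 bp outside the gap end. The
two 40-bp windows are compared by exhaustive ungapped local alignment
(match +1, mismatch -1, every segment of every diagonal), keeping the
best segment under the ordering: maximal score, then maximal percent
identity, then maximal length, then leftmost. Ungapped exhaustive
scanning is exact, dependency-free and directly checkable against a
brute-force oracle, which the test suite does on 1,000 random window
pairs. A TSD is accepted iff `L * P / 100 > 6` (strictly), where `L` is
the alignment length and `P` the percent identity *reported to one
decimal place*, as an aligner prints it. The rounding matters at the
boundary: a 9-bp alignment with 6 matches has `P = 66.7` and score
6.003, which passes, while a perfect 6-mer scores exactly 6.0 and is
rejected. With exact arithmetic `L * P / 100` equals the match count, so
the rule is "more than six matching bases in the best local alignment".

Branch assignment uses two pairwise comparisons against the cat genome
(lynx-vs-cat and tiger-vs-cat). Calls present in only one comparison are
lineage-specific; calls whose cat-coordinate anchors coincide (within
100 bp) are counted once as shared. Gene context is assigned by >= 1 bp
overlap with a gene body, with sense/antisense orientation relative to
the gene strand; unstranded calls count as genic but are excluded from
the sense-fraction denominator. Orientation enrichment against a
background given *as counts* uses the two-sided Fisher exact test
(`stats::fisher.test`); the test suite verifies it against full
hypergeometric enumeration on every 2x2 table with margins up to 12.

Full endogenous retroviruses are reconstructed by pairing LTR fragments
that share repeat name, strand and chromosome, span at most 15 kb (a
typical proviral length; the pairing rule itself sets no bound), and
whose enclosed sequence is covered at least 50% by ERV-internal
fragments of the same family and orientation. Overlapping candidates
are resolved by internal coverage (ties: longest, then leftmost), so the
output never contains two records with overlapping enclosed intervals.

## Substitution polarization and the weak-to-strong bias

Sites with states in cat, tiger and both lynxes are polarized on the
(tiger,(cat,(Iberian,Eurasian))) topology. The rules are conservative:
any lynx heterozygote is set aside as `heterozygous` (it contributes to
heterozygosity tallies, never to substitution counts); lynx-branch
assignment requires outgroup agreement (tiger == cat); sites violating
it are `unpolarizable` rather than resolved by parsimony. Every input
site receives exactly one category, and the category counts sum to the
input total - a partition invariant the window scan asserts.

A substitution is weak-to-strong (W->S) when the ancestral base is A/T
and the derived base is G/C - the signature of GC-biased gene
conversion, which requires heterozygosity to act and therefore weakens
after bottlenecks. Per-branch W->S fractions are pooled over sites
(per-window values are available in the window table) and reported with
binomial confidence intervals.

Windows tile each chromosome from coordinate 0 in 100-kb steps; windows
with fewer than 10,000 informative sites are omitted. Faster-evolving
regions (FRs) between two lineages are the `ceiling(q * N)` windows in
each tail of the pseudocounted log rate ratio, with `q = 0.025` by
default; a rank-based definition keeps tail counts exact and
deterministic under ties. The FR threshold is exposed as a parameter
because no canonical numerical definition exists. The relationship
between relative substitution rate and relative heterozygosity across
windows is summarized by the Pearson correlation of the two log ratios:
under differential fixation of ancestral polymorphism, windows where one
lineage lost diversity show elevated substitution rates in that lineage,
giving a negative correlation.

## Conserved-neighborhood codon filter and counting dN/dS

Cross-species dN/dS comparisons are only as good as the alignments, so
the package implements a strict two-step column filter for codon
alignments. First, codon columns containing gaps are removed (columns
with ambiguity codes are dropped too, logged separately). Second, the
retained columns are translated and every column with at least one
amino-acid replacement is kept only if the two preceding and two
following amino-acid columns all exist and are each fully conserved.
Three choices deserve note:

* "Fully conserved" is evaluated at the amino-acid level: synonymous
  nucleotide variation neither makes a column a replacement nor
  disqualifies it as a flank.
* Flank positions are evaluated after gap-column removal, matching the
  order of the two steps.
* Fully conserved columns are always kept; the rule constrains only
  replacement columns.

The filter is idempotent (a kept replacement column's flanks are
conserved columns, which are never removed) and self-consistent:
re-scanning the output finds no replacement column lacking its 2+2
conserved flanks. Both properties are asserted on random alignments.

dN/dS is estimated by a counting method: per-codon synonymous site
counts (each of the nine possible point mutations contributes 1/3 of a
site; mutations to stop codons count as nonsynonymous), averaged over
the two sequences; observed differences classified along minimal
mutational paths with multi-hit codons averaged over pathway orderings
and paths through stop codons excluded; Jukes-Cantor correction of both
proportions. The ratio is undefined (`NA`) when dS = 0. This estimator
is deliberately simple and transparent - a desk-scale stand-in for
likelihood codon models, validated against an independent
pathway-enumeration oracle.

## Population-genomic erosion statistics

*Diversity.* Watterson's theta is `S / (a_n L)` with `a_n` the harmonic
number of the chromosome sample size minus one and `L` the callable-site
universe (variant plus invariant). Per-SNP expected heterozygosity is
`2p(1-p)` with the raw sample frequency - no small-sample correction -
because the package reproduces summary-table arithmetic of the form
`mean(H_E) * S / L` exactly, and that identity only holds uncorrected.
The `n/(n-1)`-corrected estimator is exposed under a distinct name
(`H_E_unbiased`, `per_site_pi(unbiased = TRUE)`). Per-population per-SNP
means are taken over the species-wide SNP universe, sites monomorphic in
the focal population contributing zero, for the same reason.

*piN/piS.* Synonymous and nonsynonymous diversity assume three-quarters
of coding sites are nonsynonymous: per CDS, `piS = sum(H_E syn)/(L_c/4)`
and `piN = sum(H_E nonsyn)/(3 L_c / 4)`. CDS with 200 or fewer callable
sites are excluded (strictly more than 200 qualifies); genome-wide
values are length-weighted means, and the ratio is the ratio of the
means. Functional annotation of SNPs is an input, not computed here.

*ROH and inbreeding.* Runs of homozygosity are detected by a
deterministic density rule: het-free callable runs are merged greedily
across single heterozygous sites, lowest resulting density first, while
the density stays at or below 1 heterozygote/Mb; runs shorter than 10 kb
are discarded and survivors are classed short (10-100 kb), medium
(100 kb - 1 Mb) or long (> 1 Mb). The original study used an external
tool whose parameters are not recoverable, so the package's rule is its
own, parameterized, and validated by plant-and-recover. `F_ROH` is the
genome fraction in ROH *strictly* longer than 1 Mb. `F_h` is the
excess-homozygosity coefficient `(O_hom - E_hom)/(N - E_hom)`; allele
frequencies include the focal individual by default (a flag exposes the
alternative).

*Differentiation and LD.* FST is the Weir-Cockerham (1984) variance
-component estimator, summed over sites polymorphic in the combined
sample; the tests check it to 1e-12 against an independent
sums-of-squares (ANOVA) implementation. LD is the squared Pearson
correlation between diploid dosage vectors across individuals, binned by
pair distance; the half-max distance is where the antitonic
(isotonic-decreasing) smoothed curve falls to the midpoint of its first
-bin and asymptotic values, linearly interpolated between bin midpoints.

*Outlier windows.* Delta-Z heterozygosity standardizes each species'
per-window heterozygosity with that species' own mean and SD and takes
the difference. The default flags the 2.5% most extreme windows in each
tail by rank (with the matching sign required, so identical inputs yield
no outliers); a percentile mode (e.g. 99.9/0.1) is selectable, as both
definitions are in circulation. Subtelomeric enrichment tests whether
flagged windows overlap the outer 5 Mb of their chromosomes more often
than unflagged ones (two-sided Fisher). The X/autosome ratio divides the
mean normalized diversity (pi over divergence) of X windows by that of
autosomal windows, with a bootstrap-over-windows standard error
(stratified by compartment, fixed seed); masking of repeats,
centromere/telomere flanks and the pseudoautosomal region is applied
upstream by the caller.

## Synteny chaining and rearrangements

Alignment blocks (> 1 kb, best-hit filtered upstream) are sorted per
(query, target) by target coordinate and merged greedily while
consecutive blocks share a strand and both the target-side and the
query-side gaps are below 20 kb. The query-side condition is the
package's addition: it prevents chaining across large unaligned query
insertions. Chains must span at least 15 kb on the target with at least
40% of spanned sites aligned (the denominator is the target-side span).
Rearrangements are read off adjacent chains per scaffold: opposite
strands on one chromosome is an inversion; different chromosomes an
inter-chromosomal event; same chromosome and strand with target order
inconsistent with query order (beyond the merge gap) an
intra-chromosomal event. Because an inverted or translocated segment has
an entry and an exit breakpoint, `collapse_breakpoints()` merges the
pair into one reported event. Outgroup polarization assigns an event to
the query (lynx) lineage when the query-vs-outgroup chains show the same
discordance, and to the reference (cat) lineage when the outgroup is
collinear across the breakpoint; anything else stays unassigned.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions, chosen once:

* **Four-taxon phylogeny.** Branch substitution probabilities
  (tiger 1.8e-2, cat and lynx-ancestor 9e-3, each lynx 7e-4) are
  proportional to the published branch-specific substitution densities
  (e.g. ~7.1e5 lynx-specific variants over ~1.06e9 genotyped sites).
  Substitutions are planted i.i.d. per branch at globally distinct
  positions, so every planted event is the unique difference at its
  locus; an optional per-window rate multiplier creates faster-evolving
  windows. The W->S preference lambda multiplies the probability of
  choosing a strong target from a weak ancestor, giving a planted W->S
  fraction of `lambda*q / (lambda*q + 1 - q)` where `q` is the unbiased
  fraction given the base composition - a closed form the tests check.
* **TE insertions** are drawn from a small built-in library of labeled
  synthetic SINE/LINE/LTR/ERV-internal motifs (so RepeatMasker-format
  annotations can be emitted without RepeatMasker), placed
  non-overlapping, with TSD lengths uniform on 15-25 bp. The implied
  alignment-block table, including the TSD overlap geometry at
  insertion boundaries, is derived from the planted truth.
* **Genotype panels.** Two populations of 4 and 7 diploids (the two
  wild-population sample sizes) with planted per-site theta 1.2e-4 and
  2.2e-4 (the published per-population Watterson estimates). Segregating
  sites receive neutral site-frequency-spectrum allele counts
  conditioned on segregating, which makes both Watterson's theta and pi
  unbiased for the planted theta - the estimator-recovery tests rely on
  this. 67% of the smaller population's sites are shared (the value
  implied by the published per-population and total SNP counts), with
  Balding-Nichols differentiation (F = 0.2) around the shared frequency.
  ROH are forced by overwriting exponential tracts (mean 1.5 Mb,
  truncated to the per-individual target fraction of 0.32/0.16 so
  realized coverage tracks the target on short test genomes) with
  homozygous genotypes - exact planted truth for the detector, not a
  pedigree model.
* **Codon alignments** evolve from a random stop-free codon sequence
  under a purifying-selection background (amino-acid-changing mutations
  accepted with probability `omega = 0.2`); misalignment noise is
  planted by shuffling codons of short windows in one taxon. This is the
  regime the conserved-neighborhood filter targets: rare genuine
  replacements against abundant synonymous variation, plus clustered
  spurious replacements.
* **Rearranged scaffolds** are built from collinear segments with
  planted inversions and inter/intra-chromosomal moves, each segment
  split into sub-blocks with small gaps so chaining must do real work.

Every generator draws from a private seeded RNG stream and restores the
global RNG state, so identical configurations are byte-identical and
simulations never perturb user code.

What the generator does *not* emulate: coalescent genealogies with
recombination (LD structure is planted only where a test needs it, via a
Markov haplotype construction), mutation-rate heterogeneity beyond the
window multiplier, segmental duplications, sequencing error and
genotype-quality structure, and demography itself - only demography's
*signatures* (diversity contrast, ROH, shared/private variants,
reduced W->S bias) are planted. Passing plant-and-recover tests
therefore demonstrates correctness of the detectors under their stated
models, not robustness to every artifact of real resequencing data.

## Numerical choices and degenerate inputs

* TSD percent identity is rounded to one decimal before the
  `L*P/100 > 6` rule (aligner-style reporting; governs the boundary).
* Ties in the FR and delta-Z rank flags are broken by stable window
  order; rank-mode outliers additionally require the matching sign.
* Pseudocounts: +1 on substitution counts in log ratios; 1e-9 on
  heterozygosity ratios.
* `detect_roh` merges lowest-density-first, which is deterministic;
  ROH boundaries end at the flanking heterozygote, so recovery of a
  planted tract is measured as overlap, tolerant of edge
  discretization.
* Degenerate inputs error early and informatively: fewer than 2
  chromosomes for theta, fewer than 3 windows for correlations, fewer
  than 40 windows for tail quantiles, zero SD in Z-standardization,
  empty compartments in the X/A ratio. Zero-margin Fisher tables return
  p = 1 with a warning.

## Problem sizes used in the test and acceptance suites

The suites exercise the code at sizes chosen to make the statistical
assertions sharp while completing comfortably on one CPU: 10-Mb genomes
for TE plant-and-recover and ROH recovery, 200 replicate 1-Mb panels for
estimator recovery (mean within 3 standard errors of planted theta),
1,000 random 40-bp window pairs against the alignment oracle, all 2x2
tables with margins up to 12 against the Fisher oracle, and 100-replicate
property checks elsewhere.

## Limitations

The counting dN/dS ignores transition/transversion and codon-frequency
biases, so its absolute values are not comparable to likelihood
estimates; it is intended for filter-effect comparisons. The ROH rule is
a deliberate re-parameterization, not a reimplementation of any specific
published tool. The synteny caller reports candidate rearrangements;
assembly-artifact filtering (e.g. clone support across breakpoints) is
data-specific and left to the caller, via the breakpoint coordinates in
the output.
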