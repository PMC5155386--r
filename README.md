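# lynxerosion

Genome-erosion analyses for severely bottlenecked populations, built
around the Iberian lynx (*Lynx pardinus*) study system: the most
endangered felid, whose two remnant populations (Doñana and Andújar)
carry the signatures of recurrent demographic collapse throughout their
genomes. The package re-implements the comparative- and
population-genomic toolkit needed to measure those signatures, and a
synthetic-data module that plants ground truth so every stage is
validated by plant-and-recover.

## What it computes

**TE dynamics.** Species-specific transposable-element insertions are
called from pairwise-alignment gaps: a gap is accepted when a single
annotated repeat covers ≥ 95% of it, ≥ 99% of that repeat lies inside
it, and a target-site duplication (TSD) is detected at the boundaries.
TSDs are found by exhaustive ungapped local alignment of the −25/+15 and
−15/+25 bp boundary windows, with the strict rule `L·P/100 > 6` (`L` =
alignment length, `P` = percent identity). Full endogenous retroviruses
are reconstructed from same-type, same-strand LTR pairs whose enclosed
sequence is ≥ 50% covered by same-family internal fragments. Insertions
are assigned to branches from two pairwise comparisons against the cat
genome, and their gene context (sense/antisense within genes) is tested
for enrichment with Fisher's exact test.

**Substitution patterns.** Sites are polarized on the
(tiger,(cat,(Iberian,Eurasian))) topology with conservative
outgroup-agreement rules; weak-to-strong substitutions (A/T → G/C, the
signature of GC-biased gene conversion) are quantified per branch; and
non-overlapping 100-kb windows (≥ 10,000 informative sites) are scanned
for faster-evolving regions and their inverse relationship with
heterozygosity.

**Codon filtering and dN/dS.** A conserved-neighborhood codon-column
filter removes gapped columns and keeps amino-acid replacement columns
only when flanked by two fully conserved columns on each side, plus a
counting (Nei–Gojobori-style) dN/dS with pathway averaging and
Jukes–Cantor correction.

**Population genomics.** Watterson's θ = S/(aₙL); per-SNP and per-site
observed/expected heterozygosity; π_N/π_S with the ¾-nonsynonymous-site
rule over CDS longer than 200 callable sites; runs of homozygosity with
F_ROH (ROH > 1 Mb) and F_h; Weir–Cockerham F_ST; LD decay (r² between
genotype dosages) with half-max distance; ΔZ_H heterozygosity-outlier
windows and their subtelomeric enrichment; X/autosome normalized
diversity ratios with bootstrap SEs.

**Synteny.** Chaining of pairwise alignment blocks (merge < 20 kb gaps,
keep chains ≥ 15 kb with ≥ 40% aligned) and detection of inversions and
inter/intra-chromosomal rearrangements, polarized against an outgroup
genome.

## Worked example

Simulate a 1-Mb four-taxon genome set with planted TE insertions, call
them back, and summarize diversity in a simulated two-population panel:

```r
library(lynxerosion)

cfg <- sim_config(seed = 11, seq_length = 1e6, te_rate = 10)
sim <- simulate_phylogeny(cfg)

blocks <- simulate_alignment_blocks(sim, "iberian", "cat")
gaps   <- find_gaps(blocks, sim$genomes)
calls  <- call_te_insertions(gaps, sim$repeats$iberian)
nrow(calls); head(calls[, c("gap_start", "gap_end", "repeat_name",
                            "tsd_L", "tsd_score")])

pop <- simulate_population_genotypes(cfg)
diversity_summary(pop$genotypes, "popA")
```

which prints (seed 11):

```
[1] 15
  gap_start gap_end repeat_name tsd_L tsd_score
1     31872   33872      L1-Lx1    25        23
2    112311  112761  LTR-LxERV1    17        17
3    221702  222002    SINE-Lx1    24        24
...
$S       : int 322
$n_chrom : num 8
$H_O     : num 0.21
$H_E     : num 0.351
$theta_W : num 0.000124
$pi      : num 0.000113
```

All fifteen planted iberian-lineage insertions are recovered with their
TSD lengths and scores; the panel's Watterson θ (1.24 × 10⁻⁴ per site)
and π reflect the planted popA diversity (1.2 × 10⁻⁴), and H_O well
below H_E reflects the forced runs of homozygosity (32% of the genome,
the Doñana-like condition).

Printed-scale identities work directly:

```r
100 * watterson_theta(S = 625552, n = 8, L = 2021732768)   # 0.01193 %
100 * per_site_pi(rep(0.336, 1587509), 2021732768)          # 0.02638 %
```

## Vignette

`vignettes/genome-erosion-methods.Rmd` documents the models and their
assumptions, every tunable threshold with its default and rationale,
what the synthetic-data generator does and does not emulate, and the
numerical choices at degenerate inputs.
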