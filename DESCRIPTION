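Package: lynxerosion
Title: Genome-Erosion Analyses for Bottlenecked Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analyses of genomic erosion in severely bottlenecked
    populations, built around the Iberian lynx study system.  Implements
    species-specific transposable-element insertion calling from pairwise
    alignment gaps with target-site-duplication validation, full
    endogenous-retrovirus reconstruction from LTR pairs, polarization of
    nucleotide substitutions on a four-taxon felid topology with
    weak-to-strong (GC-biased gene conversion) bias scans in 100-kb
    windows, a conserved-neighborhood codon-column filter for reliable
    dN/dS estimation together with a counting (Nei-Gojobori style) dN/dS,
    population-genomic erosion statistics (runs of homozygosity and
    inbreeding coefficients, Watterson's theta, nucleotide diversity,
    piN/piS, Weir-Cockerham FST, linkage-disequilibrium decay,
    delta-Z heterozygosity outlier windows, subtelomeric enrichment,
    X-to-autosome diversity ratios), and synteny chaining with
    inversion/rearrangement detection polarized by an outgroup.  A
    synthetic-data module generates genomes, repeat annotations and
    diploid genotype panels with planted ground truth so every stage is
    testable by plant-and-recover.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    boot,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
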