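# End-to-end orchestration: simulate -> TE calling -> substitution scan
# -> codon filter -> popgen -> synteny, with a manifest of content
# hashes so identical config + seed gives identical outputs.

#' Run the full demonstration pipeline on synthetic data
#'
#' Simulates a four-taxon genome set and a two-population genotype
#' panel, then runs every analysis stage and writes all stage tables to
#' `outdir`.  The returned manifest lists each output file with its MD5
#' hash; identical config and seed reproduce identical hashes.
#'
#' @param config [sim_config()]; its `seed` drives all stages.
#' @param outdir output directory (created if needed).
#' @return data.frame manifest: `file`, `md5`.
#' @export
run_pipeline <- function(config = sim_config(), outdir = tempfile()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(name, writer) {
    p <- file.path(outdir, name)
    writer(p)
    paths <<- c(paths, p)
    p
  }

  # -- simulate ------------------------------------------------------
  sim <- simulate_phylogeny(config)
  emit("genomes.fa", function(p) write_fasta(sim$genomes, p))
  emit("substitutions.tsv", function(p)
    utils::write.table(sim$truth$substitutions, p, sep = "\t",
                       quote = FALSE, row.names = FALSE))
  emit("te_truth.tsv", function(p)
    utils::write.table(sim$truth$te_insertions, p, sep = "\t",
                       quote = FALSE, row.names = FALSE))
  pop <- simulate_population_genotypes(config)
  emit("panel.vcf", function(p) write_vcf(pop$genotypes, p))
  emit("roh_truth.bed", function(p)
    write_bed(data.frame(chrom = pop$truth$chrom, start = pop$truth$start,
                         end = pop$truth$end, name = pop$truth$individual),
              p))

  # -- TE calling (lynx/tiger vs cat) --------------------------------
  calls <- list()
  for (carrier in c("iberian", "tiger")) {
    blocks <- simulate_alignment_blocks(sim, carrier, "cat")
    gaps <- find_gaps(blocks, sim$genomes)
    calls[[carrier]] <- call_te_insertions(gaps, sim$repeats[[carrier]])
  }
  br <- assign_branches(calls$iberian, calls$tiger)
  emit("te_calls.tsv", function(p)
    utils::write.table(br$calls, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  ervs <- reconstruct_full_ervs(sim$repeats$iberian)
  emit("full_ervs.tsv", function(p)
    utils::write.table(ervs, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))

  # -- substitution patterns (TE-free genome set) --------------------
  cfg0 <- config
  cfg0$te_rate <- 0
  sim0 <- simulate_phylogeny(cfg0)
  sites <- polarize_genomes(sim0$genomes, sim0$truth$het_sites)
  wins <- window_scan(sites, window_size = config$window_size,
                      min_informative = 1)
  emit("windows.tsv", function(p)
    utils::write.table(wins, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  emit("ws_summary.tsv", function(p)
    utils::write.table(ws_bias_summary(sites), p, sep = "\t",
                       quote = FALSE, row.names = FALSE))

  # -- popgen --------------------------------------------------------
  gm <- pop$genotypes
  summ <- lapply(c(list(NULL), as.list(unique(gm$populations))),
                 function(pp) {
                   s <- diversity_summary(gm, pp)
                   data.frame(population = if (is.null(pp)) "all" else pp,
                              S = s$S, n_chrom = s$n_chrom, H_O = s$H_O,
                              H_E = s$H_E, theta_W = s$theta_W, pi = s$pi)
                 })
  emit("diversity.tsv", function(p)
    utils::write.table(do.call(rbind, summ), p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  ind1 <- colnames(gm$genotypes)[1]
  het_pos <- gm$sites$start[gm$genotypes[, ind1] == 1]
  roh <- detect_roh(het_pos,
                    data.frame(chrom = "chr1", start = 0,
                               end = config$seq_length))
  emit("roh.bed", function(p)
    write_bed(data.frame(chrom = roh$chrom, start = roh$start,
                         end = roh$end, name = roh$length_class), p))

  # -- synteny -------------------------------------------------------
  syn <- simulate_rearranged_scaffold(c("inversion", "inter_chromosomal"),
                                      seed = config$seed)
  chains <- chain_blocks(syn$blocks)
  rearr <- detect_rearrangements(chains)
  emit("rearrangements.tsv", function(p)
    utils::write.table(rearr, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))

  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  manifest
}
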