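# helper: windows whose only shared similarity is a planted motif pair;
# flanks are drawn from disjoint alphabets so no spurious matches exist
motif_windows <- function(motif1, motif2) {
  list(flank_left = paste0(strrep("A", 40 - nchar(motif1)), motif1),
       flank_right = paste0(motif2, strrep("C", 40 - nchar(motif2))),
       flank_ok = TRUE)
}

test_that("gaps are called between consecutive blocks of a chain", {
  seqs <- c(lynx = strrep("ACGT", 1000), cat = strrep("ACGT", 500))
  b <- data.frame(query = "lynx", qstart = c(0, 1300),
                  qend = c(1000, 2300), target = "cat",
                  tstart = c(0, 1000), tend = c(1000, 2000),
                  strand = "+", aligned_sites = 1000,
                  stringsAsFactors = FALSE)
  g <- find_gaps(b, seqs)
  expect_equal(nrow(g), 1L)
  expect_equal(g$gap_start, 1000)
  expect_equal(g$gap_end, 1300)      # one 300-bp carrier-only gap

  collinear <- b
  collinear$qstart <- collinear$tstart
  collinear$qend <- collinear$tend
  expect_equal(nrow(find_gaps(collinear, seqs)), 0L)  # gap-free chain

  overlapping <- b
  overlapping$qstart[2] <- 500
  expect_error(find_gaps(overlapping, seqs), "overlapping blocks")
})

test_that("TE call thresholds follow the 95%/99% coverage rules", {
  # gap of 1000 bp with a perfect TSD planted at its boundaries
  tsd <- "GATTACAGAT"
  seq <- paste0(strrep("A", 990), tsd, strrep("G", 1000), tsd,
                strrep("C", 990))
  gap <- data.frame(carrier = "chr1", gap_start = 1000, gap_end = 2000,
                    partner = "cat", partner_pos = 1000, strand = "+",
                    flank_left = substr(seq, 976, 1015),
                    flank_right = substr(seq, 1986, 2025),
                    flank_ok = TRUE, stringsAsFactors = FALSE)
  rep_in <- data.frame(chrom = "chr1", start = 1010, end = 1990,
                       strand = "+", repeat_name = "L1-x",
                       repeat_class = "LINE", family = "L1",
                       stringsAsFactors = FALSE)
  call <- call_te_insertion(gap, rep_in)
  expect_false(is.null(call))
  expect_equal(call$te_coverage_of_gap, 0.98)
  expect_equal(call$te_within_gap, 1.0)

  rep_low <- rep_in
  rep_low$end <- 1910                 # 900/1000 coverage
  expect_null(call_te_insertion(gap, rep_low))

  rep_out <- rep_in
  rep_out$start <- 980; rep_out$end <- 1990  # 2% of TE outside the gap
  expect_null(call_te_insertion(gap, rep_out))
})

test_that("TSD score rule is strict at L*P/100 = 6", {
  # identical 10-bp duplication
  d10 <- motif_windows("GATTACAGTT", "GATTACAGTT")
  t10 <- detect_tsd(d10)
  expect_equal(t10$L, 10)
  expect_equal(t10$P, 100)
  expect_gt(t10$score, 6)

  # perfect 6-mer: score exactly 6.0, rejected (strictly greater needed)
  d6 <- motif_windows("GATTGG", "GATTGG")
  expect_null(detect_tsd(d6))
  # perfect 7-mer: accepted
  expect_false(is.null(detect_tsd(motif_windows("GATTGGT", "GATTGGT"))))

  # L = 9 with 3 interior mismatches: P = 66.7, score 6.003, accepted
  m1 <- "GGGGGGGGG"
  m2 <- "GGTGTGTGG"
  al <- oracle_tsd_align(motif_windows(m1, m2)$flank_left,
                         motif_windows(m1, m2)$flank_right)
  expect_equal(al$L, 9)              # oracle confirms the best segment
  expect_equal(al$matches, 6)
  t9 <- detect_tsd(motif_windows(m1, m2))
  expect_equal(t9$L, 9)
  expect_equal(t9$P, 66.7)
  expect_equal(t9$score, 9 * 66.7 / 100)
  expect_gt(t9$score, 6)

  # truncated boundary window
  tr <- motif_windows("GATTACAGTT", "GATTACAGTT")
  tr$flank_ok <- FALSE
  expect_null(detect_tsd(tr))
})

test_that("TSD scorer equals the exhaustive oracle on random windows", {
  set.seed(99)
  for (i in 1:60) {
    w1 <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    w2 <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    a <- tsd_align(w1, w2)
    o <- oracle_tsd_align(w1, w2)
    expect_equal(a$score, o$score)
    expect_equal(a$matches, o$matches)
    expect_equal(a$L, o$L)
  }
})

test_that("plant-and-recover is exact on noise-free simulations", {
  cfg <- sim_config(seed = 3, seq_length = 5e5, te_rate = 10)
  sim <- simulate_phylogeny(cfg)
  blocks <- simulate_alignment_blocks(sim, "iberian", "cat")
  gaps <- find_gaps(blocks, sim$genomes)
  calls <- call_te_insertions(gaps, sim$repeats$iberian)
  tr <- sim$truth$te_insertions
  tr <- tr[tr$carrier == "iberian", ]
  expect_equal(sort(calls$gap_start), sort(tr$carrier_start))  # recall
  expect_equal(nrow(calls), nrow(tr))                          # precision
  expect_equal(calls$repeat_name[order(calls$gap_start)],
               tr$repeat_name[order(tr$carrier_start)])
})

test_that("branch assignment conserves counts and splits lineages", {
  mk <- function(pos, cls) data.frame(
    carrier = "x", gap_start = pos, gap_end = pos + 100, partner = "cat",
    partner_pos = pos, repeat_name = "r", repeat_class = cls,
    strand = "+", te_coverage_of_gap = 1, te_within_gap = 1,
    tsd_L = 10L, tsd_P = 100, tsd_score = 10, stringsAsFactors = FALSE)
  lynx <- rbind(mk(1000, "SINE"), mk(5000, "LINE"), mk(9000, "LTR"))
  tiger <- rbind(mk(20000, "SINE"), mk(5010, "LINE"))  # one shared anchor
  br <- assign_branches(lynx, tiger)
  expect_equal(sum(br$calls$branch == "lynx"), 2L)
  expect_equal(sum(br$calls$branch == "tiger"), 1L)
  expect_equal(sum(br$calls$branch == "shared"), 1L)   # counted once
  expect_equal(nrow(br$calls), 4L)  # lynx + tiger + shared = distinct
  expect_true("ERV" %in% colnames(br$counts))

  disjoint <- assign_branches(lynx, mk(90000, "SINE"))
  expect_equal(sort(unique(disjoint$calls$branch)), c("lynx", "tiger"))
})

test_that("branch assignment recovers simulated per-branch planting", {
  cfg <- sim_config(seed = 29, seq_length = 5e5, te_rate = 8)
  sim <- simulate_phylogeny(cfg)
  calls <- list()
  for (carrier in c("iberian", "tiger")) {
    bl <- simulate_alignment_blocks(sim, carrier, "cat")
    gaps <- find_gaps(bl, sim$genomes)
    calls[[carrier]] <- call_te_insertions(gaps, sim$repeats[[carrier]])
  }
  br <- assign_branches(calls$iberian, calls$tiger)
  ev <- sim$truth$te_events
  # lynx-vs-cat carries iberian + lynx-ancestor insertions, none of which
  # are in tiger; tiger-vs-cat carries tiger insertions only
  expect_equal(sum(br$calls$branch == "lynx"),
               sum(ev$branch %in% c("iberian", "lynx_ancestor")))
  expect_equal(sum(br$calls$branch == "tiger"), sum(ev$branch == "tiger"))
})

test_that("gene context classifies overlap and orientation", {
  genes <- data.frame(chrom = "chr1", start = c(1000, 8000),
                      end = c(5000, 9000), name = c("g1", "g2"),
                      score = 0, strand = c("-", "+"),
                      stringsAsFactors = FALSE)
  calls <- data.frame(carrier = "chr1",
                      gap_start = c(2000, 6000, 8100, 8200),
                      gap_end = c(2300, 6300, 8400, 8500),
                      strand = c("+", "+", "+", "*"),
                      stringsAsFactors = FALSE)
  gc <- gene_context(calls, genes)
  expect_equal(gc$calls$gene_context,
               c("genic_antisense", "intergenic", "genic_sense",
                 "genic_unstranded"))
  expect_equal(gc$summary$n_genic, 3L)
  expect_equal(gc$summary$n_sense, 1L)
  expect_equal(gc$summary$fraction, 0.5)  # unstranded excluded from denom
})

test_that("sense-orientation fractions match printed-style reporting", {
  calls <- data.frame(carrier = "chr1",
                      gap_start = seq(0, by = 1000, length.out = 112),
                      stringsAsFactors = FALSE)
  calls$gap_end <- calls$gap_start + 200
  calls$strand <- rep(c("+", "-"), c(57, 55))
  genes <- data.frame(chrom = "chr1", start = 0, end = 120000,
                      name = "g", score = 0, strand = "+",
                      stringsAsFactors = FALSE)
  s <- gene_context(calls, genes)$summary
  expect_equal(s$n_sense, 57L)
  expect_equal(s$n_genic, 112L)
  expect_equal(s$fraction, 0.51)
})

test_that("Fisher exact test matches hypergeometric enumeration", {
  expect_equal(sense_enrichment_test(5, 5, 0, 5), 2 / 252,
               tolerance = 1e-12)
  expect_gt(sense_enrichment_test(500, 1000, 500, 1000), 0.99)
  expect_warning(p0 <- sense_enrichment_test(0, 0, 0, 5), "zero-margin")
  expect_equal(p0, 1)
  # spot-check against the enumeration oracle (full sweep in acceptance)
  set.seed(4)
  for (i in 1:25) {
    a <- sample(0:8, 1); b <- sample(0:8, 1)
    c <- sample(0:8, 1); d <- sample(0:8, 1)
    if ((a + b) * (c + d) * (a + c) * (b + d) == 0) next
    expect_equal(sense_enrichment_test(a, a + b, c, c + d),
                 oracle_fisher_p(a, b, c, d), tolerance = 1e-9)
  }
})

test_that("full-ERV reconstruction applies pairing and coverage rules", {
  mk_ltr <- function(s, e, strand = "+", name = "LTR1", fam = "ERV1")
    data.frame(chrom = "chr1", start = s, end = e, strand = strand,
               repeat_name = name, repeat_class = "LTR", family = fam,
               stringsAsFactors = FALSE)
  mk_int <- function(s, e, strand = "+", fam = "ERV1")
    data.frame(chrom = "chr1", start = s, end = e, strand = strand,
               repeat_name = paste0(fam, "-int"),
               repeat_class = "ERV-internal", family = fam,
               stringsAsFactors = FALSE)
  # 500-bp LTRs, 6-kb enclosed with 4 kb same-family internal coverage
  reps <- rbind(mk_ltr(0, 500), mk_ltr(6500, 7000),
                mk_int(1000, 5000))
  erv <- reconstruct_full_ervs(reps)
  expect_equal(nrow(erv), 1L)
  expect_equal(erv$internal_coverage, 4000 / 6000, tolerance = 1e-12)

  # opposite strands never pair
  reps2 <- rbind(mk_ltr(0, 500), mk_ltr(6500, 7000, strand = "-"),
                 mk_int(1000, 5000))
  expect_equal(nrow(reconstruct_full_ervs(reps2)), 0L)

  # insufficient internal coverage
  reps3 <- rbind(mk_ltr(0, 500), mk_ltr(6500, 7000), mk_int(1000, 3000))
  expect_equal(nrow(reconstruct_full_ervs(reps3)), 0L)

  # overlapping candidates: highest internal coverage wins
  reps4 <- rbind(mk_ltr(0, 500, name = "LTR1"),
                 mk_ltr(6500, 7000, name = "LTR1"),
                 mk_ltr(1000, 1500, name = "LTR2"),
                 mk_ltr(6000, 6400, name = "LTR2"),
                 mk_int(1600, 5900))
  both <- reconstruct_full_ervs(reps4)
  expect_equal(nrow(both), 1L)
  expect_equal(both$repeat_name, "LTR2")  # 4300/4500 > 4300/6000
  # non-overlapping accepted candidates are all kept
  reps5 <- rbind(reps, mk_ltr(20000, 20500), mk_ltr(26500, 27000),
                 mk_int(21000, 25000))
  expect_equal(nrow(reconstruct_full_ervs(reps5)), 2L)
})
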