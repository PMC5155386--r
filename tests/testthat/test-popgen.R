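test_that("Watterson's theta follows the harmonic-number formula", {
  # closed form by hand: n = 2 gives a = 1
  expect_equal(watterson_theta(5, 2, 1000), 0.005)
  expect_equal(watterson_theta(0, 8, 1000), 0)
  # printed-scale inputs reproduce the published per-site percentages
  expect_equal(round(100 * watterson_theta(625552, 8, 2021732768), 3),
               0.012)
  expect_equal(round(100 * watterson_theta(1383709, 14, 2021732768), 3),
               0.022)
  expect_error(watterson_theta(5, 1, 1000), "n >= 2")
})

test_that("site heterozygosity uses raw sample frequencies", {
  h <- site_heterozygosity(c(1, 1))
  expect_equal(h$H_O, 1)
  expect_equal(h$p, 0.5)
  expect_equal(h$H_E, 0.5)
  h2 <- site_heterozygosity(c(0, 0, 0))
  expect_equal(h2$H_O, 0)
  expect_equal(h2$H_E, 0)
  h3 <- site_heterozygosity(c(2, 1, 0))
  expect_equal(h3$p, 0.5)
  expect_equal(h3$H_E, 0.5)
  expect_equal(h3$H_O, 1 / 3)
  expect_equal(h3$H_E_unbiased, 0.5 * 6 / 5)
  expect_error(site_heterozygosity(c(NA, NA)), "missing")
})

test_that("per-site pi matches printed-scale arithmetic", {
  expect_equal(per_site_pi(numeric(0), 1e6), 0)
  expect_equal(round(100 * per_site_pi(rep(0.5, 1000), 1e6), 3), 0.05)
  # mean per-SNP H_E 0.336 over 1,587,509 SNPs and the callable universe
  expect_equal(round(100 * per_site_pi(rep(0.336, 1587509), 2021732768),
                     3), 0.026)
  expect_error(per_site_pi(0.5, 0), "L must be")
})

test_that("piS/piN apply the three-quarters site rule per CDS", {
  cds <- data.frame(cds_id = "c1", callable_sites = 400)
  snps <- data.frame(cds_id = "c1", he = 0.5, effect = "synonymous")
  r <- pin_pis(cds, snps)
  expect_equal(r$pi_S, 0.5 / 100)
  expect_equal(r$pi_N, 0)
  expect_equal(r$ratio, 0)

  # equal syn and nonsyn heterozygosity sums give ratio 1/3
  snps2 <- data.frame(cds_id = "c1", he = c(0.4, 0.4),
                      effect = c("synonymous", "nonsynonymous"))
  expect_equal(pin_pis(cds, snps2)$ratio, 1 / 3, tolerance = 1e-12)

  # exactly 200 callable sites is excluded (strictly larger required)
  cds200 <- data.frame(cds_id = "c1", callable_sites = 200)
  expect_error(pin_pis(cds200, snps), "no CDS larger")

  # weighting across CDS by callable length
  cds3 <- data.frame(cds_id = c("c1", "c2"),
                     callable_sites = c(400, 1200))
  snps3 <- data.frame(cds_id = c("c1", "c2"), he = c(0.5, 0.3),
                      effect = "synonymous")
  got <- pin_pis(cds3, snps3)
  expect_equal(got$pi_S,
               (400 * (0.5 / 100) + 1200 * (0.3 / 300)) / 1600,
               tolerance = 1e-12)
})

test_that("ROH detection recovers planted tracts and classifies lengths", {
  cfg <- sim_config(seed = 61, seq_length = 1e7,
                    pop_sizes = c(popA = 3L, popB = 3L),
                    theta = c(popA = 3e-4, popB = 3e-4),
                    roh_fraction = c(popA = 0.3, popB = 0),
                    tract_mean = 2e6)
  p <- simulate_population_genotypes(cfg)
  gm <- p$genotypes
  ind <- "A01"
  het_pos <- gm$sites$start[which(gm$genotypes[, ind] == 1)]
  roh <- detect_roh(het_pos, data.frame(chrom = "chr1", start = 0,
                                        end = 1e7))
  tr <- p$truth[p$truth$individual == ind, ]
  expect_gt(nrow(tr), 0)
  recovered <- sum(vapply(seq_len(nrow(tr)), function(i)
    sum(pmax(0, pmin(tr$end[i], roh$end) - pmax(tr$start[i], roh$start))),
    numeric(1)))
  expect_gte(recovered / sum(tr$end - tr$start), 0.95)

  # a fully heterozygous individual has no ROH
  dense_het <- seq(0, 1e6, by = 500)
  expect_equal(nrow(detect_roh(dense_het,
                               data.frame(chrom = "chr1", start = 0,
                                          end = 1e6 + 1))), 0L)

  # 50-kb homozygous tract between dense heterozygosity is short-class
  hets <- c(seq(0, 1e5, by = 200), seq(1.5e5, 2.5e5, by = 200))
  r <- detect_roh(hets, data.frame(chrom = "chr1", start = 0, end = 2.5e5),
                  min_len = 1e4)
  expect_true(any(r$length_class == "short" &
                    r$start >= 1e5 & r$end <= 1.5e5 + 1))
  # classes partition the detected intervals
  expect_equal(sum(r$end - r$start),
               sum((r$end - r$start)[r$length_class %in%
                                       c("short", "medium", "long")]))
})

test_that("F_ROH counts only tracts strictly longer than the cutoff", {
  roh <- data.frame(chrom = "chr1", start = c(0, 2e6, 5e6),
                    end = c(640e6, 3.5e6, 5.5e6))
  expect_equal(f_roh(roh, 2000e6), 641.5e6 / 2000e6)
  expect_equal(f_roh(roh[2:3, ], 2000e6), 1.5e6 / 2000e6)
  exact <- data.frame(start = 0, end = 1e6)
  expect_equal(f_roh(exact, 2000e6), 0)   # exactly 1 Mb is excluded
  none <- data.frame(start = numeric(0), end = numeric(0))
  expect_equal(f_roh(none, 2000e6), 0)
})

test_that("F_h matches its closed form and is calibrated at HWE", {
  p <- rep(0.5, 100)
  expect_equal(f_h(rep(1, 100), p), -1)    # all heterozygous
  expect_equal(f_h(rep(0, 100), p), 1)     # all homozygous
  set.seed(20)
  g <- stats::rbinom(20000, 2, 0.3)
  expect_lt(abs(f_h(g, rep(0.3, 20000))), 0.02)  # ~0 at HWE
  expect_true(is.na(f_h(c(0, 2), c(0, 1))))      # degenerate denominator
})

test_that("Weir-Cockerham FST behaves at the boundaries", {
  g1 <- matrix(2, nrow = 1, ncol = 10)
  g2 <- matrix(0, nrow = 1, ncol = 10)
  fst <- fst_weir_cockerham(g1, g2)
  expect_gt(fst$fst, 0.95)                # fixed difference

  set.seed(3)
  gg <- matrix(stats::rbinom(100 * 20, 2, 0.4), ncol = 20)
  same <- fst_weir_cockerham(gg[, 1:10], gg[, 11:20])
  expect_lt(abs(same$fst), 0.05)          # no differentiation
  expect_error(fst_weir_cockerham(matrix(NA_integer_, 1, 2),
                                  matrix(0L, 1, 2)), "non-missing")
})

test_that("FST agrees with an independent ANOVA implementation", {
  set.seed(101)
  for (rep in 1:4) {
    n1 <- sample(4:10, 1); n2 <- sample(4:10, 1)
    g1 <- matrix(stats::rbinom(100 * n1, 2, stats::runif(100, 0.05, 0.95)),
                 nrow = 100)
    g2 <- matrix(stats::rbinom(100 * n2, 2, stats::runif(100, 0.05, 0.95)),
                 nrow = 100)
    keep <- rowSums(cbind(g1, g2)) > 0 &
      rowSums(cbind(g1, g2)) < 2 * (n1 + n2)
    g1 <- g1[keep, , drop = FALSE]; g2 <- g2[keep, , drop = FALSE]
    expect_equal(fst_weir_cockerham(g1, g2)$fst,
                 oracle_fst_anova(g1, g2), tolerance = 1e-12)
  }
})

test_that("LD decay r2 and half-max behave on constructed panels", {
  # duplicated site: r2 = 1 at its distance
  set.seed(9)
  g <- matrix(stats::rbinom(5 * 8, 2, 0.5), nrow = 5)
  g[2, ] <- g[1, ]
  sites <- data.frame(chrom = "chr1",
                      start = c(100, 600, 5000, 9000, 12000))
  sites$end <- sites$start + 1
  colnames(g) <- paste0("i", 1:8)
  gm <- genotype_matrix(sites, g, stats::setNames(rep("p", 8),
                                                  colnames(g)), 1e5)
  ld <- ld_decay(gm, max_dist = 2000, n_bins = 4)
  expect_equal(ld$curve$mean_r2[1], 1)     # the duplicated pair's bin
  expect_error(ld_decay(gm, max_dist = 2000, n_bins = 4,
                        individuals = paste0("i", 1:3)), ">= 4")
})

test_that("LD decay mean r2 under independence matches the 1/(n-1) bias", {
  n_ind <- 12
  r2s <- numeric(100)
  set.seed(14)
  for (i in 1:100) {
    g <- matrix(stats::rbinom(30 * n_ind, 2, 0.5), nrow = 30)
    colnames(g) <- paste0("i", seq_len(n_ind))
    sites <- data.frame(chrom = "chr1", start = seq(0, by = 100,
                                                    length.out = 30))
    sites$end <- sites$start + 1
    gm <- genotype_matrix(sites, g,
                          stats::setNames(rep("p", n_ind), colnames(g)),
                          1e5)
    ld <- ld_decay(gm, max_dist = 3000, n_bins = 1)
    r2s[i] <- ld$curve$mean_r2[1]
  }
  se <- stats::sd(r2s) / 10
  expect_lt(abs(mean(r2s) - 1 / (n_ind - 1)), 4 * se)
})

test_that("LD decay recovers a planted exponential decay scale", {
  # haplotypes evolve as a Markov chain: corr(h_i, h_j) = exp(-d/s)
  n_ind <- 60; n_sites <- 400; s <- 5e4
  spacing <- 2500
  set.seed(23)
  rho <- exp(-spacing / s)
  hap <- matrix(0L, n_sites, 2 * n_ind)
  hap[1, ] <- stats::rbinom(2 * n_ind, 1, 0.5)
  for (k in 2:n_sites) {
    keep <- stats::runif(2 * n_ind) < rho
    hap[k, ] <- ifelse(keep, hap[k - 1, ],
                       stats::rbinom(2 * n_ind, 1, 0.5))
  }
  g <- hap[, seq(1, 2 * n_ind, 2)] + hap[, seq(2, 2 * n_ind, 2)]
  colnames(g) <- paste0("i", seq_len(n_ind))
  sites <- data.frame(chrom = "chr1",
                      start = seq(0, by = spacing, length.out = n_sites))
  sites$end <- sites$start + 1
  gm <- genotype_matrix(sites, g,
                        stats::setNames(rep("p", n_ind), colnames(g)),
                        1e7)
  ld <- ld_decay(gm, max_dist = 3e5, n_bins = 30)
  # expected half-max of the analytic curve r2(d) = exp(-2d/s) between
  # its first-bin and asymptote values, through the same definition
  mids <- ld$curve$mid
  analytic <- exp(-2 * mids / s)
  target <- (analytic[1] + analytic[length(analytic)]) / 2
  d_true <- mids[which(analytic <= target)[1]]
  expect_false(is.na(ld$half_max_dist))
  expect_lt(abs(ld$half_max_dist - d_true) / d_true, 0.2)
})

test_that("delta-Z heterozygosity standardizes and flags planted loss", {
  set.seed(6)
  het <- stats::runif(200, 1e-4, 1e-3)
  same <- delta_zh(het, het)
  expect_true(all(same$dz == 0))
  expect_false(any(same$outlier_high | same$outlier_low))

  het_b <- het * stats::runif(200, 0.8, 1.2)
  dz <- delta_zh(het, het_b)
  expect_equal(mean(dz$z_a), 0, tolerance = 1e-12)
  expect_equal(stats::sd(dz$z_b), 1, tolerance = 1e-12)

  # plant strong heterozygosity loss in species b in 5 windows, against
  # an otherwise identical diversity landscape
  lost <- c(10, 50, 90, 130, 170)
  het_lost <- het
  het_lost[lost] <- het_lost[lost] * 0.01
  dz2 <- delta_zh(het, het_lost)
  expect_true(all(dz2$outlier_high[lost]))  # z_a - z_b large positive
  expect_error(delta_zh(het[1:10], het[1:10]), ">= 40")
  expect_error(delta_zh(rep(1e-4, 50), stats::runif(50)), "zero")

  pz <- delta_zh(het, het_lost, tail = 0.025, mode = "percentile")
  expect_true(all(pz$outlier_high[lost]))
})

test_that("subtelomeric enrichment tests window positions", {
  lens <- c(chrA = 5e7)
  win <- data.frame(chrom = "chrA",
                    start = seq(0, 4.9e7, by = 1e5))
  win$end <- win$start + 1e5
  subtel <- win$start < 5e6 | win$end > 4.5e7
  # flags uniformly spread: no enrichment
  set.seed(2)
  fl <- seq_len(nrow(win)) %% 10 == 0
  r <- subtelomeric_enrichment(win, fl, lens)
  expect_gt(r$p, 0.05)
  # all flags inside the margins: extreme enrichment
  fl2 <- subtel & seq_len(nrow(win)) %% 2 == 0
  r2 <- subtelomeric_enrichment(win, fl2, lens)
  expect_lt(r2$p, 1e-6)
  expect_equal(r2$prop_flagged_subtel, 1)
  # degenerate geometry: margin covers the whole chromosome
  expect_message(subtelomeric_enrichment(win, fl, c(chrA = 9e6)),
                 "whole chromosome")
})

test_that("X/autosome ratio and bootstrap SE are exact and reproducible", {
  set.seed(12)
  auto <- stats::runif(50, 0.8, 1.2)
  x <- auto[1:20] * 0.75
  r <- xa_ratio(x, auto, n_boot = 200, seed = 5)
  expect_equal(r$ratio, mean(x) / mean(auto))
  r2 <- xa_ratio(x, auto, n_boot = 200, seed = 5)
  expect_identical(r$se, r2$se)           # same seed, same SE

  # constructed 0.75x compartments give exactly 0.75
  xx <- rep(0.75, 20); aa <- rep(1, 30)
  expect_equal(xa_ratio(xx, aa, n_boot = 50, seed = 1)$ratio, 0.75)

  # planted equality: ratio within 2 bootstrap SEs of 1
  set.seed(33)
  a2 <- stats::runif(40, 0.9, 1.1); x2 <- stats::runif(40, 0.9, 1.1)
  re <- xa_ratio(x2, a2, n_boot = 500, seed = 9)
  expect_lt(abs(re$ratio - 1), 2 * re$se)
  expect_error(xa_ratio(x2[1:5], a2, n_boot = 10, seed = 1), ">= 10")
})
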