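# Population-genomic erosion statistics: diversity, inbreeding, ROH,
# differentiation, LD decay, heterozygosity-outlier windows and
# X/autosome ratios.

#' Watterson's theta per site
#'
#' `theta = S / (a_n * L)` with `a_n` the harmonic number of `n - 1`.
#'
#' @param S number of segregating sites.
#' @param n number of sampled chromosomes (>= 2).
#' @param L number of callable sites (variant + invariant).
#' @return theta per site (proportion, not percent).
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2) stop("need n >= 2 chromosomes")
  if (L <= 0) stop("L must be > 0")
  a_n <- sum(1 / seq_len(n - 1))
  S / (a_n * L)
}

#' Observed and expected heterozygosity of one site
#'
#' `H_O` is the fraction of heterozygous individuals; `H_E = 2p(1-p)`
#' with `p` the sample alternate-allele frequency (no small-sample
#' correction, matching per-SNP summaries computed on raw frequencies).
#' The `n/(n-1)`-corrected value is returned separately as `H_E_unbiased`.
#'
#' @param g diploid dosage vector (0/1/2, `NA` = missing).
#' @return list: `H_O`, `H_E`, `H_E_unbiased`, `p`, `n_chrom`.
#' @export
site_heterozygosity <- function(g) {
  g <- g[!is.na(g)]
  if (length(g) == 0) stop("all genotypes missing")
  n_chrom <- 2 * length(g)
  p <- sum(g) / n_chrom
  he <- 2 * p * (1 - p)
  list(H_O = mean(g == 1), H_E = he,
       H_E_unbiased = if (n_chrom > 1) he * n_chrom / (n_chrom - 1)
                      else NA_real_,
       p = p, n_chrom = n_chrom)
}

#' Per-site nucleotide diversity from per-SNP expected heterozygosities
#'
#' `pi = sum(H_E) / L` over the species-wide SNP universe (sites
#' monomorphic in a focal population contribute 0).
#'
#' @param he per-SNP expected heterozygosities.
#' @param L callable-site count.
#' @param unbiased apply the `n/(n-1)` correction via `n_chrom`.
#' @param n_chrom chromosomes sampled (needed if `unbiased`).
#' @return pi per site.
#' @export
per_site_pi <- function(he, L, unbiased = FALSE, n_chrom = NULL) {
  if (L <= 0) stop("L must be > 0")
  if (unbiased) {
    stopifnot(!is.null(n_chrom))
    he <- he * n_chrom / (n_chrom - 1)
  }
  sum(he) / L
}

#' Table-style diversity summary for a population
#'
#' Computes SNP count, per-SNP observed/expected heterozygosity
#' (averaged over the species-wide SNP universe), Watterson's theta and
#' per-site pi for one population (or the whole panel).
#'
#' @param gm [genotype_matrix()].
#' @param population population label, or `NULL` for all individuals.
#' @return list with `S`, `n_chrom`, `H_O`, `H_E`, `theta_W`, `pi`.
#' @export
diversity_summary <- function(gm, population = NULL) {
  cols <- if (is.null(population)) colnames(gm$genotypes)
          else names(gm$populations)[gm$populations == population]
  g <- gm$genotypes[, cols, drop = FALSE]
  nn <- rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / (2 * nn)
  seg <- !is.na(p) & p > 0 & p < 1
  he <- 2 * p * (1 - p)
  he[!seg] <- 0
  ho <- rowMeans(g == 1, na.rm = TRUE)
  ho[!seg] <- 0
  n_chrom <- 2 * length(cols)
  list(S = sum(seg), n_chrom = n_chrom,
       H_O = mean(ho[seg]), H_E = mean(he[seg]),
       theta_W = watterson_theta(sum(seg), n_chrom, gm$callable_sites),
       pi = per_site_pi(he, gm$callable_sites))
}

#' Synonymous and nonsynonymous nucleotide diversity (piS, piN)
#'
#' Assumes three-quarters of coding sites are nonsynonymous: per CDS
#' `piS = sum(H_E syn) / (L_c/4)` and `piN = sum(H_E nonsyn) / (3 L_c/4)`.
#' CDS with 200 or fewer callable sites are excluded (strictly larger
#' than 200 qualifies); genomic values are `L_c`-weighted means and the
#' ratio is the ratio of those means.
#'
#' @param cds data.frame: `cds_id`, `callable_sites`.
#' @param snps data.frame: `cds_id`, `he` (per-SNP expected
#'   heterozygosity), `effect` (`"synonymous"`/`"nonsynonymous"`).
#' @param min_callable CDS size threshold (strict).
#' @return list: `pi_S`, `pi_N`, `ratio`, `n_cds`.
#' @export
pin_pis <- function(cds, snps, min_callable = 200) {
  use <- cds[cds$callable_sites > min_callable, , drop = FALSE]
  if (nrow(use) == 0) stop("no CDS larger than ", min_callable,
                           " callable sites")
  ps <- pn <- numeric(nrow(use))
  for (i in seq_len(nrow(use))) {
    s <- snps[snps$cds_id == use$cds_id[i], , drop = FALSE]
    Lc <- use$callable_sites[i]
    ps[i] <- sum(s$he[s$effect == "synonymous"]) / (Lc / 4)
    pn[i] <- sum(s$he[s$effect == "nonsynonymous"]) / (3 * Lc / 4)
  }
  w <- use$callable_sites
  pi_S <- sum(ps * w) / sum(w)
  pi_N <- sum(pn * w) / sum(w)
  list(pi_S = pi_S, pi_N = pi_N,
       ratio = if (pi_S > 0) pi_N / pi_S else NA_real_,
       n_cds = nrow(use))
}

#' Detect runs of homozygosity for one individual
#'
#' Deterministic density rule: maximal stretches of callable sequence in
#' which the heterozygote density stays at or below `max_het_per_mb`,
#' built by greedily merging het-free callable runs across single
#' heterozygous sites (lowest resulting density first).  Runs shorter
#' than `min_len` are discarded; survivors are classified as short
#' (10-100 kb), medium (100 kb - 1 Mb) or long (> 1 Mb).
#'
#' @param het_pos 0-based positions of heterozygous genotypes.
#' @param callable data.frame of callable intervals (`chrom`, `start`,
#'   `end`); typically one interval per chromosome.
#' @param min_len minimal reported length (bp).
#' @param max_het_per_mb maximal heterozygous sites per Mb inside a run.
#' @param chrom chromosome of `het_pos` (single-chromosome call).
#' @return data.frame: `chrom`, `start`, `end`, `n_het`, `length_class`.
#' @export
detect_roh <- function(het_pos, callable, min_len = 1e4,
                       max_het_per_mb = 1, chrom = NULL) {
  out <- list()
  for (ci in seq_len(nrow(callable))) {
    c0 <- callable$start[ci]; c1 <- callable$end[ci]
    cc <- callable$chrom[ci]
    h <- sort(het_pos[het_pos >= c0 & het_pos < c1])
    if (!is.null(chrom) && length(chrom) == length(het_pos))
      h <- sort(het_pos[chrom == cc & het_pos >= c0 & het_pos < c1])
    # segments between hets; segs[i] spans (bounds[i], bounds[i+1])
    bounds <- c(c0 - 1, h, c1)
    # het-free runs: from just after one het to just before the next
    seg <- data.frame(start = bounds[-length(bounds)] + 1,
                      end = c(h, c1), n_het = 0)
    seg <- seg[seg$end > seg$start, , drop = FALSE]
    if (nrow(seg) == 0) next
    repeat {
      if (nrow(seg) < 2) break
      dens <- rep(Inf, nrow(seg) - 1)
      for (i in seq_len(nrow(seg) - 1)) {
        len <- seg$end[i + 1] - seg$start[i]
        nh <- seg$n_het[i] + seg$n_het[i + 1] + 1
        dens[i] <- nh / (len / 1e6)
      }
      i <- which.min(dens)
      if (dens[i] > max_het_per_mb) break
      seg$end[i] <- seg$end[i + 1]
      seg$n_het[i] <- seg$n_het[i] + seg$n_het[i + 1] + 1
      seg <- seg[-(i + 1), , drop = FALSE]
    }
    seg <- seg[seg$end - seg$start >= min_len, , drop = FALSE]
    if (nrow(seg))
      out[[length(out) + 1]] <- data.frame(chrom = cc, seg,
                                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_het = numeric(),
                      length_class = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  len <- res$end - res$start
  res$length_class <- ifelse(len > 1e6, "long",
                             ifelse(len > 1e5, "medium", "short"))
  rownames(res) <- NULL
  res
}

#' ROH-based inbreeding coefficient
#'
#' Fraction of the genome in runs of homozygosity strictly longer than
#' `min_len` (default 1 Mb).
#'
#' @param roh [detect_roh()] output for one individual.
#' @param genome_length total (callable) genome length.
#' @param min_len length cutoff, strict.
#' @return F_ROH.
#' @export
f_roh <- function(roh, genome_length, min_len = 1e6) {
  stopifnot(genome_length > 0)
  len <- roh$end - roh$start
  sum(len[len > min_len]) / genome_length
}

#' Excess-homozygosity inbreeding coefficient
#'
#' `F_h = (O_hom - E_hom) / (N - E_hom)` with
#' `E_hom = sum(1 - 2 p (1 - p))` over the individual's genotyped sites.
#'
#' @param g diploid dosage vector for one individual.
#' @param p allele frequencies (same length), from the individual's
#'   population (including the individual by default).
#' @return F_h (or `NA` for a degenerate denominator).
#' @export
f_h <- function(g, p) {
  keep <- !is.na(g) & !is.na(p)
  g <- g[keep]; p <- p[keep]
  e_hom <- sum(1 - 2 * p * (1 - p))
  o_hom <- sum(g != 1)
  denom <- length(g) - e_hom
  if (abs(denom) < 1e-12) return(NA_real_)
  (o_hom - e_hom) / denom
}

#' Weir-Cockerham FST between two populations
#'
#' Variance-components estimator (a, b, c) for diploid data; the global
#' estimate is `sum(a) / sum(a + b + c)` over sites polymorphic in the
#' combined sample.
#'
#' @param g1,g2 site x individual dosage matrices for the two
#'   populations.
#' @return list: `fst` (global), `per_site` (vector, `NA` where
#'   undefined), `a`, `b`, `c`.
#' @export
fst_weir_cockerham <- function(g1, g2) {
  g1 <- as.matrix(g1); g2 <- as.matrix(g2)
  stopifnot(nrow(g1) == nrow(g2))
  n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
  if (any(n1 < 2) || any(n2 < 2))
    stop("need >= 2 non-missing genotypes per population at every site")
  p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- rowMeans(g1 == 1, na.rm = TRUE)
  h2 <- rowMeans(g2 == 1, na.rm = TRUE)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) /
       (4 * nbar))
  cc <- hbar / 2
  poly <- pbar > 0 & pbar < 1
  per_site <- ifelse(poly & (a + b + cc) != 0, a / (a + b + cc), NA_real_)
  fst <- sum(a[poly]) / sum((a + b + cc)[poly])
  list(fst = fst, per_site = per_site, a = a, b = b, c = cc)
}

#' Linkage-disequilibrium decay
#'
#' `r^2` is the squared Pearson correlation between diploid dosage
#' vectors across individuals, for all site pairs within `max_dist` on
#' the same chromosome, binned by distance.  The half-max distance is
#' where the monotone-smoothed (antitonic) curve falls to
#' `(max + asymptote) / 2`, linearly interpolated between bin midpoints.
#'
#' @param gm [genotype_matrix()].
#' @param max_dist maximal pair distance (bp).
#' @param n_bins number of equal-width distance bins.
#' @param individuals optional subset of individuals.
#' @return list: `curve` (data.frame `mid`, `mean_r2`, `n_pairs`,
#'   `smoothed`), `half_max_dist`.
#' @export
ld_decay <- function(gm, max_dist, n_bins = 20, individuals = NULL) {
  g <- gm$genotypes
  if (!is.null(individuals)) g <- g[, individuals, drop = FALSE]
  if (ncol(g) < 4) stop("need >= 4 individuals for r^2")
  d_all <- numeric(0); r2_all <- numeric(0)
  for (chr in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == chr)
    pos <- gm$sites$start[idx]
    gg <- g[idx, , drop = FALSE]
    sds <- apply(gg, 1, stats::sd, na.rm = TRUE)
    for (i in seq_along(idx)) {
      if (is.na(sds[i]) || sds[i] == 0) next
      j <- i + 1
      while (j <= length(idx) && pos[j] - pos[i] <= max_dist) {
        if (!is.na(sds[j]) && sds[j] > 0) {
          r <- suppressWarnings(stats::cor(gg[i, ], gg[j, ],
                                           use = "complete.obs"))
          if (!is.na(r)) {
            d_all <- c(d_all, pos[j] - pos[i])
            r2_all <- c(r2_all, r^2)
          }
        }
        j <- j + 1
      }
    }
  }
  if (length(d_all) == 0) stop("no informative site pairs within max_dist")
  br <- seq(0, max_dist, length.out = n_bins + 1)
  bin <- cut(d_all, br, include.lowest = TRUE, labels = FALSE)
  mids <- (br[-1] + br[-(n_bins + 1)]) / 2
  mean_r2 <- tapply(r2_all, factor(bin, levels = seq_len(n_bins)), mean)
  n_pairs <- tapply(rep(1, length(bin)),
                    factor(bin, levels = seq_len(n_bins)), sum)
  keep <- !is.na(mean_r2)
  mids <- mids[keep]; mean_r2 <- as.numeric(mean_r2[keep])
  n_pairs <- as.numeric(n_pairs[keep])
  # antitonic (monotone nonincreasing) smoothing
  ir <- stats::isoreg(mids, -mean_r2)
  smoothed <- -ir$yf
  hi <- smoothed[1]; lo <- smoothed[length(smoothed)]
  target <- (hi + lo) / 2
  half <- NA_real_
  for (i in seq_along(smoothed)[-1]) {
    if (smoothed[i] <= target && smoothed[i - 1] > target) {
      half <- mids[i - 1] + (mids[i] - mids[i - 1]) *
        (smoothed[i - 1] - target) / (smoothed[i - 1] - smoothed[i])
      break
    }
  }
  list(curve = data.frame(mid = mids, mean_r2 = mean_r2,
                          n_pairs = n_pairs, smoothed = smoothed),
       half_max_dist = half)
}

#' Standardized heterozygosity difference between two species
#'
#' Z-transforms each species' per-window heterozygosity with that
#' species' own mean and SD and takes the difference
#' `dZ = Z_a - Z_b`.  Outliers are either the `tail` largest positive
#' and negative windows (rank mode, the default) or windows beyond the
#' stated percentiles (percentile mode).
#'
#' @param het_a,het_b per-window heterozygosities (same windows).
#' @param tail two-tailed outlier fraction (rank mode).
#' @param mode `"rank"` or `"percentile"`; percentile mode flags
#'   `dZ > quantile(1 - tail)` and `dZ <= quantile(tail)`.
#' @return data.frame: `z_a`, `z_b`, `dz`, `outlier_high`, `outlier_low`.
#' @export
delta_zh <- function(het_a, het_b, tail = 0.025,
                     mode = c("rank", "percentile")) {
  mode <- match.arg(mode)
  stopifnot(length(het_a) == length(het_b))
  n <- length(het_a)
  if (n < 40) stop("need >= 40 windows")
  if (stats::sd(het_a) == 0 || stats::sd(het_b) == 0) {
    if (all(het_a == het_b)) {
      return(data.frame(z_a = 0, z_b = 0, dz = rep(0, n),
                        outlier_high = FALSE, outlier_low = FALSE))
    }
    stop("zero heterozygosity SD in one species")
  }
  z_a <- (het_a - mean(het_a)) / stats::sd(het_a)
  z_b <- (het_b - mean(het_b)) / stats::sd(het_b)
  dz <- z_a - z_b
  if (mode == "rank") {
    k <- ceiling(tail * n)
    ord <- order(dz, seq_len(n))
    hi <- seq_len(n) %in% ord[(n - k + 1):n] & dz > 0
    lo <- seq_len(n) %in% ord[1:k] & dz < 0
  } else {
    qhi <- stats::quantile(dz, 1 - tail, names = FALSE)
    qlo <- stats::quantile(dz, tail, names = FALSE)
    hi <- dz > qhi
    lo <- dz <= qlo
  }
  data.frame(z_a = z_a, z_b = z_b, dz = dz,
             outlier_high = hi, outlier_low = lo)
}

#' Subtelomeric enrichment of flagged windows
#'
#' A window is subtelomeric iff it overlaps the first or last `margin`
#' bp of its chromosome.  Enrichment of flagged windows in subtelomeric
#' regions is tested with a two-sided Fisher exact test.
#'
#' @param windows data.frame with `chrom`, `start`, `end`.
#' @param flagged logical vector per window.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param margin subtelomere width (bp).
#' @return list: `p`, `table`, `prop_flagged_subtel`,
#'   `prop_unflagged_subtel`, `subtelomeric` (per-window flag).
#' @export
subtelomeric_enrichment <- function(windows, flagged, chrom_lengths,
                                    margin = 5e6) {
  len <- chrom_lengths[windows$chrom]
  if (any(is.na(len))) stop("missing chromosome length")
  if (any(margin * 2 >= chrom_lengths))
    message("margin covers whole chromosome(s): ",
            paste(names(chrom_lengths)[margin * 2 >= chrom_lengths],
                  collapse = ", "))
  subtel <- windows$start < margin | windows$end > len - margin
  tab <- table(factor(flagged, levels = c(TRUE, FALSE)),
               factor(subtel, levels = c(TRUE, FALSE)))
  p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1
       else stats::fisher.test(tab)$p.value
  list(p = p, table = tab,
       prop_flagged_subtel = mean(subtel[flagged]),
       prop_unflagged_subtel = mean(subtel[!flagged]),
       subtelomeric = subtel)
}

#' X-to-autosome normalized diversity ratio with bootstrap SE
#'
#' Ratio of mean pi/D (diversity normalized by divergence) over X
#' windows to that over autosomal windows; the standard error is
#' obtained by bootstrap over windows, resampling within each
#' compartment.
#'
#' @param pid_x,pid_auto per-window pi/D values for X and autosomes.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed (bootstrap is deterministic given the seed).
#' @return list: `ratio`, `se`, `n_x`, `n_auto`.
#' @export
xa_ratio <- function(pid_x, pid_auto, n_boot = 1000, seed = 1L) {
  if (length(pid_x) < 10 || length(pid_auto) < 10)
    stop("need >= 10 windows per compartment")
  dat <- data.frame(v = c(pid_x, pid_auto),
                    comp = rep(c("X", "A"),
                               c(length(pid_x), length(pid_auto))))
  statistic <- function(d, idx) {
    dd <- d[idx, ]
    mean(dd$v[dd$comp == "X"]) / mean(dd$v[dd$comp == "A"])
  }
  bt <- with_seed(seed,
                  boot::boot(dat, statistic, R = n_boot,
                             strata = factor(dat$comp)))
  list(ratio = mean(pid_x) / mean(pid_auto),
       se = stats::sd(bt$t),
       n_x = length(pid_x), n_auto = length(pid_auto))
}
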