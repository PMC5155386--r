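# Polarization of substitutions on the (tiger,(cat,(Iberian,Eurasian)))
# topology, weak-to-strong bias quantification, and 100-kb window scans
# for faster-evolving regions and their relation to heterozygosity.

SITE_CATEGORIES <- c("invariant", "shared_lynx_substitution",
                     "iberian_specific", "eurasian_specific", "cat_branch",
                     "heterozygous", "unpolarizable")

#' Polarize one site on the four-taxon topology
#'
#' Lynx genotypes are given as `"X/Y"` strings (or single bases for
#' homozygotes).  Any heterozygous lynx genotype makes the site
#' `heterozygous`; lynx-branch assignment requires outgroup agreement
#' (tiger == cat), otherwise the site is `unpolarizable`.
#'
#' @param cat,tiger single bases.
#' @param iberian,eurasian genotypes (`"G"`, `"G/G"` or `"A/G"`).
#' @return list: `category`, `ancestral`, `derived`, `branch` (`NA` for
#'   non-substitution categories).
#' @export
polarize_site <- function(cat, tiger, iberian, eurasian) {
  split_gt <- function(g) {
    a <- strsplit(g, "/", fixed = TRUE)[[1]]
    if (length(a) == 1) c(a, a) else a
  }
  ib <- split_gt(iberian); eu <- split_gt(eurasian)
  bases <- c(cat, tiger, ib, eu)
  if (!all(bases %in% c("A", "C", "G", "T")))
    return(list(category = "dropped", ancestral = NA_character_,
                derived = NA_character_, branch = NA_character_))
  none <- list(ancestral = NA_character_, derived = NA_character_,
               branch = NA_character_)
  if (ib[1] != ib[2] || eu[1] != eu[2])
    return(c(list(category = "heterozygous"), none))
  ib <- ib[1]; eu <- eu[1]
  if (cat == tiger && cat == ib && cat == eu)
    return(c(list(category = "invariant"), none))
  if (cat == tiger) {
    anc <- cat
    if (ib == eu && ib != anc)
      return(list(category = "shared_lynx_substitution", ancestral = anc,
                  derived = ib, branch = "lynx_ancestor"))
    if (ib != anc && eu == anc)
      return(list(category = "iberian_specific", ancestral = anc,
                  derived = ib, branch = "iberian"))
    if (eu != anc && ib == anc)
      return(list(category = "eurasian_specific", ancestral = anc,
                  derived = eu, branch = "eurasian"))
    return(c(list(category = "unpolarizable"), none))
  }
  if (tiger == ib && tiger == eu && cat != tiger)
    return(list(category = "cat_branch", ancestral = tiger, derived = cat,
                branch = "cat"))
  c(list(category = "unpolarizable"), none)
}

#' Classify a substitution as weak/strong transition type
#'
#' W = \{A, T\} (weak, two hydrogen bonds), S = \{C, G\} (strong).
#'
#' @param ancestral,derived single distinct bases.
#' @return one of `"WS"`, `"SW"`, `"WW"`, `"SS"`.
#' @export
classify_ws <- function(ancestral, derived) {
  stopifnot(ancestral %in% c("A", "C", "G", "T"),
            derived %in% c("A", "C", "G", "T"))
  if (any(ancestral == derived)) stop("ancestral and derived bases equal")
  cls <- function(b) ifelse(b %in% c("A", "T"), "W", "S")
  paste0(cls(ancestral), cls(derived))
}

#' Build a polarized site table from four aligned genomes
#'
#' Convenience for simulated data: compares the four genome strings
#' position by position (optionally with planted lynx heterozygous
#' sites) and polarizes every site.
#'
#' @param genomes named character vector with `cat`, `tiger`, `iberian`,
#'   `eurasian` (equal lengths; simulate with `te_rate = 0`).
#' @param het_sites optional data.frame (`species`, `position`,
#'   `allele`) of lynx heterozygous sites.
#' @param chrom chromosome label for the output.
#' @return data.frame: `chrom`, `pos`, `category`, `ancestral`,
#'   `derived`, `branch`, `ws`, `het_iberian`, `het_eurasian`.
#' @export
polarize_genomes <- function(genomes, het_sites = NULL, chrom = "chr1") {
  sp <- lapply(genomes[c("cat", "tiger", "iberian", "eurasian")],
               function(s) strsplit(s, "")[[1]])
  L <- unique(lengths(sp))
  if (length(L) != 1)
    stop("genomes must have equal length (simulate with te_rate = 0)")
  het_ib <- rep(FALSE, L); het_eu <- rep(FALSE, L)
  if (!is.null(het_sites) && nrow(het_sites)) {
    het_ib[het_sites$position[het_sites$species == "iberian"] + 1] <- TRUE
    het_eu[het_sites$position[het_sites$species == "eurasian"] + 1] <- TRUE
  }
  # categories are vectorized; the scalar polarize_site defines the rules
  cat_b <- sp$cat; tig <- sp$tiger; ib <- sp$iberian; eu <- sp$eurasian
  category <- rep("unpolarizable", L)
  ancestral <- rep(NA_character_, L); derived <- rep(NA_character_, L)
  branch <- rep(NA_character_, L)
  het <- het_ib | het_eu
  inv <- !het & cat_b == tig & cat_b == ib & cat_b == eu
  out_ok <- !het & cat_b == tig
  sh <- out_ok & ib == eu & ib != cat_b
  ibs <- out_ok & ib != cat_b & eu == cat_b
  eus <- out_ok & eu != cat_b & ib == cat_b
  catb <- !het & cat_b != tig & tig == ib & tig == eu
  category[catb] <- "cat_branch"
  ancestral[catb] <- tig[catb]; derived[catb] <- cat_b[catb]
  branch[catb] <- "cat"
  category[sh] <- "shared_lynx_substitution"
  ancestral[sh] <- cat_b[sh]; derived[sh] <- ib[sh]
  branch[sh] <- "lynx_ancestor"
  category[ibs] <- "iberian_specific"
  ancestral[ibs] <- cat_b[ibs]; derived[ibs] <- ib[ibs]
  branch[ibs] <- "iberian"
  category[eus] <- "eurasian_specific"
  ancestral[eus] <- cat_b[eus]; derived[eus] <- eu[eus]
  branch[eus] <- "eurasian"
  category[inv] <- "invariant"
  category[het] <- "heterozygous"
  ws <- rep(NA_character_, L)
  has <- !is.na(ancestral)
  w <- c(A = "W", T = "W", C = "S", G = "S")
  ws[has] <- paste0(w[ancestral[has]], w[derived[has]])
  data.frame(chrom = chrom, pos = seq_len(L) - 1L, category = category,
             ancestral = ancestral, derived = derived, branch = branch,
             ws = ws, het_iberian = het_ib, het_eurasian = het_eu,
             stringsAsFactors = FALSE)
}

#' Condense polarized sites into non-overlapping windows
#'
#' Windows tile each chromosome from coordinate 0; windows with fewer
#' than `min_informative` informative sites (any non-dropped site) are
#' omitted.  Heterozygous sites contribute to the heterozygosity tallies
#' but never to substitution counts.
#'
#' @param sites polarized site table ([polarize_genomes()] layout).
#' @param window_size window width in bp (default 100 kb).
#' @param min_informative minimal informative sites per emitted window.
#' @return data.frame of per-window statistics.
#' @export
window_scan <- function(sites, window_size = 1e5, min_informative = 1e4) {
  sites <- sites[sites$category %in% c(SITE_CATEGORIES), , drop = FALSE]
  win <- floor(sites$pos / window_size)
  key <- paste(sites$chrom, win)
  out <- list()
  for (k in unique(key)) {
    s <- sites[key == k, , drop = FALSE]
    n_inf <- nrow(s)
    if (n_inf < min_informative) next
    w0 <- floor(s$pos[1] / window_size) * window_size
    cnt <- table(factor(s$category, levels = SITE_CATEGORIES))
    ws_frac <- function(br) {
      b <- s$branch == br & !is.na(s$branch)
      n <- sum(b)
      if (n == 0) return(NA_real_)
      sum(s$ws[b] == "WS") / n
    }
    out[[length(out) + 1]] <- data.frame(
      chrom = s$chrom[1], start = w0, end = w0 + window_size,
      n_informative = n_inf,
      n_invariant = as.integer(cnt[["invariant"]]),
      n_shared = as.integer(cnt[["shared_lynx_substitution"]]),
      n_iberian = as.integer(cnt[["iberian_specific"]]),
      n_eurasian = as.integer(cnt[["eurasian_specific"]]),
      n_cat = as.integer(cnt[["cat_branch"]]),
      n_heterozygous = as.integer(cnt[["heterozygous"]]),
      n_unpolarizable = as.integer(cnt[["unpolarizable"]]),
      ws_iberian = ws_frac("iberian"), ws_eurasian = ws_frac("eurasian"),
      ws_lynx_ancestor = ws_frac("lynx_ancestor"), ws_cat = ws_frac("cat"),
      het_iberian = sum(s$het_iberian) / n_inf,
      het_eurasian = sum(s$het_eurasian) / n_inf,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(NULL)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Flag faster-evolving regions (FRs) between two lineages
#'
#' Per window, the log ratio of pseudocounted branch substitution counts
#' is computed; the `ceiling(tail_quantile * N)` windows with the
#' largest ratios are FRs of lineage A, the same number with the
#' smallest are FRs of lineage B (ties broken by stable window order).
#'
#' @param windows window table from [window_scan()].
#' @param col_a,col_b substitution-count columns for the two lineages
#'   (e.g. `"n_iberian"`, `"n_eurasian"`).
#' @param tail_quantile two-tailed flagging quantile.
#' @param pseudocount added to both counts.
#' @return `windows` with `log_ratio`, `fr_a`, `fr_b` columns.
#' @export
identify_frs <- function(windows, col_a, col_b, tail_quantile = 0.025,
                         pseudocount = 1) {
  n <- nrow(windows)
  if (n < 40) stop("need >= 40 windows for a meaningful quantile")
  lr <- log((windows[[col_a]] + pseudocount) /
              (windows[[col_b]] + pseudocount))
  k <- ceiling(tail_quantile * n)
  ord <- order(lr, seq_len(n))  # stable
  windows$log_ratio <- lr
  windows$fr_a <- seq_len(n) %in% ord[(n - k + 1):n]
  windows$fr_b <- seq_len(n) %in% ord[1:k]
  windows
}

#' Correlation between substitution-rate and heterozygosity ratios
#'
#' Pearson correlation (with two-sided p) between per-window log ratios
#' of branch substitution counts and of heterozygosity between two
#' lineages.  An inverse correlation indicates that faster-evolving
#' windows in a lineage are windows where that lineage lost
#' heterozygosity (differential fixation of ancestral polymorphism).
#'
#' @param windows window table.
#' @param subs_a,subs_b,het_a,het_b column names.
#' @param pseudocount added to substitution counts; heterozygosity gets
#'   a small epsilon.
#' @return list: `r`, `p`, `n`.
#' @export
rate_het_correlation <- function(windows, subs_a = "subs_a",
                                 subs_b = "subs_b", het_a = "het_a",
                                 het_b = "het_b", pseudocount = 1) {
  if (nrow(windows) < 3) stop("need >= 3 windows")
  lr <- log((windows[[subs_a]] + pseudocount) /
              (windows[[subs_b]] + pseudocount))
  eps <- 1e-9
  lh <- log((windows[[het_a]] + eps) / (windows[[het_b]] + eps))
  ct <- stats::cor.test(lr, lh, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(windows))
}

#' Per-branch weak-to-strong substitution fractions
#'
#' Pools substitutions per branch over a polarized site table and
#' reports the W->S fraction with a binomial confidence interval.
#'
#' @param sites polarized site table.
#' @param conf confidence level.
#' @return data.frame: `branch`, `n_subs`, `n_ws`, `ws_fraction`,
#'   `ci_lo`, `ci_hi` (fraction `NA` when a branch has no
#'   substitutions).
#' @export
ws_bias_summary <- function(sites, conf = 0.95) {
  branches <- c("iberian", "eurasian", "lynx_ancestor", "cat")
  rows <- lapply(branches, function(br) {
    b <- !is.na(sites$branch) & sites$branch == br
    n <- sum(b)
    nws <- sum(sites$ws[b] == "WS")
    if (n == 0)
      return(data.frame(branch = br, n_subs = 0L, n_ws = 0L,
                        ws_fraction = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, stringsAsFactors = FALSE))
    bt <- stats::binom.test(nws, n, conf.level = conf)
    data.frame(branch = br, n_subs = n, n_ws = nws,
               ws_fraction = nws / n, ci_lo = bt$conf.int[1],
               ci_hi = bt$conf.int[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
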