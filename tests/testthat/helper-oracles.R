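# Independent oracles used to cross-check the package implementations.

# Exhaustive ungapped local alignment by explicit substring comparison:
# loops over every start pair and length, keeping the best segment under
# the (score, percent identity, length) lexicographic ordering.
oracle_tsd_align <- function(a, b) {
  xa <- strsplit(toupper(a), "")[[1]]
  xb <- strsplit(toupper(b), "")[[1]]
  best <- NULL
  for (i in seq_along(xa)) for (j in seq_along(xb)) {
    kmax <- min(length(xa) - i, length(xb) - j) + 1
    matches <- 0
    for (k in seq_len(kmax)) {
      if (xa[i + k - 1] == xb[j + k - 1]) matches <- matches + 1
      score <- 2 * matches - k
      P <- matches / k * 100
      if (is.null(best) || score > best$score ||
          (score == best$score && P > best$P) ||
          (score == best$score && P == best$P && k > best$L)) {
        best <- list(score = score, L = k, matches = matches, P = P)
      }
    }
  }
  best
}

# Two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins, using log-factorial arithmetic.
oracle_fisher_p <- function(a, b, c, d) {
  lfac <- function(x) lgamma(x + 1)
  prob <- function(a2) {
    b2 <- a + b - a2; c2 <- a + c - a2; d2 <- d - a + a2
    if (b2 < 0 || c2 < 0 || d2 < 0) return(0)
    n <- a2 + b2 + c2 + d2
    exp(lfac(a2 + b2) + lfac(c2 + d2) + lfac(a2 + c2) + lfac(b2 + d2) -
          lfac(n) - lfac(a2) - lfac(b2) - lfac(c2) - lfac(d2))
  }
  p_obs <- prob(a)
  amin <- max(0, a - d); amax <- min(a + b, a + c)
  ps <- vapply(amin:amax, prob, numeric(1))
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# Independent counting dN/dS oracle: recursive path enumeration and
# per-codon site counting by direct mutation enumeration.
oracle_dnds_counts <- function(seq_a, seq_b) {
  gc <- Biostrings::GENETIC_CODE
  split3 <- function(s) substring(s, seq(1, nchar(s), 3),
                                  seq(3, nchar(s), 3))
  ca <- split3(seq_a); cb <- split3(seq_b)
  syn_sites <- function(codon) {
    cs <- strsplit(codon, "")[[1]]
    tot <- 0
    for (p in 1:3) {
      n_syn <- 0
      for (alt in setdiff(c("A", "C", "G", "T"), cs[p])) {
        mut <- cs; mut[p] <- alt
        if (gc[[paste(mut, collapse = "")]] == gc[[codon]])
          n_syn <- n_syn + 1
      }
      tot <- tot + n_syn / 3
    }
    tot
  }
  walk <- function(cur, tgt) {
    # returns matrix of (syn, nonsyn) per completed stop-free path
    d <- which(cur != tgt)
    if (length(d) == 0) return(matrix(numeric(0), ncol = 2))
    acc <- list()
    for (p in d) {
      nxt <- cur; nxt[p] <- tgt[p]
      if (gc[[paste(nxt, collapse = "")]] == "*") next
      step_syn <- as.numeric(gc[[paste(cur, collapse = "")]] ==
                               gc[[paste(nxt, collapse = "")]])
      if (length(d) == 1) {
        acc[[length(acc) + 1]] <- c(step_syn, 1 - step_syn)
      } else {
        sub <- walk(nxt, tgt)
        if (nrow(sub))
          acc[[length(acc) + 1]] <-
            cbind(sub[, 1] + step_syn, sub[, 2] + 1 - step_syn)
      }
    }
    if (length(acc) == 0) return(matrix(numeric(0), ncol = 2))
    do.call(rbind, acc)
  }
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    S <- S + (syn_sites(ca[i]) + syn_sites(cb[i])) / 2
    if (ca[i] != cb[i]) {
      paths <- walk(strsplit(ca[i], "")[[1]], strsplit(cb[i], "")[[1]])
      if (nrow(paths) == 0) {
        Nd <- Nd + length(which(strsplit(ca[i], "")[[1]] !=
                                  strsplit(cb[i], "")[[1]]))
      } else {
        Sd <- Sd + mean(paths[, 1])
        Nd <- Nd + mean(paths[, 2])
      }
    }
  }
  list(S = S, N = 3 * length(ca) - S, Sd = Sd, Nd = Nd)
}

# Weir-Cockerham FST via the ANOVA sums-of-squares route (independent of
# the closed-form variance-component formulas in the package).
oracle_fst_anova <- function(g1, g2) {
  a_tot <- 0; d_tot <- 0
  for (s in seq_len(nrow(g1))) {
    x1 <- g1[s, ]; x2 <- g2[s, ]
    n1 <- length(x1); n2 <- length(x2)
    p1 <- sum(x1) / (2 * n1); p2 <- sum(x2) / (2 * n2)
    ntot <- n1 + n2
    pw <- (n1 * p1 + n2 * p2) / ntot
    if (pw <= 0 || pw >= 1) next
    nc <- (ntot - (n1^2 + n2^2) / ntot) / 1
    SSG <- (sum(x1 == 1) + sum(x2 == 1)) / 2
    MSG <- SSG / ntot
    SSI <- sum(2 * (x1 / 2 - p1)^2) + sum(2 * (x2 / 2 - p2)^2)
    MSI <- SSI / (ntot - 2)
    SSP <- 2 * n1 * (p1 - pw)^2 + 2 * n2 * (p2 - pw)^2
    MSP <- SSP / 1
    a <- (MSP - MSI) / (2 * nc)
    bb <- (MSI - MSG) / 2
    cc <- MSG
    a_tot <- a_tot + a
    d_tot <- d_tot + a + bb + cc
  }
  a_tot / d_tot
}

# small VCF writer for reader tests (independent of the package writer)
toy_vcf <- function(path, records, samples) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

expect_close <- function(x, y, tol) {
  testthat::expect_true(abs(x - y) <= tol,
                        label = sprintf("|%.6g - %.6g| <= %.3g", x, y, tol))
}
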