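# Synthetic-data generators with planted ground truth.
#
# Every generator draws from its own seeded RNG stream and restores the
# global RNG state on exit, so simulations are deterministic and do not
# perturb user code.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

BRANCHES <- c("tiger", "cat", "lynx_ancestor", "iberian", "eurasian")

# Labeled synthetic repeat motifs; lengths are typical of each class.
# These stand in for a RepeatMasker library so .out-format annotations can
# be emitted without running RepeatMasker.
te_library <- function() {
  list(
    SINE = list(name = "SINE-Lx1", class = "SINE", family = "tRNA-Lx",
                length = 300L),
    LINE = list(name = "L1-Lx1", class = "LINE", family = "L1",
                length = 2000L),
    LTR = list(name = "LTR-LxERV1", class = "LTR", family = "ERV1-Lx",
               length = 450L),
    `ERV-internal` = list(name = "LxERV1-int", class = "ERV-internal",
                          family = "ERV1-Lx", length = 4500L))
}

random_dna <- function(n, gc = 0.42) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulation configuration
#'
#' Defaults emulate the lynx study conditions: a four-taxon phylogeny
#' (tiger,(cat,(Iberian,Eurasian))) with branch substitution rates
#' proportional to the observed branch-specific substitution densities,
#' TE insertions flanked by 15-25 bp target-site duplications, and two
#' diploid populations (popA = 4 and popB = 7 individuals, the Donana and
#' Andujar sample sizes) with planted per-site theta 1.2e-4 and 2.2e-4,
#' strong differentiation, and forced runs of homozygosity covering 32%
#' and 16% of each individual's genome.
#'
#' @param seed integer seed for the simulation's private RNG stream.
#' @param seq_length genome length in bp.
#' @param branch_rates per-branch substitution probabilities, named by
#'   `tiger`, `cat`, `lynx_ancestor`, `iberian`, `eurasian`.
#' @param ws_preference lambda >= 0; multiplier applied to the
#'   probability of weak-to-strong (A/T -> G/C) substitutions.  1 is
#'   unbiased; the planted W->S fraction is
#'   `lambda*q / (lambda*q + 1 - q)` with `q` the unbiased fraction given
#'   the ancestral base composition.
#' @param te_rate TE insertions per Mb per branch.
#' @param tsd_length_range inclusive range of target-site-duplication
#'   lengths in bp; must lie within [5, 50] (0 disables TSDs).
#' @param pop_sizes individuals per population, named `popA`, `popB`.
#' @param theta planted per-site theta per population.
#' @param shared_frac fraction of the smaller population's segregating
#'   sites that are shared between populations.
#' @param divergence Balding-Nichols differentiation parameter for shared
#'   sites (0 = identical frequencies in both populations).
#' @param roh_fraction per-individual fraction of the genome forced into
#'   homozygous tracts, per population.
#' @param tract_mean mean forced-ROH tract length in bp (exponential).
#' @param het_rate probability that an invariant lynx site is made
#'   heterozygous in one lynx (phylogeny simulation only).
#' @param gc ancestral GC content.
#' @param window_rate_multiplier optional numeric vector, one multiplier
#'   per tiling window of `window_size` bp, scaling all branch
#'   substitution rates inside that window (creates faster-evolving
#'   regions).
#' @param window_size window width used by `window_rate_multiplier`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       seq_length = 1e6,
                       branch_rates = c(tiger = 0.018, cat = 0.009,
                                        lynx_ancestor = 0.009,
                                        iberian = 7e-4, eurasian = 7e-4),
                       ws_preference = 1,
                       te_rate = 2,
                       tsd_length_range = c(15L, 25L),
                       pop_sizes = c(popA = 4L, popB = 7L),
                       theta = c(popA = 1.2e-4, popB = 2.2e-4),
                       shared_frac = 0.67,
                       divergence = 0.2,
                       roh_fraction = c(popA = 0.32, popB = 0.16),
                       tract_mean = 1.5e6,
                       het_rate = 0,
                       gc = 0.42,
                       window_rate_multiplier = NULL,
                       window_size = 1e5) {
  stopifnot(all(BRANCHES %in% names(branch_rates)),
            all(branch_rates >= 0), ws_preference >= 0, te_rate >= 0,
            all(theta >= 0), shared_frac >= 0, shared_frac <= 1,
            divergence >= 0, divergence < 1,
            all(roh_fraction >= 0), all(roh_fraction <= 1))
  if (!(identical(tsd_length_range, c(0L, 0L)) ||
        (tsd_length_range[1] >= 5 && tsd_length_range[2] <= 50 &&
         tsd_length_range[1] <= tsd_length_range[2])))
    stop("tsd_length_range must lie within [5, 50] (or c(0L, 0L))")
  structure(list(seed = as.integer(seed), seq_length = seq_length,
                 branch_rates = branch_rates[BRANCHES],
                 ws_preference = ws_preference, te_rate = te_rate,
                 tsd_length_range = tsd_length_range,
                 pop_sizes = pop_sizes, theta = theta,
                 shared_frac = shared_frac, divergence = divergence,
                 roh_fraction = roh_fraction, tract_mean = tract_mean,
                 het_rate = het_rate, gc = gc,
                 window_rate_multiplier = window_rate_multiplier,
                 window_size = window_size),
            class = "sim_config")
}

# choose substitution positions and derived bases on one branch with
# W->S preference lambda; returns data.frame(position, ancestral, derived)
sample_substitutions <- function(anc_bases, n_sub, lambda,
                                 site_weight_mult = NULL) {
  n <- length(anc_bases)
  n_sub <- min(n_sub, n)
  if (n_sub == 0 || n == 0)
    return(data.frame(position = integer(), ancestral = character(),
                      derived = character(), stringsAsFactors = FALSE))
  is_w <- anc_bases %in% c("A", "T")
  w <- ifelse(is_w, 2 * lambda + 1, 3)
  if (!is.null(site_weight_mult)) w <- w * site_weight_mult
  # weighted sampling without replacement (exponential-key trick)
  keys <- stats::rexp(n) / w
  idx <- order(keys)[seq_len(n_sub)]
  anc <- anc_bases[idx]
  derived <- character(n_sub)
  aw <- anc %in% c("A", "T")
  if (any(aw)) {
    # W ancestor: each strong base w.p. lambda/(2*lambda+1), the other
    # weak base w.p. 1/(2*lambda+1)
    u <- stats::runif(sum(aw)) * (2 * lambda + 1)
    other_w <- ifelse(anc[aw] == "A", "T", "A")
    derived[aw] <- ifelse(u < lambda, "C",
                          ifelse(u < 2 * lambda, "G", other_w))
  }
  if (any(!aw)) {
    alts <- rbind(c("A", "G", "T"), c("A", "C", "T"))  # C row, G row
    pick <- sample.int(3, sum(!aw), replace = TRUE)
    derived[!aw] <- alts[cbind(match(anc[!aw], c("C", "G")), pick)]
  }
  data.frame(position = idx - 1L, ancestral = anc, derived = derived,
             stringsAsFactors = FALSE)
}

#' Simulate a four-taxon phylogeny with planted substitutions and TEs
#'
#' Generates an ancestral genome and derives tiger, cat, Iberian and
#' Eurasian lynx genomes on the (tiger,(cat,(Iberian,Eurasian))) topology
#' by planting branch-specific substitutions (with a tunable
#' weak-to-strong preference) and TE insertions flanked by target-site
#' duplications.  All planted events are recorded.
#'
#' @param config [sim_config()].
#' @return list with `genomes` (named DNA strings), `truth` (lists
#'   `substitutions`, `te_insertions`, `het_sites`), `repeats` (per-genome
#'   repeat annotation data.frames in ancestral+shift coordinates) and
#'   `ancestral` (root sequence).
#' @export
simulate_phylogeny <- function(config) {
  with_seed(config$seed, {
    L <- as.integer(config$seq_length)
    anc <- random_dna(L, config$gc)
    anc_bases <- strsplit(anc, "")[[1]]

    mult <- NULL
    if (!is.null(config$window_rate_multiplier)) {
      widx <- pmin(length(config$window_rate_multiplier),
                   (seq_len(L) - 1) %/% config$window_size + 1)
      mult <- config$window_rate_multiplier[widx]
    }

    available <- rep(TRUE, L)
    subs <- list()
    for (br in BRANCHES) {
      rate <- config$branch_rates[[br]]
      n_sub <- stats::rbinom(1, L, min(1, rate * if (is.null(mult)) 1 else
        mean(mult)))
      pool <- which(available)
      s <- sample_substitutions(anc_bases[pool], min(n_sub, length(pool)),
                                config$ws_preference,
                                if (is.null(mult)) NULL else mult[pool])
      s$position <- pool[s$position + 1L] - 1L
      available[s$position + 1L] <- FALSE
      s$branch <- rep(br, nrow(s))
      subs[[br]] <- s
    }
    subs <- do.call(rbind, subs)
    rownames(subs) <- NULL

    seqs <- list(tiger = anc_bases, cat = anc_bases,
                 iberian = anc_bases, eurasian = anc_bases)
    carriers <- list(tiger = "tiger", cat = "cat",
                     lynx_ancestor = c("iberian", "eurasian"),
                     iberian = "iberian", eurasian = "eurasian")
    for (br in BRANCHES) {
      rows <- subs$branch == br
      for (sp in carriers[[br]])
        seqs[[sp]][subs$position[rows] + 1L] <- subs$derived[rows]
    }

    # heterozygous lynx sites: planted on otherwise untouched positions
    het_sites <- data.frame(species = character(), position = integer(),
                            allele = character(), stringsAsFactors = FALSE)
    if (config$het_rate > 0) {
      for (sp in c("iberian", "eurasian")) {
        n_het <- stats::rbinom(1, L, config$het_rate)
        pool <- which(available)
        pos <- sample(pool, min(n_het, length(pool))) - 1L
        available[pos + 1L] <- FALSE
        alt <- vapply(anc_bases[pos + 1L], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        het_sites <- rbind(het_sites,
                           data.frame(species = sp, position = pos,
                                      allele = alt,
                                      stringsAsFactors = FALSE))
      }
    }

    # TE insertions: positions in ancestral coordinates, non-overlapping
    lib <- te_library()
    te_classes <- c("SINE", "SINE", "LINE", "LTR")  # SINE-rich, as in felids
    te_truth <- list()
    used <- matrix(numeric(0), ncol = 2)
    margin <- 200L
    for (br in BRANCHES) {
      n_te <- stats::rpois(1, config$te_rate * L / 1e6)
      for (k in seq_len(n_te)) {
        el <- lib[[sample(te_classes, 1)]]
        tsd_len <- if (config$tsd_length_range[2] == 0) 0L else
          sample(config$tsd_length_range[1]:config$tsd_length_range[2], 1)
        ok <- FALSE
        for (try in 1:100) {
          pos <- sample.int(L - 2L * margin, 1) + margin
          if (nrow(used) == 0 ||
              all(pos + el$length + 100 < used[, 1] |
                  pos - 100 > used[, 2])) { ok <- TRUE; break }
        }
        if (!ok) stop("te_rate too high: cannot place non-overlapping TEs")
        used <- rbind(used, c(pos, pos + el$length))
        te_truth[[length(te_truth) + 1]] <- data.frame(
          branch = br, position = pos, te_length = el$length,
          tsd_length = tsd_len, repeat_name = el$name,
          repeat_class = el$class, family = el$family,
          strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      }
    }
    te_truth <- if (length(te_truth)) do.call(rbind, te_truth) else
      data.frame(branch = character(), position = integer(),
                 te_length = integer(), tsd_length = integer(),
                 repeat_name = character(), repeat_class = character(),
                 family = character(), strand = character(),
                 stringsAsFactors = FALSE)

    # apply insertions per species, right-to-left so ancestral coordinates
    # stay valid during editing; record carrier coordinates of each TE
    genomes <- list()
    repeats <- list()
    te_truth_rows <- list()
    for (sp in c("tiger", "cat", "iberian", "eurasian")) {
      branches_here <- names(Filter(function(x) sp %in% x, carriers))
      tt <- te_truth[te_truth$branch %in% branches_here, , drop = FALSE]
      tt <- tt[order(tt$position), , drop = FALSE]
      s <- seqs[[sp]]
      seqstr <- paste(s, collapse = "")
      offset <- 0
      rows <- list()
      for (i in seq_len(nrow(tt))) {
        r <- tt[i, ]
        te_seq <- with_te_seq(r$repeat_name, r$te_length, config$seed)
        res <- plant_te_insertion(seqstr, r$position + offset, te_seq,
                                  r$tsd_length,
                                  tsd_range = c(0L, 50L))
        seqstr <- res$sequence
        r$carrier <- sp
        r$carrier_start <- r$position + offset + r$tsd_length
        r$carrier_end <- r$carrier_start + r$te_length
        r$tsd_sequence <- res$tsd_sequence
        offset <- offset + r$te_length + r$tsd_length
        rows[[i]] <- r
      }
      genomes[[sp]] <- seqstr
      if (length(rows)) {
        rr <- do.call(rbind, rows)
        te_truth_rows[[sp]] <- rr
        repeats[[sp]] <- data.frame(
          chrom = sp, start = rr$carrier_start, end = rr$carrier_end,
          strand = rr$strand, repeat_name = rr$repeat_name,
          repeat_class = rr$repeat_class, family = rr$family,
          stringsAsFactors = FALSE)
      } else {
        repeats[[sp]] <- data.frame(chrom = character(), start = numeric(),
                                    end = numeric(), strand = character(),
                                    repeat_name = character(),
                                    repeat_class = character(),
                                    family = character(),
                                    stringsAsFactors = FALSE)
      }
    }

    list(genomes = unlist(genomes),
         truth = list(substitutions = subs,
                      te_insertions = if (length(te_truth_rows))
                        do.call(rbind, te_truth_rows) else te_truth,
                      te_events = te_truth,
                      het_sites = het_sites),
         repeats = repeats,
         ancestral = anc)
  })
}

# deterministic TE sequence for a given repeat name (so the same element
# is identical wherever it inserts)
with_te_seq <- function(name, len, seed) {
  with_seed(utf8ToInt(substr(name, 1, 1)) * 1000L + len %% 997L + seed,
            random_dna(len, gc = 0.45))
}

#' Plant one TE insertion with a target-site duplication
#'
#' The `tsd_length` bp immediately following `position` are duplicated so
#' that they flank the inserted element on both sides, emulating the
#' staggered-cut mechanics of retrotransposon integration.
#'
#' @param sequence DNA string.
#' @param position 0-based insertion point.
#' @param te_sequence element sequence to insert.
#' @param tsd_length length of the duplicated target site (0 = plain
#'   insertion).
#' @param tsd_range allowed TSD length range.
#' @return list: modified `sequence`, `truth` row (`te_start`/`te_end` in
#'   modified coordinates), `tsd_sequence`.
#' @export
plant_te_insertion <- function(sequence, position, te_sequence, tsd_length,
                               tsd_range = c(15L, 25L)) {
  n <- nchar(sequence)
  if (tsd_length != 0 &&
      (tsd_length < tsd_range[1] || tsd_length > tsd_range[2]))
    stop("tsd_length ", tsd_length, " outside configured range [",
         tsd_range[1], ", ", tsd_range[2], "]")
  if (position < 0 || position + tsd_length > n)
    stop("position + tsd_length beyond end of sequence")
  tsd <- if (tsd_length > 0)
    substr(sequence, position + 1, position + tsd_length) else ""
  out <- paste0(substr(sequence, 1, position + tsd_length),
                te_sequence, tsd,
                substr(sequence, position + tsd_length + 1, n))
  list(sequence = out,
       truth = data.frame(position = position,
                          te_start = position + tsd_length,
                          te_end = position + tsd_length +
                            nchar(te_sequence),
                          tsd_length = tsd_length,
                          stringsAsFactors = FALSE),
       tsd_sequence = tsd)
}

# ancestral -> species coordinate shift from that species' insertions
coord_shift <- function(te_rows, pos) {
  if (nrow(te_rows) == 0) return(rep(0, length(pos)))
  vapply(pos, function(p)
    sum((te_rows$te_length + te_rows$tsd_length)[te_rows$position < p]),
    numeric(1))
}

#' Derive the pairwise alignment-block table implied by planted truth
#'
#' Blocks are the maximal aligned segments between the planted insertions
#' of either genome.  At a carrier-specific insertion the two flanking
#' blocks overlap by the TSD length on the partner side (the duplicated
#' target site aligns twice), the geometry a local aligner produces at a
#' genuine TSD-flanked insertion.
#'
#' @param sim result of [simulate_phylogeny()].
#' @param carrier,partner species names.
#' @return alignment-block data.frame (query = carrier, target = partner).
#' @export
simulate_alignment_blocks <- function(sim, carrier, partner) {
  ev <- sim$truth$te_events
  carriers <- list(tiger = "tiger", cat = "cat",
                   lynx_ancestor = c("iberian", "eurasian"),
                   iberian = "iberian", eurasian = "eurasian")
  in_sp <- function(branch, sp) sp %in% carriers[[branch]]
  keep <- vapply(ev$branch, function(b)
    in_sp(b, carrier) || in_sp(b, partner), logical(1))
  ev <- ev[keep, , drop = FALSE]
  ev <- ev[order(ev$position), , drop = FALSE]
  L <- nchar(sim$ancestral)
  ca <- ev[vapply(ev$branch, in_sp, logical(1), sp = carrier), ,
           drop = FALSE]
  pa <- ev[vapply(ev$branch, in_sp, logical(1), sp = partner), ,
           drop = FALSE]

  bounds <- sort(unique(c(0, ev$position, L)))
  blocks <- list()
  for (i in seq_len(length(bounds) - 1)) {
    a0 <- bounds[i]; a1 <- bounds[i + 1]
    q0 <- a0 + coord_shift(ca, a0 + 0.5)
    q1 <- a1 + coord_shift(ca, a1 - 0.5)
    t0 <- a0 + coord_shift(pa, a0 + 0.5)
    t1 <- a1 + coord_shift(pa, a1 - 0.5)
    # the target site duplicated at the next insertion boundary aligns
    # once more at the end of this segment
    ev_right <- ev[ev$position == a1, , drop = FALSE]
    if (nrow(ev_right) == 1 && ev_right$tsd_length > 0) {
      q1 <- q1 + ev_right$tsd_length
      t1 <- t1 + ev_right$tsd_length
    }
    if (q1 > q0 && t1 > t0)
      blocks[[length(blocks) + 1]] <- data.frame(
        query = carrier, qstart = q0, qend = q1,
        target = partner, tstart = t0, tend = t1, strand = "+",
        aligned_sites = min(q1 - q0, t1 - t0), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

# site-frequency-spectrum draw: derived count i in 1..(n-1) w.p. (1/i)/a_n
rsfs <- function(n_draw, n_chrom) {
  i <- seq_len(n_chrom - 1)
  sample(i, n_draw, replace = TRUE, prob = 1 / i)
}

harmonic <- function(k) sum(1 / seq_len(k))

#' Simulate diploid genotype panels for two populations
#'
#' Segregating sites are planted at each population's per-site theta with
#' neutral site-frequency-spectrum allele counts (so Watterson's theta
#' and pi are both recovered in expectation).  A configurable fraction of
#' sites is shared between the populations, with Balding-Nichols
#' differentiation around the shared frequency; remaining sites are
#' private.  Runs of homozygosity are forced by overwriting sampled
#' tracts with homozygous genotypes, giving exact planted truth.
#'
#' @param config [sim_config()].
#' @return list: `genotypes` ([genotype_matrix()]), `truth` (data.frame of
#'   planted ROH tracts), `site_origin` (shared/private labels).
#' @export
simulate_population_genotypes <- function(config) {
  if (any(config$pop_sizes < 2))
    stop("each population needs >= 2 individuals for diversity estimators")
  with_seed(config$seed + 1L, {
    L <- config$seq_length
    nA <- 2L * config$pop_sizes[["popA"]]
    nB <- 2L * config$pop_sizes[["popB"]]
    SA <- stats::rpois(1, config$theta[["popA"]] * L * harmonic(nA - 1))
    SB <- stats::rpois(1, config$theta[["popB"]] * L * harmonic(nB - 1))
    n_sh <- round(config$shared_frac * min(SA, SB))
    n_tot <- SA + SB - n_sh
    if (n_tot > L) stop("theta too high for seq_length")
    pos <- sort(sample.int(L, n_tot)) - 1L
    kind <- sample(c(rep("shared", n_sh), rep("privA", SA - n_sh),
                     rep("privB", SB - n_sh)))

    countA <- countB <- integer(n_tot)
    sh <- kind == "shared"
    if (any(sh)) {
      p0 <- rsfs(sum(sh), nA + nB) / (nA + nB)
      draw_cond <- function(n_chrom, p) {
        # binomial count conditioned on segregating
        k <- stats::rbinom(length(p), n_chrom, p)
        bad <- which(k == 0 | k == n_chrom)
        while (length(bad)) {
          k[bad] <- stats::rbinom(length(bad), n_chrom, p[bad])
          bad <- bad[k[bad] == 0 | k[bad] == n_chrom]
        }
        k
      }
      Fst <- config$divergence
      pA <- if (Fst == 0) p0 else
        stats::rbeta(sum(sh), p0 * (1 - Fst) / Fst,
                     (1 - p0) * (1 - Fst) / Fst)
      pB <- if (Fst == 0) p0 else
        stats::rbeta(sum(sh), p0 * (1 - Fst) / Fst,
                     (1 - p0) * (1 - Fst) / Fst)
      pA <- pmin(pmax(pA, 1e-6), 1 - 1e-6)
      pB <- pmin(pmax(pB, 1e-6), 1 - 1e-6)
      countA[sh] <- draw_cond(nA, pA)
      countB[sh] <- draw_cond(nB, pB)
    }
    countA[kind == "privA"] <- rsfs(sum(kind == "privA"), nA)
    countB[kind == "privB"] <- rsfs(sum(kind == "privB"), nB)

    spread <- function(counts, n_chrom) {
      t(vapply(counts, function(k) {
        hap <- integer(n_chrom)
        if (k > 0) hap[sample.int(n_chrom, k)] <- 1L
        hap
      }, integer(n_chrom)))
    }
    hapA <- spread(countA, nA)
    hapB <- spread(countB, nB)
    to_geno <- function(hap) {
      n_ind <- ncol(hap) / 2
      matrix(unlist(lapply(seq_len(n_ind), function(j)
        hap[, 2 * j - 1] + hap[, 2 * j])), nrow = nrow(hap))
    }
    geno <- cbind(to_geno(hapA), to_geno(hapB))
    inds <- c(sprintf("A%02d", seq_len(config$pop_sizes[["popA"]])),
              sprintf("B%02d", seq_len(config$pop_sizes[["popB"]])))
    colnames(geno) <- inds
    pops <- stats::setNames(rep(c("popA", "popB"), config$pop_sizes), inds)

    # force ROH tracts
    tracts <- list()
    freq <- (countA + countB) / (nA + nB)
    for (ind in inds) {
      frac <- config$roh_fraction[[pops[[ind]]]]
      covered <- 0
      guard <- 0
      while (frac * L - covered >= 5e4 && guard < 10000) {
        guard <- guard + 1
        # exponential tract lengths, truncated to the remaining target so
        # realized coverage tracks roh_fraction even on short genomes
        len <- min(max(5e4, stats::rexp(1, 1 / config$tract_mean)),
                   frac * L - covered, L - 1)
        s <- sample.int(max(1, L - len), 1) - 1
        ov <- FALSE
        for (tr in tracts)
          if (tr$individual == ind && s < tr$end && s + len > tr$start) {
            ov <- TRUE; break
          }
        if (ov) next
        tracts[[length(tracts) + 1]] <-
          list(individual = ind, start = s, end = s + len)
        covered <- covered + len
        inside <- which(pos >= s & pos < s + len)
        if (length(inside)) {
          hom <- ifelse(stats::runif(length(inside)) < freq[inside], 2L, 0L)
          geno[inside, ind] <- hom
        }
      }
    }
    truth <- if (length(tracts))
      data.frame(individual = vapply(tracts, `[[`, "", "individual"),
                 chrom = "chr1",
                 start = vapply(tracts, `[[`, 0, "start"),
                 end = vapply(tracts, `[[`, 0, "end"),
                 stringsAsFactors = FALSE)
    else data.frame(individual = character(), chrom = character(),
                    start = numeric(), end = numeric(),
                    stringsAsFactors = FALSE)

    # drop sites monomorphic across the full panel (shared sites can fix
    # after ROH forcing)
    seg <- rowSums(geno, na.rm = TRUE) > 0 &
      rowSums(geno, na.rm = TRUE) < 2 * ncol(geno)
    sites <- data.frame(chrom = "chr1", start = pos, end = pos + 1,
                        stringsAsFactors = FALSE)
    gm <- genotype_matrix(sites[seg, , drop = FALSE],
                          geno[seg, , drop = FALSE], pops,
                          callable_sites = L)
    list(genotypes = gm, truth = truth, site_origin = kind[seg])
  })
}

#' Simulate 100-kb-window summaries with coupled fixation and diversity
#'
#' Emulates the faster-evolving-region signature: each window carries an
#' ancestral diversity level; the fraction of that diversity a species
#' has lost is converted into extra fixed substitutions, so windows where
#' one species lost heterozygosity show an elevated substitution rate in
#' that species (coupling > 0).  With coupling = 0 rates and
#' heterozygosities are independent.
#'
#' @param n_windows number of windows.
#' @param mu_subs expected substitutions per window per species.
#' @param coupling strength of the fixation/heterozygosity-loss coupling.
#' @param seed RNG seed.
#' @return data.frame: `window`, `subs_a`, `subs_b`, `het_a`, `het_b`.
#' @export
simulate_fr_windows <- function(n_windows, mu_subs = 50, coupling = 0,
                                seed = 1L) {
  with_seed(seed, {
    h0 <- stats::rlnorm(n_windows, meanlog = log(1e-3), sdlog = 0.4)
    ua <- stats::rbeta(n_windows, 2, 2)  # fraction of diversity retained
    ub <- stats::rbeta(n_windows, 2, 2)
    het_a <- h0 * ua
    het_b <- h0 * ub
    subs_a <- stats::rpois(n_windows, mu_subs * (1 + coupling * (1 - ua)))
    subs_b <- stats::rpois(n_windows, mu_subs * (1 + coupling * (1 - ub)))
    data.frame(window = seq_len(n_windows), subs_a = subs_a,
               subs_b = subs_b, het_a = het_a, het_b = het_b)
  })
}

#' Simulate a rearranged scaffold's alignment blocks
#'
#' Builds a query scaffold composed of collinear segments on a reference
#' chromosome and plants up to five rearrangement events (inversions,
#' intra- and inter-chromosomal moves).  Each segment is emitted as
#' several same-strand blocks separated by small gaps so that chaining
#' must merge them before events are visible.
#'
#' @param kinds character vector of planted events, in query order; each
#'   of `"inversion"`, `"intra_chromosomal"`, `"inter_chromosomal"`.
#' @param segment_len length of each aligned segment (bp).
#' @param seed RNG seed.
#' @return list: `blocks` (alignment-block data.frame), `truth` (kinds in
#'   query order).
#' @export
simulate_rearranged_scaffold <- function(kinds, segment_len = 4e4,
                                         seed = 1L) {
  stopifnot(length(kinds) <= 5,
            all(kinds %in% c("inversion", "intra_chromosomal",
                             "inter_chromosomal")))
  with_seed(seed, {
    # one baseline segment, then per event one segment realizing it, then
    # a closing baseline segment after each event
    segs <- list(list(target = "chrT1", strand = "+"))
    tpos <- c(chrT1 = 0, chrT2 = 0)
    for (k in kinds) {
      if (k == "inversion")
        segs[[length(segs) + 1]] <- list(target = "chrT1", strand = "-")
      else if (k == "inter_chromosomal")
        segs[[length(segs) + 1]] <- list(target = "chrT2", strand = "+")
      else  # intra: a segment whose target coordinates jump backwards
        segs[[length(segs) + 1]] <- list(target = "chrT1", strand = "+",
                                         backjump = TRUE)
      segs[[length(segs) + 1]] <- list(target = "chrT1", strand = "+")
    }
    blocks <- list()
    q <- 0
    t_main <- 5e6  # forward position on chrT1
    t_alt <- 1e6   # position on chrT2
    t_back <- 1e6  # backward-jump region on chrT1
    n_sub <- 3L
    sub_len <- floor(segment_len / n_sub)
    segment_len <- sub_len * n_sub  # keep all coordinates integral
    for (sg in segs) {
      if (sg$target == "chrT2") {
        t0 <- t_alt; t_alt <- t_alt + segment_len + 1e5
      } else if (isTRUE(sg$backjump)) {
        t0 <- t_back; t_back <- t_back + segment_len + 1e5
      } else {
        t0 <- t_main; t_main <- t_main + segment_len + 1e5
      }
      for (j in seq_len(n_sub)) {
        qs <- q + (j - 1) * sub_len
        offs <- (j - 1) * sub_len
        ts <- if (sg$strand == "+") t0 + offs else
          t0 + segment_len - offs - sub_len
        blocks[[length(blocks) + 1]] <- data.frame(
          query = "scaf1", qstart = qs, qend = qs + sub_len - 500,
          target = sg$target, tstart = ts, tend = ts + sub_len - 500,
          strand = sg$strand, aligned_sites = sub_len - 500,
          stringsAsFactors = FALSE)
      }
      q <- q + segment_len + 2000
    }
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    list(blocks = out, truth = kinds)
  })
}

#' Simulate a codon alignment with localized misalignment noise
#'
#' Taxa diverge from a common gapless codon sequence by synonymous and
#' nonsynonymous point substitutions (never creating stops).  Optionally,
#' short windows in one taxon are shuffled at the codon level, emulating
#' locally misaligned regions that carry spurious amino-acid
#' replacements.
#'
#' @param n_codons alignment length in codons.
#' @param taxa taxon names.
#' @param sub_rate per-site nucleotide mutation proposal probability per
#'   taxon.
#' @param omega acceptance probability for amino-acid-changing mutations
#'   (synonymous mutations are always accepted); the default emulates a
#'   purifying-selection background with dN/dS well below 1.
#' @param misalign_windows number of shuffled windows to plant.
#' @param misalign_len window length in codons.
#' @param seed RNG seed.
#' @return list: `alignment` (named character vector), `truth`
#'   (data.frame of misaligned codon-column ranges, 0-based).
#' @export
simulate_codon_alignment <- function(n_codons, taxa = c("t1", "t2", "t3",
                                                        "t4"),
                                     sub_rate = 0.02, omega = 0.2,
                                     misalign_windows = 0,
                                     misalign_len = 5, seed = 1L) {
  with_seed(seed, {
    codons <- setdiff(names(Biostrings::GENETIC_CODE),
                      names(which(Biostrings::GENETIC_CODE == "*")))
    root <- sample(codons, n_codons, replace = TRUE)
    aln <- list()
    for (tx in taxa) {
      s <- root
      n_mut <- stats::rbinom(1, n_codons * 3, sub_rate)
      for (m in seq_len(n_mut)) {
        for (try in 1:20) {
          i <- sample.int(n_codons, 1)
          p <- sample.int(3, 1)
          cd <- strsplit(s[i], "")[[1]]
          cd[p] <- sample(setdiff(c("A", "C", "G", "T"), cd[p]), 1)
          cand <- paste(cd, collapse = "")
          if (Biostrings::GENETIC_CODE[[cand]] == "*") next
          if (Biostrings::GENETIC_CODE[[cand]] !=
              Biostrings::GENETIC_CODE[[s[i]]] &&
              stats::runif(1) > omega) next
          s[i] <- cand
          break
        }
      }
      aln[[tx]] <- s
    }
    truth <- data.frame(start = integer(), end = integer(),
                        stringsAsFactors = FALSE)
    if (misalign_windows > 0) {
      tx <- taxa[length(taxa)]
      for (w in seq_len(misalign_windows)) {
        s0 <- sample.int(n_codons - misalign_len, 1)
        idx <- s0:(s0 + misalign_len - 1)
        aln[[tx]][idx] <- sample(aln[[tx]][idx])
        truth <- rbind(truth, data.frame(start = s0 - 1L,
                                         end = s0 - 1L + misalign_len))
      }
    }
    list(alignment = vapply(aln, paste, "", collapse = ""), truth = truth)
  })
}

#' Write a genotype matrix as a minimal VCF
#'
#' @param gm [genotype_matrix()].
#' @param path output file.
#' @param ref,alt reference and alternate alleles (recycled).
#' @export
write_vcf <- function(gm, path, ref = "A", alt = "G") {
  n <- nrow(gm$sites)
  gt_str <- apply(gm$genotypes, c(1, 2), function(g)
    if (is.na(g)) "./." else c("0/0", "0/1", "1/1")[g + 1])
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", unique(gm$sites$chrom), ">"),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(gm$genotypes)),
                 collapse = "\t"))
  body <- vapply(seq_len(n), function(i)
    paste(c(gm$sites$chrom[i], gm$sites$start[i] + 1, ".",
            rep_len(ref, n)[i], rep_len(alt, n)[i], ".", "PASS", ".",
            "GT", gt_str[i, ]), collapse = "\t"), character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
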