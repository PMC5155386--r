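# Species-specific TE insertion calling from alignment gaps, with
# target-site-duplication validation, ERV reconstruction from LTR pairs,
# branch assignment and gene-context orientation analysis.

#' Find strongly supported gaps between consecutive alignment blocks
#'
#' A gap is carrier-only sequence between two consecutive blocks of one
#' (query, target) chain: the blocks are adjacent (or TSD-overlapping) on
#' the partner side but separated on the carrier side.  TSD search
#' windows around both gap boundaries are extracted from the carrier
#' genome.
#'
#' @param blocks alignment-block data.frame (query = carrier genome).
#' @param carrier_seqs named character vector of carrier sequences.
#' @param min_len,max_len carrier-gap length bounds (defaults 50 bp and
#'   20 kb exclude micro-indels and assembly gaps).
#' @param max_partner_gap maximum partner-side separation for the gap to
#'   count as carrier-only; negative partner gaps (the duplicated target
#'   site aligning on both flanks) are allowed down to -100 bp.
#' @param upstream,inside TSD window geometry: `upstream` bp outside and
#'   `inside` bp inside each gap boundary (-25/+15 at the start,
#'   -15/+25 at the end).
#' @return data.frame of gap records with flank windows.
#' @export
find_gaps <- function(blocks, carrier_seqs, min_len = 50, max_len = 2e4,
                      max_partner_gap = 10, upstream = 25L, inside = 15L) {
  validate_alignment_blocks(blocks)
  out <- list()
  for (key in unique(paste(blocks$query, blocks$target, blocks$strand))) {
    b <- blocks[paste(blocks$query, blocks$target, blocks$strand) == key, ,
                drop = FALSE]
    b <- b[order(b$qstart), , drop = FALSE]
    if (nrow(b) < 2) next
    # TSD-sized overlaps arise where the partner genome carries the
    # insertion (the duplicated target site aligns on both flanks);
    # larger overlaps violate the chain invariant
    if (any(b$qstart[-1] < b$qend[-nrow(b)] - 100))
      stop("overlapping blocks on carrier within one chain: ", key)
    for (i in seq_len(nrow(b) - 1)) {
      cgap <- b$qstart[i + 1] - b$qend[i]
      pgap <- if (b$strand[i] == "+") b$tstart[i + 1] - b$tend[i]
              else b$tstart[i] - b$tend[i + 1]
      if (cgap < min_len || cgap > max_len) next
      if (pgap > max_partner_gap || pgap < -100) next
      gs <- b$qend[i]
      ge <- b$qstart[i + 1]
      seq <- carrier_seqs[[b$query[i]]]
      fl_l <- substr(seq, max(1, gs - upstream + 1), gs + inside)
      fl_r <- substr(seq, max(1, ge - inside + 1), ge + upstream)
      out[[length(out) + 1]] <- data.frame(
        carrier = b$query[i], gap_start = gs, gap_end = ge,
        partner = b$target[i],
        partner_pos = if (b$strand[i] == "+") b$tend[i] else b$tstart[i],
        strand = b$strand[i],
        flank_left = fl_l, flank_right = fl_r,
        flank_ok = (gs - upstream >= 0) &&
          (ge + upstream <= nchar(seq)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(carrier = character(), gap_start = numeric(),
                      gap_end = numeric(), partner = character(),
                      partner_pos = numeric(), strand = character(),
                      flank_left = character(), flank_right = character(),
                      flank_ok = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Best ungapped local alignment between two short windows
#'
#' Scans every pair of equal-length substrings (all diagonals, all
#' segments) scoring match +1 / mismatch -1, and returns the best segment
#' under the ordering: maximal score, then maximal percent identity, then
#' maximal length, then leftmost start.
#'
#' @param a,b DNA strings (typically the two 40-bp TSD windows).
#' @return list: `L` (alignment length), `matches`, `P` (percent
#'   identity, unrounded), `score` (matches - mismatches), `start_a`,
#'   `start_b` (0-based), or `NULL` if either window is empty.
#' @export
tsd_align <- function(a, b) {
  xa <- strsplit(toupper(a), "")[[1]]
  xb <- strsplit(toupper(b), "")[[1]]
  na <- length(xa); nb <- length(xb)
  if (na == 0 || nb == 0) return(NULL)
  best <- NULL
  for (d in (-(na - 1)):(nb - 1)) {
    ia <- max(1, 1 - d); ib <- ia + d
    k <- min(na - ia, nb - ib) + 1
    if (k <= 0) next
    m <- ifelse(xa[ia:(ia + k - 1)] == xb[ib:(ib + k - 1)], 1, -1)
    cs <- c(0, cumsum(m))
    # S[i,j] = score of segment i..j ; enumerate via outer difference
    S <- outer(cs[-1], cs[-(k + 1)], "-")   # rows j, cols i
    valid <- row(S) >= col(S)
    len <- row(S) - col(S) + 1
    sc <- S[valid]; ln <- len[valid]
    mt <- (sc + ln) / 2
    pid <- mt / ln
    o <- order(-sc, -pid, -ln, col(S)[valid], row(S)[valid])[1]
    cand <- list(score = sc[o], L = ln[o], matches = mt[o],
                 P = pid[o] * 100,
                 start_a = ia + col(S)[valid][o] - 2,
                 start_b = ib + col(S)[valid][o] - 2)
    if (is.null(best) ||
        cand$score > best$score ||
        (cand$score == best$score && cand$P > best$P) ||
        (cand$score == best$score && cand$P == best$P &&
         cand$L > best$L))
      best <- cand
  }
  best
}

#' Detect a target-site duplication at the boundaries of a gap
#'
#' Compares the -25/+15 bp window around the gap start with the -15/+25
#' bp window around the gap end by exhaustive ungapped local alignment
#' and applies the L*P/100 > 6 rule, where L is the alignment length and
#' P the percent identity (reported to one decimal, as an aligner
#' prints it).
#'
#' @param gap one row of [find_gaps()] output (or a list with
#'   `flank_left`, `flank_right`, `flank_ok`).
#' @param min_score detection threshold; the score must be strictly
#'   greater.
#' @return list `(L, P, score)` or `NULL` (no TSD: window truncated by a
#'   contig edge, empty, or score at/below threshold).
#' @export
detect_tsd <- function(gap, min_score = 6) {
  if (!is.null(gap$flank_ok) && !isTRUE(gap$flank_ok[1])) return(NULL)
  al <- tsd_align(gap$flank_left[1], gap$flank_right[1])
  if (is.null(al)) return(NULL)
  P <- round(al$P, 1)
  score <- al$L * P / 100
  if (score > min_score) list(L = al$L, P = P, score = score) else NULL
}

#' Call a species-specific TE insertion for one gap
#'
#' A call is made iff a single repeat covers at least 95% of the gap,
#' at least 99% of that repeat lies within the gap, and a target-site
#' duplication is detected at the gap boundaries.  When several repeats
#' qualify the one with the highest gap coverage wins (ties: longest,
#' then leftmost).
#'
#' @param gap one row of [find_gaps()] output.
#' @param repeats repeat annotations in carrier coordinates
#'   ([read_repeatmasker_out()] layout).
#' @param min_coverage,min_within the two coverage thresholds.
#' @param min_tsd_score TSD score threshold (strict).
#' @return one-row data.frame or `NULL` when no repeat qualifies.
#' @export
call_te_insertion <- function(gap, repeats, min_coverage = 0.95,
                              min_within = 0.99, min_tsd_score = 6) {
  r <- repeats[repeats$chrom == gap$carrier[1], , drop = FALSE]
  if (nrow(r) == 0) return(NULL)
  ov <- overlap_bp(gap$carrier[1], gap$gap_start[1], gap$gap_end[1], r)
  gap_len <- gap$gap_end[1] - gap$gap_start[1]
  cov <- ov / gap_len
  within <- ov / (r$end - r$start)
  ok <- which(cov >= min_coverage & within >= min_within)
  if (length(ok) == 0) return(NULL)
  o <- ok[order(-cov[ok], -(r$end - r$start)[ok], r$start[ok])[1]]
  tsd <- detect_tsd(gap, min_score = min_tsd_score)
  if (is.null(tsd)) return(NULL)
  data.frame(carrier = gap$carrier[1], gap_start = gap$gap_start[1],
             gap_end = gap$gap_end[1], partner = gap$partner[1],
             partner_pos = gap$partner_pos[1],
             repeat_name = r$repeat_name[o],
             repeat_class = r$repeat_class[o], strand = r$strand[o],
             te_coverage_of_gap = cov[o], te_within_gap = within[o],
             tsd_L = tsd$L, tsd_P = tsd$P, tsd_score = tsd$score,
             stringsAsFactors = FALSE)
}

#' Call TE insertions for a whole gap table
#'
#' @param gaps [find_gaps()] output.
#' @param repeats repeat annotations in carrier coordinates.
#' @param ... thresholds passed to [call_te_insertion()].
#' @return data.frame of calls (possibly 0 rows).
#' @export
call_te_insertions <- function(gaps, repeats, ...) {
  calls <- lapply(seq_len(nrow(gaps)),
                  function(i) call_te_insertion(gaps[i, ], repeats, ...))
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (length(calls) == 0)
    return(data.frame(carrier = character(), gap_start = numeric(),
                      gap_end = numeric(), partner = character(),
                      partner_pos = numeric(), repeat_name = character(),
                      repeat_class = character(), strand = character(),
                      te_coverage_of_gap = numeric(),
                      te_within_gap = numeric(), tsd_L = integer(),
                      tsd_P = numeric(), tsd_score = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, calls)
  rownames(res) <- NULL
  res
}

#' Assign TE insertions to branches from two pairwise comparisons
#'
#' Insertions called in the lynx-vs-cat comparison only are
#' lynx-specific; those in the tiger-vs-cat comparison only are
#' tiger-specific; calls present in both comparisons (matched by their
#' cat-coordinate anchor) are counted once as shared.
#'
#' @param calls_lynx_vs_cat,calls_tiger_vs_cat call tables from
#'   [call_te_insertions()], both anchored on cat coordinates
#'   (`partner_pos`).
#' @param tol anchor-matching tolerance in bp.
#' @return list: `calls` (with a `branch` column), `counts` (branch x
#'   TE-class table collapsing LTR/ERV-internal onto ERV).
#' @export
assign_branches <- function(calls_lynx_vs_cat, calls_tiger_vs_cat,
                            tol = 100) {
  lc <- calls_lynx_vs_cat
  tc <- calls_tiger_vs_cat
  match_anchor <- function(pos, other) {
    if (nrow(other) == 0) return(rep(FALSE, length(pos)))
    vapply(pos, function(p) any(abs(other$partner_pos - p) <= tol),
           logical(1))
  }
  shared_l <- match_anchor(lc$partner_pos, tc)
  shared_t <- match_anchor(tc$partner_pos, lc)
  lc$branch <- ifelse(shared_l, "shared", "lynx")
  tc$branch <- ifelse(shared_t, "shared", "tiger")
  # a shared insertion appears in both tables; count it once
  keep_t <- !(shared_t)
  all_calls <- rbind(lc, tc[keep_t, , drop = FALSE])
  cls <- ifelse(all_calls$repeat_class %in% c("LTR", "ERV-internal"),
                "ERV", all_calls$repeat_class)
  counts <- table(branch = all_calls$branch, class = cls)
  list(calls = all_calls, counts = counts)
}

#' Annotate gene context and sense-orientation of TE insertions
#'
#' An insertion is genic iff its interval overlaps a gene body by at
#' least 1 bp; a genic insertion is in sense orientation iff its strand
#' equals the gene's strand.  Unstranded insertions in genes are counted
#' genic but excluded from the sense-fraction denominator.
#'
#' @param calls call table with `carrier`, `gap_start`, `gap_end`,
#'   `strand`.
#' @param genes gene BED data.frame with `chrom`, `start`, `end`,
#'   `strand`.
#' @return list: `calls` (with `gene_context` column), `summary`
#'   (`n_sense`, `n_genic`, `fraction` to 2 decimals).
#' @export
gene_context <- function(calls, genes) {
  ctx <- character(nrow(calls))
  n_unstranded <- 0L
  for (i in seq_len(nrow(calls))) {
    ov <- overlap_bp(calls$carrier[i], calls$gap_start[i],
                     calls$gap_end[i], genes)
    hit <- which(ov > 0)
    if (length(hit) == 0) {
      ctx[i] <- "intergenic"
    } else if (calls$strand[i] == "*") {
      ctx[i] <- "genic_unstranded"
      n_unstranded <- n_unstranded + 1L
    } else {
      g <- genes$strand[hit[1]]
      ctx[i] <- if (calls$strand[i] == g) "genic_sense"
                else "genic_antisense"
    }
  }
  calls$gene_context <- ctx
  n_genic <- sum(ctx != "intergenic")
  n_sense <- sum(ctx == "genic_sense")
  denom <- n_genic - n_unstranded
  list(calls = calls,
       summary = list(n_sense = n_sense, n_genic = n_genic,
                      n_unstranded = n_unstranded,
                      fraction = if (denom > 0)
                        round(n_sense / denom, 2) else NA_real_))
}

#' Fisher exact test for sense-orientation enrichment
#'
#' Two-sided exact test comparing the observed sense/genic counts with a
#' background given as counts.
#'
#' @param n_sense,n_genic observed sense count and genic total.
#' @param bg_sense,bg_genic background counts.
#' @return two-sided p value.
#' @export
sense_enrichment_test <- function(n_sense, n_genic, bg_sense, bg_genic) {
  stopifnot(n_sense >= 0, n_genic >= n_sense,
            bg_sense >= 0, bg_genic >= bg_sense)
  tab <- matrix(c(n_sense, n_genic - n_sense,
                  bg_sense, bg_genic - bg_sense), nrow = 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero-margin table; p = 1")
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Reconstruct full ERVs from LTR pairs
#'
#' Pairs long terminal repeats that are of the same type (identical
#' repeat name), on the same strand and chromosome, whose full span is
#' within `max_span`, and for which at least `min_internal` of the
#' LTR-enclosed sequence is covered by ERV-internal fragments of the
#' same family and orientation.  Overlapping candidates are resolved by
#' keeping the one with the highest internal coverage (ties: longest,
#' then leftmost).
#'
#' @param repeats repeat annotations including LTR and ERV-internal
#'   classes.
#' @param max_span maximal full proviral span in bp.
#' @param min_internal minimal fraction of the enclosed sequence covered
#'   by same-family, same-strand ERV-internal fragments.
#' @return data.frame of accepted full-ERV candidates.
#' @export
reconstruct_full_ervs <- function(repeats, max_span = 15000,
                                  min_internal = 0.5) {
  ltr <- repeats[repeats$repeat_class == "LTR", , drop = FALSE]
  int <- repeats[repeats$repeat_class == "ERV-internal", , drop = FALSE]
  cands <- list()
  if (nrow(ltr) >= 2) {
    for (key in unique(paste(ltr$chrom, ltr$repeat_name, ltr$strand))) {
      g <- ltr[paste(ltr$chrom, ltr$repeat_name, ltr$strand) == key, ,
               drop = FALSE]
      g <- g[order(g$start), , drop = FALSE]
      if (nrow(g) < 2) next
      for (i in seq_len(nrow(g) - 1)) for (j in (i + 1):nrow(g)) {
        span <- g$end[j] - g$start[i]
        enc0 <- g$end[i]; enc1 <- g$start[j]
        if (span > max_span || enc1 <= enc0) next
        fam <- int[int$chrom == g$chrom[i] &
                     int$family == g$family[i] &
                     int$strand == g$strand[i], , drop = FALSE]
        covered <- 0
        if (nrow(fam)) {
          lo <- pmax(enc0, fam$start); hi <- pmin(enc1, fam$end)
          seg <- data.frame(lo = lo[hi > lo], hi = hi[hi > lo])
          if (nrow(seg)) {
            seg <- seg[order(seg$lo), , drop = FALSE]
            cur_lo <- seg$lo[1]; cur_hi <- seg$hi[1]
            for (k in seq_len(nrow(seg))[-1]) {
              if (seg$lo[k] <= cur_hi) cur_hi <- max(cur_hi, seg$hi[k])
              else { covered <- covered + cur_hi - cur_lo
                     cur_lo <- seg$lo[k]; cur_hi <- seg$hi[k] }
            }
            covered <- covered + cur_hi - cur_lo
          }
        }
        icov <- covered / (enc1 - enc0)
        if (icov >= min_internal)
          cands[[length(cands) + 1]] <- data.frame(
            chrom = g$chrom[i], start = g$start[i], end = g$end[j],
            strand = g$strand[i], repeat_name = g$repeat_name[i],
            family = g$family[i], enclosed_start = enc0,
            enclosed_end = enc1, internal_coverage = icov,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cands) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      repeat_name = character(), family = character(),
                      enclosed_start = numeric(), enclosed_end = numeric(),
                      internal_coverage = numeric(),
                      stringsAsFactors = FALSE))
  cand <- do.call(rbind, cands)
  cand <- cand[order(-cand$internal_coverage,
                     -(cand$end - cand$start), cand$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) for (j in (i + 1):nrow(cand)) {
      if (keep[j] && cand$chrom[j] == cand$chrom[i] &&
          cand$enclosed_start[j] < cand$enclosed_end[i] &&
          cand$enclosed_end[j] > cand$enclosed_start[i])
        keep[j] <- FALSE
    }
  }
  res <- cand[keep, , drop = FALSE]
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
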