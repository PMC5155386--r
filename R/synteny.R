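# Chaining of pairwise alignment blocks and detection of inversions and
# inter/intra-chromosomal rearrangements, polarized with an outgroup.

#' Chain alignment blocks
#'
#' Per (query, target) pair, blocks are sorted by target coordinate and
#' consecutive same-strand blocks are merged greedily when both the
#' target-side and the query-side gaps are below `merge_gap`.  Only
#' chains spanning at least `min_span` on the target with at least
#' `min_aligned` of the spanned sites aligned are kept.
#'
#' @param blocks alignment-block data.frame (best-hit filtered,
#'   length > 1000 bp).
#' @param merge_gap maximal gap (bp) between merged neighbors.
#' @param min_span minimal target span of an emitted chain.
#' @param min_aligned minimal aligned fraction of the target span.
#' @return data.frame of chains: `query`, `qstart`, `qend`, `target`,
#'   `tstart`, `tend`, `strand`, `aligned_sites`, `n_blocks`,
#'   `aligned_fraction`.
#' @export
chain_blocks <- function(blocks, merge_gap = 2e4, min_span = 1.5e4,
                         min_aligned = 0.40) {
  validate_alignment_blocks(blocks)
  chains <- list()
  for (key in unique(paste(blocks$query, blocks$target))) {
    b <- blocks[paste(blocks$query, blocks$target) == key, , drop = FALSE]
    b <- b[order(b$tstart, b$qstart), , drop = FALSE]
    cur <- NULL
    flush <- function(ch) {
      if (!is.null(ch)) chains[[length(chains) + 1]] <<- ch
    }
    for (i in seq_len(nrow(b))) {
      row <- b[i, ]
      if (is.null(cur)) { cur <- row; cur$n_blocks <- 1L; next }
      tgap <- row$tstart - cur$tend
      # query gap between the new block and the chain's query extent
      qgap <- if (row$qstart >= cur$qend) row$qstart - cur$qend
              else if (row$qend <= cur$qstart) cur$qstart - row$qend
              else 0
      if (row$strand == cur$strand && tgap < merge_gap && tgap >= 0 &&
          qgap < merge_gap) {
        cur$tend <- max(cur$tend, row$tend)
        cur$qstart <- min(cur$qstart, row$qstart)
        cur$qend <- max(cur$qend, row$qend)
        cur$aligned_sites <- cur$aligned_sites + row$aligned_sites
        cur$n_blocks <- cur$n_blocks + 1L
      } else {
        flush(cur)
        cur <- row; cur$n_blocks <- 1L
      }
    }
    flush(cur)
  }
  if (length(chains) == 0) return(empty_chain_df())
  ch <- do.call(rbind, chains)
  span <- ch$tend - ch$tstart
  ch$aligned_fraction <- ch$aligned_sites / span
  ch <- ch[span >= min_span & ch$aligned_fraction >= min_aligned, ,
           drop = FALSE]
  if (nrow(ch) == 0) return(empty_chain_df())
  ch <- ch[order(ch$query, ch$qstart), , drop = FALSE]
  rownames(ch) <- NULL
  ch
}

empty_chain_df <- function() {
  data.frame(query = character(), qstart = numeric(), qend = numeric(),
             target = character(), tstart = numeric(), tend = numeric(),
             strand = character(), aligned_sites = numeric(),
             n_blocks = integer(), aligned_fraction = numeric(),
             stringsAsFactors = FALSE)
}

#' Detect rearrangements from chained alignments
#'
#' Walks the chains of each query scaffold in query order and classifies
#' each adjacent pair: opposite strands on one target chromosome is an
#' inversion; different target chromosomes an inter-chromosomal
#' rearrangement; same chromosome and strand with target order
#' inconsistent with query order (beyond `merge_gap`) an
#' intra-chromosomal rearrangement.
#'
#' @param chains [chain_blocks()] output.
#' @param merge_gap tolerance for target-order consistency.
#' @return data.frame of events: `query`, `kind`, breakpoint query
#'   coordinates, flanking-chain target info, `lineage` (unassigned).
#' @export
detect_rearrangements <- function(chains, merge_gap = 2e4) {
  out <- list()
  for (q in unique(chains$query)) {
    ch <- chains[chains$query == q, , drop = FALSE]
    ch <- ch[order(ch$qstart), , drop = FALSE]
    if (nrow(ch) < 2) next
    for (i in seq_len(nrow(ch) - 1)) {
      a <- ch[i, ]; b <- ch[i + 1, ]
      kind <- NULL
      if (a$target != b$target) {
        kind <- "inter_chromosomal"
      } else if (a$strand != b$strand) {
        kind <- "inversion"
      } else {
        consistent <- if (a$strand == "+") b$tstart >= a$tend - merge_gap
                      else b$tend <= a$tstart + merge_gap
        if (!consistent) kind <- "intra_chromosomal"
      }
      if (!is.null(kind))
        out[[length(out) + 1]] <- data.frame(
          query = q, kind = kind,
          q_break_start = a$qend, q_break_end = b$qstart,
          target_a = a$target, tstart_a = a$tstart, tend_a = a$tend,
          strand_a = a$strand,
          target_b = b$target, tstart_b = b$tstart, tend_b = b$tend,
          strand_b = b$strand,
          lineage = "unassigned", stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(query = character(), kind = character(),
                      q_break_start = numeric(), q_break_end = numeric(),
                      target_a = character(), tstart_a = numeric(),
                      tend_a = numeric(), strand_a = character(),
                      target_b = character(), tstart_b = numeric(),
                      tend_b = numeric(), strand_b = character(),
                      lineage = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Collapse paired breakpoints into single rearrangement events
#'
#' A rearranged segment bounded by two breakpoints (entry and exit of an
#' inverted or translocated chain) is reported by
#' [detect_rearrangements()] as two adjacent events of the same kind
#' sharing the middle chain; this helper merges each such pair into one
#' event.
#'
#' @param rearr [detect_rearrangements()] output.
#' @return data.frame with one row per rearrangement event.
#' @export
collapse_breakpoints <- function(rearr) {
  if (nrow(rearr) < 2) return(rearr)
  keep <- rep(TRUE, nrow(rearr))
  i <- 1
  while (i < nrow(rearr)) {
    a <- rearr[i, ]; b <- rearr[i + 1, ]
    if (keep[i] && a$query == b$query && a$kind == b$kind &&
        a$target_b == b$target_a && a$strand_b == b$strand_a &&
        a$tstart_b == b$tstart_a && a$tend_b == b$tend_a) {
      rearr$q_break_end[i] <- b$q_break_end
      rearr$target_b[i] <- b$target_b
      rearr$tstart_b[i] <- b$tstart_b
      rearr$tend_b[i] <- b$tend_b
      rearr$strand_b[i] <- b$strand_b
      keep[i + 1] <- FALSE
      i <- i + 2
    } else {
      i <- i + 1
    }
  }
  out <- rearr[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Polarize a rearrangement with outgroup chains
#'
#' Compares the query scaffold's organization against the outgroup
#' (e.g. dog) over the breakpoint region.  If the outgroup chains are
#' collinear across the breakpoint (one same-strand chain spanning it),
#' the query matches the outgroup and the event is assigned to the
#' reference (cat) lineage; if the query-vs-outgroup chains show the
#' same kind of discordance at the breakpoint, the query changed and the
#' event is assigned to the query (lynx) lineage; otherwise it remains
#' unassigned.
#'
#' @param rearrangement one row of [detect_rearrangements()].
#' @param outgroup_chains chains of the same query scaffold against the
#'   outgroup genome.
#' @param merge_gap consistency tolerance.
#' @return `"lynx"`, `"cat"` or `"unassigned"` (attribute `reason` when
#'   unassigned).
#' @export
polarize_with_outgroup <- function(rearrangement, outgroup_chains,
                                   merge_gap = 2e4) {
  oc <- outgroup_chains[outgroup_chains$query == rearrangement$query[1], ,
                        drop = FALSE]
  bs <- rearrangement$q_break_start[1]
  be <- rearrangement$q_break_end[1]
  if (nrow(oc) == 0)
    return(structure("unassigned", reason = "no outgroup coverage"))
  spanning <- oc$qstart < bs & oc$qend > be
  if (any(spanning)) return("cat")
  # outgroup chains flanking the breakpoint: same discordance as query?
  oc <- oc[order(oc$qstart), , drop = FALSE]
  left <- oc[oc$qend <= be, , drop = FALSE]
  right <- oc[oc$qstart >= bs, , drop = FALSE]
  if (nrow(left) == 0 || nrow(right) == 0)
    return(structure("unassigned", reason = "no outgroup coverage"))
  a <- left[nrow(left), ]; b <- right[1, ]
  kind <- if (a$target != b$target) "inter_chromosomal"
          else if (a$strand != b$strand) "inversion"
          else {
            consistent <- if (a$strand == "+")
              b$tstart >= a$tend - merge_gap
            else b$tend <= a$tstart + merge_gap
            if (!consistent) "intra_chromosomal" else "none"
          }
  if (kind == rearrangement$kind[1]) return("lynx")
  structure("unassigned", reason = "outgroup arrangement matches neither")
}
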