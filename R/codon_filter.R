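# Conserved-neighborhood codon-column filtering for reliable dN/dS, and
# a counting (Nei-Gojobori style) dN/dS with Jukes-Cantor correction.

#' Codon alignment container
#'
#' @param rows named character vector of equal-length DNA strings whose
#'   length is divisible by 3.
#' @return object of class `codon_alignment`.
#' @export
codon_alignment <- function(rows) {
  stopifnot(length(rows) >= 2, !is.null(names(rows)))
  n <- unique(nchar(rows))
  if (length(n) != 1) stop("alignment rows must have equal length")
  if (n %% 3 != 0) stop("row length not divisible by 3")
  structure(list(taxa = names(rows), rows = toupper(rows),
                 n_codons = n / 3), class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$taxa), "taxa x", x$n_codons,
      "codons\n")
  invisible(x)
}

codon_matrix <- function(aln) {
  m <- vapply(aln$rows, function(s)
    substring(s, seq_len(aln$n_codons) * 3 - 2, seq_len(aln$n_codons) * 3),
    character(aln$n_codons))
  t(matrix(m, nrow = aln$n_codons, ncol = length(aln$taxa)))
}

from_codon_matrix <- function(m, taxa) {
  rows <- vapply(seq_along(taxa), function(i)
    paste(m[i, ], collapse = ""), character(1))
  names(rows) <- taxa
  structure(list(taxa = taxa, rows = rows, n_codons = ncol(m)),
            class = "codon_alignment")
}

translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  out <- gc[codon]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Remove codon columns containing gaps or ambiguity codes
#'
#' Columns with `-` in any row are dropped (reason `gap`); columns with
#' `N` or other ambiguity codes are dropped too and logged separately
#' (reason `ambiguous`).
#'
#' @param aln [codon_alignment()].
#' @return filtered `codon_alignment` with attribute `dropped` (a table
#'   of drop reasons).
#' @export
remove_gap_columns <- function(aln) {
  m <- codon_matrix(aln)
  has_gap <- apply(m, 2, function(col) any(grepl("-", col, fixed = TRUE)))
  has_amb <- apply(m, 2, function(col) any(grepl("[^ACGT-]", col)))
  keep <- !has_gap & !has_amb
  if (!any(keep)) warning("all codon columns dropped")
  out <- from_codon_matrix(m[, keep, drop = FALSE], aln$taxa)
  attr(out, "dropped") <- c(gap = sum(has_gap),
                            ambiguous = sum(has_amb & !has_gap))
  out
}

#' Keep replacement codon columns only when flanked by conserved ones
#'
#' Each retained codon column is translated; columns whose amino acids
#' are fully conserved are always kept, while a column with at least one
#' amino-acid replacement is kept only if the two preceding and two
#' following amino-acid columns (in post-gap-removal coordinates) all
#' exist and are each fully conserved.  Synonymous nucleotide variation
#' within a conserved amino-acid column does not count as replacement.
#'
#' @param aln gapless [codon_alignment()] (apply [remove_gap_columns()]
#'   first).
#' @return filtered `codon_alignment` with attribute `n_dropped`.
#' @export
filter_by_conserved_neighbors <- function(aln) {
  m <- codon_matrix(aln)
  nc <- ncol(m)
  if (nc == 0) return(aln)
  aa <- apply(m, 2, function(col) translate_codon(col))
  if (!is.matrix(aa)) aa <- matrix(aa, ncol = nc)
  conserved <- apply(aa, 2, function(col) length(unique(col)) == 1)
  keep <- conserved
  repl <- which(!conserved)
  for (i in repl) {
    fl <- c(i - 2, i - 1, i + 1, i + 2)
    keep[i] <- all(fl >= 1 & fl <= nc) && all(conserved[fl])
  }
  out <- from_codon_matrix(m[, keep, drop = FALSE], aln$taxa)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Concatenate filtered codon alignments
#'
#' @param alignments list of `codon_alignment`s over the identical taxon
#'   set and order; empty members are skipped with a warning.
#' @return list: `alignment` (concatenated), `offsets` (data.frame
#'   `gene`, `start_codon`, `n_codons`; 0-based codon offsets).
#' @export
concatenate_alignments <- function(alignments) {
  stopifnot(length(alignments) >= 1)
  if (is.null(names(alignments)))
    names(alignments) <- paste0("gene", seq_along(alignments))
  taxa <- alignments[[1]]$taxa
  parts <- list(); offs <- list(); at <- 0
  for (g in names(alignments)) {
    a <- alignments[[g]]
    if (!identical(a$taxa, taxa))
      stop("taxon set mismatch in gene ", g)
    if (a$n_codons == 0) {
      warning("empty alignment skipped: ", g)
      next
    }
    parts[[g]] <- a$rows
    offs[[g]] <- data.frame(gene = g, start_codon = at,
                            n_codons = a$n_codons,
                            stringsAsFactors = FALSE)
    at <- at + a$n_codons
  }
  rows <- vapply(taxa, function(tx)
    paste(vapply(parts, `[[`, "", tx), collapse = ""), character(1))
  list(alignment = codon_alignment(rows),
       offsets = do.call(rbind, c(offs, make.row.names = FALSE)))
}

# all minimal mutational paths between two codons: returns per-path
# (syn, nonsyn) step counts; paths passing through stop codons dropped
codon_paths <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  diff <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(diff) == 0) return(matrix(numeric(0), ncol = 2))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  out <- list()
  for (ord in perms(diff)) {
    cur <- strsplit(c1, "")[[1]]
    tgt <- strsplit(c2, "")[[1]]
    syn <- 0; non <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur; nxt[p] <- tgt[p]
      a1 <- gc[[paste(cur, collapse = "")]]
      a2 <- gc[[paste(nxt, collapse = "")]]
      if (a2 == "*") { ok <- FALSE; break }
      if (a1 == a2) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    if (ok) out[[length(out) + 1]] <- c(syn, non)
  }
  if (length(out) == 0)
    return(matrix(c(0, length(diff)), ncol = 2))  # all paths via stops
  do.call(rbind, out)
}

# synonymous site count of one codon (mutations to stops count as
# nonsynonymous)
syn_sites_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  s <- 0
  cb <- strsplit(codon, "")[[1]]
  for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"), cb[p])) {
    alt <- cb; alt[p] <- b
    if (gc[[paste(alt, collapse = "")]] == aa) s <- s + 1 / 3
  }
  s
}

#' Counting dN/dS between two codon sequences
#'
#' Nei-Gojobori style: per-codon synonymous/nonsynonymous site counts
#' averaged over the pair; observed differences classified along minimal
#' mutational paths (multi-hit codons averaged over pathway orderings,
#' paths through stop codons excluded); Jukes-Cantor correction.
#'
#' @param seq_a,seq_b equal-length gapless codon sequences.
#' @return list: `dN`, `dS`, `ratio` (`NA` when `dS` = 0), `N`, `S`
#'   (site counts), `Nd`, `Sd` (difference counts).
#' @export
counting_dnds <- function(seq_a, seq_b) {
  aln <- codon_alignment(c(a = seq_a, b = seq_b))
  m <- codon_matrix(aln)
  gc <- Biostrings::GENETIC_CODE
  if (any(gc[m] == "*"))
    stop("internal stop codon in input")
  S <- 0; Nd <- 0; Sd <- 0
  for (j in seq_len(ncol(m))) {
    s_a <- syn_sites_codon(m[1, j])
    s_b <- syn_sites_codon(m[2, j])
    S <- S + (s_a + s_b) / 2
    if (m[1, j] != m[2, j]) {
      paths <- codon_paths(m[1, j], m[2, j])
      Sd <- Sd + mean(paths[, 1])
      Nd <- Nd + mean(paths[, 2])
    }
  }
  N <- 3 * ncol(m) - S
  jc <- function(p) {
    if (p <= 0) return(0)
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  dS <- if (S > 0) jc(Sd / S) else 0
  dN <- if (N > 0) jc(Nd / N) else 0
  ratio <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  list(dN = dN, dS = dS, ratio = ratio, N = N, S = S, Nd = Nd, Sd = Sd)
}
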