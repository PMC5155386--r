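#' Read a FASTA file of DNA sequences
#'
#' Sequences are upper-cased and validated to contain only A, C, G, T, N.
#' Record ids (first whitespace-delimited token of each header) must be
#' unique.
#'
#' @param path FASTA file.
#' @return named character vector, one uppercase DNA string per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA: line ", nonblank[1], " is not a header")
  seq_lines <- nonblank[!startsWith(trimws(lines[nonblank]), ">")]
  bad <- seq_lines[grepl("[^ACGTNacgtn]", lines[seq_lines])]
  if (length(bad))
    stop("non-IUPAC (non-ACGTN) character in FASTA at line ", bad[1])
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id: ", ids[duplicated(ids)][1])
  out <- toupper(as.character(ss))
  names(out) <- ids
  out
}

#' Write DNA sequences to FASTA
#'
#' @param seqs named character vector of DNA strings.
#' @param path output file.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  ss <- Biostrings::DNAStringSet(toupper(unlist(seqs)))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Diploid genotype matrix
#'
#' Container for diploid genotypes at polymorphic sites.  Genotypes are
#' coded as alternate-allele dosages 0/1/2 with `NA` for missing.
#'
#' @param sites data.frame of width-1 intervals (`chrom`, `start`, `end`),
#'   0-based half-open, strictly increasing within each chromosome.
#' @param genotypes integer matrix, sites x individuals.
#' @param populations named character vector mapping individual to
#'   population label.
#' @param callable_sites number of reliably genotyped positions (variant
#'   plus invariant) underlying per-site statistics.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, genotypes, populations, callable_sites) {
  genotypes <- as.matrix(genotypes)
  validate_intervals(sites, "genotype_matrix sites")
  stopifnot(nrow(sites) == nrow(genotypes),
            !is.null(colnames(genotypes)),
            all(colnames(genotypes) %in% names(populations)))
  if (callable_sites < nrow(sites))
    stop("callable_sites must be >= number of variant sites")
  for (chr in unique(sites$chrom)) {
    p <- sites$start[sites$chrom == chr]
    if (is.unsorted(p, strictly = TRUE))
      stop("site positions must be strictly increasing within ", chr)
  }
  ok <- genotypes %in% c(0L, 1L, 2L) | is.na(genotypes)
  if (!all(ok)) stop("genotypes must be 0/1/2/NA")
  populations <- populations[colnames(genotypes)]
  structure(list(sites = sites, genotypes = genotypes,
                 populations = populations,
                 callable_sites = as.numeric(callable_sites)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$sites), "sites x", ncol(x$genotypes),
      "individuals;", length(unique(x$populations)), "population(s);",
      format(x$callable_sites, big.mark = ","), "callable sites\n")
  invisible(x)
}

#' Read diploid genotypes from a VCF
#'
#' Only biallelic SNP records are kept; all other records are skipped and
#' counted (attribute `n_skipped`).  GT fields are parsed into
#' alternate-allele dosages; `./.` becomes `NA`.  1-based VCF positions
#' are converted to the internal 0-based convention.
#'
#' @param path VCF file.
#' @param sample_names samples to extract, in the required order.
#' @param populations optional named character vector individual ->
#'   population; defaults to one population `"pop"`.
#' @param callable_sites callable-site count for per-site statistics;
#'   defaults to the number of retained records.
#' @return [genotype_matrix()] with attribute `n_skipped`.
#' @export
read_vcf_genotypes <- function(path, sample_names, populations = NULL,
                               callable_sites = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  avail <- colnames(v@gt)[-1]
  missing <- setdiff(sample_names, avail)
  if (length(missing))
    stop("sample(s) not in VCF: ", paste(missing, collapse = ", "),
         "; available: ", paste(avail, collapse = ", "))
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = list(NULL, colnames(vcfR::getFIX(v))))
  snp <- fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, sample_names, drop = FALSE]
  dosage <- function(g) {
    ifelse(is.na(g) | grepl("\\.", g), NA_integer_,
           vapply(strsplit(g, "[/|]"),
                  function(a) sum(as.integer(a)), integer(1)))
  }
  geno <- apply(gt, 2, dosage)
  geno <- matrix(as.integer(geno), ncol = length(sample_names),
                 dimnames = list(NULL, sample_names))
  pos <- as.numeric(fix[snp, "POS"]) - 1
  sites <- data.frame(chrom = fix[snp, "CHROM"], start = pos, end = pos + 1,
                      stringsAsFactors = FALSE)
  if (is.null(populations)) {
    populations <- stats::setNames(rep("pop", length(sample_names)),
                                   sample_names)
  }
  if (is.null(callable_sites)) callable_sites <- nrow(sites)
  gm <- genotype_matrix(sites, geno, populations, callable_sites)
  attr(gm, "n_skipped") <- n_skipped
  gm
}

#' Read RepeatMasker .out annotations
#'
#' Converts the 1-based inclusive .out coordinates to 0-based half-open
#' and the `C` orientation to `-`.  The `class` column is collapsed onto
#' the closed set SINE / LINE / LTR / ERV-internal / other; LTR-class
#' fragments whose repeat name ends in `-int` are ERV-internal.
#'
#' @param path RepeatMasker .out file.
#' @return data.frame: `chrom`, `start`, `end`, `strand`, `repeat_name`,
#'   `repeat_class`, `family`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  keep <- which(grepl("^\\s*[0-9]+\\s", lines))
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 11 || is.na(suppressWarnings(as.numeric(f[6]))) ||
        is.na(suppressWarnings(as.numeric(f[7]))))
      stop("unparseable RepeatMasker line ", i)
    f
  })
  if (length(rows) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      repeat_name = character(), repeat_class = character(),
                      family = character(), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, rows)
  cls_raw <- m[, 11]
  cls <- sub("/.*$", "", cls_raw)
  fam <- ifelse(grepl("/", cls_raw), sub("^[^/]*/", "", cls_raw), m[, 10])
  repeat_class <- ifelse(cls == "LTR" & grepl("-int$", m[, 10]),
                         "ERV-internal",
                         ifelse(cls %in% c("SINE", "LINE", "LTR"), cls,
                                ifelse(cls == "ERV-internal", cls, "other")))
  out <- data.frame(chrom = m[, 5],
                    start = as.numeric(m[, 6]) - 1,
                    end = as.numeric(m[, 7]),
                    strand = ifelse(m[, 9] == "C", "-", "+"),
                    repeat_name = m[, 10],
                    repeat_class = repeat_class,
                    family = fam,
                    stringsAsFactors = FALSE)
  validate_intervals(out, "repeat annotation")
  out
}

#' Write repeat annotations in RepeatMasker .out layout
#'
#' @param repeats data.frame as returned by [read_repeatmasker_out()].
#' @param path output file.
#' @export
write_repeatmasker_out <- function(repeats, path) {
  hdr <- c(
    "   SW  perc perc perc  query     position in query    matching repeat        position in repeat",
    "score  div. del. ins.  sequence  begin  end  (left)   repeat   class/family  begin  end (left) ID",
    "")
  cls <- ifelse(repeats$repeat_class == "ERV-internal",
                paste0("LTR/", repeats$family),
                paste0(repeats$repeat_class, "/", repeats$family))
  body <- sprintf("%5d %5.1f %4.1f %4.1f  %s %d %d (%d) %s %s %s %d %d (%d) %d",
                  1000L, 0, 0, 0,
                  repeats$chrom, repeats$start + 1, repeats$end, 0L,
                  ifelse(repeats$strand == "-", "C", "+"),
                  repeats$repeat_name, cls,
                  1L, repeats$end - repeats$start, 0L,
                  seq_len(nrow(repeats)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a tab-separated pairwise alignment-block table
#'
#' Schema: `query`, `qstart`, `qend`, `target`, `tstart`, `tend`,
#' `strand`, `aligned_sites`; coordinates 0-based half-open.
#'
#' @param path TSV file with header.
#' @return data.frame of alignment blocks.
#' @export
read_alignment_blocks <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("query", "qstart", "qend", "target", "tstart", "tend",
            "strand", "aligned_sites")
  if (!all(need %in% names(df)))
    stop("alignment block table must have columns: ",
         paste(need, collapse = ", "))
  validate_alignment_blocks(df)
  df[need]
}

validate_alignment_blocks <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$qstart >= df$qend | df$tstart >= df$tend))
    stop("alignment block with empty interval")
  if (!all(df$strand %in% c("+", "-")))
    stop("alignment block strand must be '+' or '-'")
  span <- pmin(df$qend - df$qstart, df$tend - df$tstart)
  bad <- which(df$aligned_sites > span)
  if (length(bad))
    stop("aligned_sites exceeds block span at row ", bad[1])
  invisible(df)
}

#' Write an alignment-block table
#' @param blocks data.frame in the [read_alignment_blocks()] schema.
#' @param path output file.
#' @export
write_alignment_blocks <- function(blocks, path) {
  cols <- c("query", "qstart", "qend", "target", "tstart", "tend",
            "strand", "aligned_sites")
  utils::write.table(blocks[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a BED file (3-6 columns)
#'
#' BED is natively 0-based half-open so coordinates pass through
#' unchanged.
#'
#' @param path BED file.
#' @return data.frame: `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- cols[seq_len(ncol(df))]
  validate_intervals(df, "BED")
  df
}

#' Write a BED file
#' @param df data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  # BED columns are positional: fill any missing middle column
  if ("strand" %in% cols && !"name" %in% cols) df$name <- "."
  if ("strand" %in% cols && !"score" %in% cols) df$score <- 0
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  utils::write.table(df[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}
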