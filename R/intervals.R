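#' Construct a table of genomic intervals
#'
#' All coordinates inside the package are 0-based half-open (`start`
#' inclusive, `end` exclusive); conversion from 1-based source dialects
#' (VCF, RepeatMasker .out) happens only in the readers.
#'
#' @param chrom character vector of sequence names.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand strand per interval: `"+"`, `"-"` or `"*"` (unstranded).
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom) | !nzchar(df$chrom)))
    stop(what, ": chrom must be non-empty")
  bad <- which(!(df$start < df$end))
  if (length(bad))
    stop(what, ": start must be < end (first offending row ", bad[1], ")")
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", "*")))
    stop(what, ": strand must be one of '+', '-', '*'")
  invisible(df)
}

# bp of overlap between one interval (chrom,start,end) and each row of df
overlap_bp <- function(chrom, start, end, df) {
  same <- df$chrom == chrom
  lo <- pmax(start, df$start)
  hi <- pmin(end, df$end)
  ifelse(same & hi > lo, hi - lo, 0)
}
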