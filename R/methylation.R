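# Per-CpG bisulfite read counts -> site methylation statuses -> window
# methylation levels and frequencies. The pipeline starts at count tables;
# read alignment and conversion-efficiency issues are out of scope.

#' Read a per-CpG methylation count table
#'
#' Tab-separated with header and columns `chrom`, `position` (0-based),
#' `strand`, `count_methylated`, `count_total`. Minus-strand records are
#' mapped to the plus-strand C coordinate of their CpG (position - 1) and, by
#' default, merged with the plus-strand record of the same dinucleotide by
#' summing counts (CpG methylation is palindromic; the CpG dinucleotide is
#' the unit of analysis).
#'
#' @param path File path.
#' @param min_coverage Minimum total read count per site (default 1);
#'   lower-coverage rows are dropped with a message.
#' @param merge_strands Merge the two strands of one CpG (default `TRUE`).
#' @return Data frame with columns `chrom`, `position`, `count_methylated`,
#'   `count_total`.
#' @export
read_methylation_table <- function(path, min_coverage = 1, merge_strands = TRUE) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "position", "strand", "count_methylated", "count_total")
  if (!all(need %in% names(df))) {
    stop("methylation table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(df$count_methylated > df$count_total)
  if (length(bad) > 0) {
    stop(sprintf("methylated count exceeds total at line %d (position %s:%d)",
                 bad[1] + 1L, df$chrom[bad[1]], df$position[bad[1]]), call. = FALSE)
  }
  if (any(df$count_methylated < 0 | df$count_total < 0)) {
    stop("negative read counts", call. = FALSE)
  }
  drop <- df$count_total < min_coverage
  if (any(drop)) {
    message(sprintf("dropping %d record(s) below coverage %d", sum(drop), min_coverage))
    df <- df[!drop, , drop = FALSE]
  }
  df$position <- ifelse(df$strand == "-", df$position - 1L, df$position)
  if (merge_strands) {
    key <- paste(df$chrom, df$position)
    df <- data.frame(
      chrom = tapply(df$chrom, key, `[`, 1L),
      position = as.integer(tapply(df$position, key, `[`, 1L)),
      count_methylated = as.integer(tapply(df$count_methylated, key, sum)),
      count_total = as.integer(tapply(df$count_total, key, sum)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  } else {
    df <- df[, c("chrom", "position", "count_methylated", "count_total")]
  }
  df[order(df$chrom, df$position), , drop = FALSE]
}

#' Methylation status of a single CpG site
#'
#' Fraction of reads that were non-converted: `x_mCpG / (x_mCpG + x_CpG)`,
#' ranging between 0 and 1.
#'
#' @param count_methylated,count_total Read counts (vectorised).
#' @return Numeric status in `[0, 1]`; `NA` where `count_total` is 0.
#' @examples
#' site_status(8, 10)
#' @export
site_status <- function(count_methylated, count_total) {
  ifelse(count_total >= 1, count_methylated / count_total, NA_real_)
}

#' Window CpG methylation level (pooled counts)
#'
#' The coverage-weighted level
#' `L_mCpG = sum(x_mCpG) / sum(x_mCpG + x_CpG)` over the usable CpG records of
#' the window -- the pooled-count ratio, not the mean of per-site statuses.
#'
#' @param records Data frame with columns `count_methylated` and
#'   `count_total` (the set Omega of CpGs in the window's analysable regions).
#' @return Level in `[0, 1]`; `NA` for an empty record set.
#' @examples
#' window_methylation_level(data.frame(count_methylated = c(8, 0),
#'                                     count_total = c(10, 10)))  # 0.4
#' @export
window_methylation_level <- function(records) {
  if (is.null(records) || nrow(records) == 0) return(NA_real_)
  tot <- sum(records$count_total)
  if (tot == 0) return(NA_real_)
  sum(records$count_methylated) / tot
}

#' Frequency of methylated sites in a window
#'
#' The product of the window CpG methylation level and its CpG content: the
#' per-dinucleotide-position frequency of methylated CpGs, the quantity that
#' should drive the regional impact of methylation on GC content evolution.
#'
#' @param level Window methylation level in `[0, 1]`.
#' @param cpg_content Window CpG content in `[0, 1]`.
#' @return The exact product.
#' @examples
#' methylation_frequency(0.41, 0.0092)
#' @export
methylation_frequency <- function(level, cpg_content) {
  stopifnot_prob(level[!is.na(level)], "methylation level")
  stopifnot_prob(cpg_content[!is.na(cpg_content)], "CpG content")
  level * cpg_content
}

#' Export site methylation statuses as bedGraph
#'
#' One line per CpG: chrom, start, end (start + 1) and the site status, for
#' genome-browser inspection.
#'
#' @param records Data frame as returned by [read_methylation_table()].
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_methylation_bedgraph <- function(records, path) {
  df <- data.frame(records$chrom, records$position, records$position + 1L,
                   site_status(records$count_methylated, records$count_total))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
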