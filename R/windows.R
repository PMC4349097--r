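# Window partitioning, the triple-alignment window container, masking,
# filtering, and per-window composition / recombination statistics.
# All coordinates are 0-based half-open, matching BED conventions.

#' Tile chromosomes into consecutive non-overlapping windows
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp), or a
#'   data frame with columns `chrom` and `length`.
#' @param window_size Window size in bp (default 1 Mb). The terminal window of
#'   a chromosome may be shorter.
#' @return Data frame with columns `chrom`, `start`, `end` (0-based half-open).
#' @examples
#' partition_windows(c(chr1 = 2500000), 1e6)
#' @export
partition_windows <- function(chrom_lengths, window_size = 1e6) {
  if (is.data.frame(chrom_lengths)) {
    chrom_lengths <- setNames(chrom_lengths$length, chrom_lengths$chrom)
  }
  if (window_size < 1) stop("window_size must be >= 1", call. = FALSE)
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive", call. = FALSE)
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    start <- seq(0, len - 1, by = window_size)
    data.frame(chrom = ch, start = start, end = pmin(start + window_size, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Triple alignment window
#'
#' Container for one genomic window of a gapped alignment of two sister
#' species and an outgroup, plus a per-column mask flag (`TRUE` = masked).
#' Sequences may be given as character strings or integer codes; non-ACGT
#' characters (gaps, N) become ambiguous positions.
#'
#' @param sister1,sister2,outgroup Aligned sequences of equal length.
#'   `sister1` is the reference species used for composition and methylation.
#' @param chrom,start Window coordinates (0-based start).
#' @param mask Optional initial logical mask (default all `FALSE`).
#' @return An object of class `triple_window` with fields `chrom`, `start`,
#'   `end`, `seqs` (list of 3 integer code vectors) and `mask`.
#' @export
triple_window <- function(sister1, sister2, outgroup,
                          chrom = "chr", start = 0L, mask = NULL) {
  seqs <- lapply(list(sister1 = sister1, sister2 = sister2, outgroup = outgroup),
                 encode_seq)
  L <- unique(lengths(seqs))
  if (length(L) != 1L) stop("aligned sequences must have equal length", call. = FALSE)
  if (is.null(mask)) mask <- rep(FALSE, L)
  if (length(mask) != L) stop("mask length mismatch", call. = FALSE)
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(start) + L, seqs = seqs,
                 mask = as.logical(mask)),
            class = "triple_window")
}

#' @export
print.triple_window <- function(x, ...) {
  cat(sprintf("triple_window %s:%d-%d (%d columns, %d unambiguous)\n",
              x$chrom, x$start, x$end, length(x$mask), n_unambiguous(x)))
  invisible(x)
}

# integer codes with masked columns zeroed, for all three species
.masked_codes <- function(window) {
  lapply(window$seqs, function(s) {
    s[window$mask] <- 0L
    s
  })
}

#' Number of unambiguous columns of a window
#'
#' A column counts as unambiguous when it is unmasked and all three species
#' carry A/C/G/T (no gap, no N).
#'
#' @param window A [triple_window()].
#' @return Integer count.
#' @export
n_unambiguous <- function(window) {
  ok <- !window$mask
  for (s in window$seqs) ok <- ok & s > 0L
  sum(ok)
}

#' Apply mask intervals and ambiguity flags to a window
#'
#' Columns falling inside any interval (genome coordinates, 0-based half-open,
#' e.g. transcribed/UTR/repeat annotation read with [read_bed()]) are flagged,
#' as are columns with a gap or ambiguous base in any of the three species.
#' Intervals extending beyond the window are clipped with a warning.
#'
#' @param window A [triple_window()].
#' @param mask_intervals `NULL` or a data frame with columns `chrom`, `start`,
#'   `end`.
#' @return The window with its `mask` updated.
#' @export
apply_masks <- function(window, mask_intervals = NULL) {
  L <- length(window$mask)
  mask <- window$mask
  for (s in window$seqs) mask <- mask | s == 0L
  if (!is.null(mask_intervals) && nrow(mask_intervals) > 0) {
    iv <- mask_intervals[mask_intervals$chrom == window$chrom, , drop = FALSE]
    if (nrow(iv) > 0 && any(iv$end > window$end | iv$start < 0)) {
      warning("mask interval(s) extend beyond the window; clipped")
    }
    for (k in seq_len(nrow(iv))) {
      a <- max(iv$start[k], window$start) - window$start
      b <- min(iv$end[k], window$end) - window$start
      if (b > a) mask[(a + 1L):b] <- TRUE
    }
  }
  window$mask <- mask
  window
}

#' Read a BED file of intervals
#'
#' Plain 3+ column BED (0-based half-open), no header.
#'
#' @param path File path.
#' @return Data frame with columns `chrom`, `start`, `end` (plus `rate` if a
#'   4th numeric column is present, as written by the simulator's
#'   recombination map).
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4 && is.numeric(df[[4]])) names(df)[4] <- "rate"
  df
}

#' Keep windows with enough unambiguous sites
#'
#' @param windows List of [triple_window()] objects (masks applied).
#' @param min_unambiguous Minimum number of unambiguous columns (default
#'   10,000).
#' @return The retained windows; warns when none survive.
#' @export
filter_windows <- function(windows, min_unambiguous = 10000) {
  keep <- vapply(windows, n_unambiguous, integer(1)) >= min_unambiguous
  if (!any(keep)) warning("no windows pass the unambiguous-site filter")
  windows[keep]
}

#' Base composition of a window's reference species
#'
#' GC content over unmasked sites, CpG dinucleotide content over unmasked
#' genome-adjacent pairs (pairs straddling a masked column are skipped), and
#' CpG observed/expected where the expectation is `f(C) * f(G)` from the same
#' unmasked sites.
#'
#' @param x A [triple_window()] (its `sister1`), or a sequence (string or
#'   codes).
#' @param mask Optional logical mask when `x` is a bare sequence.
#' @return List with `gc_content`, `cpg_content`, `cpg_oe` (`cpg_oe` is `NA`
#'   when `f(C) * f(G) = 0`).
#' @examples
#' composition("ACGT")  # gc 0.5, cpg 1/3, oe 16/3
#' @export
composition <- function(x, mask = NULL) {
  if (inherits(x, "triple_window")) {
    codes <- x$seqs$sister1
    codes[x$mask] <- 0L
  } else {
    codes <- encode_seq(x)
    if (!is.null(mask)) codes[mask] <- 0L
  }
  ok <- codes > 0L
  n <- sum(ok)
  if (n < 2L) stop("need at least 2 unmasked sites", call. = FALSE)
  fC <- sum(codes == 2L) / n
  fG <- sum(codes == 3L) / n
  gc <- fC + fG
  a <- codes[-length(codes)]; b <- codes[-1L]
  pair_ok <- a > 0L & b > 0L
  n_pairs <- sum(pair_ok)
  cpg <- if (n_pairs > 0) sum(a == 2L & b == 3L) / n_pairs else NA_real_
  oe <- if (fC * fG > 0) cpg / (fC * fG) else {
    message("composition: f(C)*f(G) = 0, CpG[o/e] undefined")
    NA_real_
  }
  list(gc_content = gc, cpg_content = cpg, cpg_oe = oe)
}

#' Distance-weighted recombination rate of a window
#'
#' The window rate is the mean of the marker-interval rates weighted by the
#' physical overlap of each interval with the window.
#'
#' @param window A [triple_window()] or a list/data frame row with `chrom`,
#'   `start`, `end`.
#' @param marker_map Data frame with columns `chrom`, `start`, `end`, `rate`
#'   (cM/Mb), sorted and non-overlapping.
#' @return Rate in cM/Mb, or `NA` when no interval overlaps the window.
#' @export
window_recombination_rate <- function(window, marker_map) {
  iv <- marker_map[marker_map$chrom == window$chrom, , drop = FALSE]
  if (nrow(iv) == 0) return(NA_real_)
  ov <- pmax(0, pmin(iv$end, window$end) - pmax(iv$start, window$start))
  if (sum(ov) == 0) return(NA_real_)
  sum(ov * iv$rate) / sum(ov)
}
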