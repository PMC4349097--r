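# Internal helpers shared across modules. Sequences travel internally as
# integer vectors with A=1, C=2, G=3, T=4 and 0 for anything ambiguous.

.BASES <- c("A", "C", "G", "T")

# complement of the integer code; 0 stays 0
.rc_code <- function(x) ifelse(x == 0L, 0L, 5L - x)

#' Encode a nucleotide sequence as integer codes
#'
#' A, C, G, T (case-insensitive) map to 1..4; every other character (N, gap,
#' IUPAC ambiguity) maps to 0 and is treated as ambiguous downstream.
#'
#' @param x A single character string, a character vector of single letters,
#'   or an integer vector already in code space (returned unchanged).
#' @return Integer vector of codes.
#' @keywords internal
encode_seq <- function(x) {
  if (is.integer(x)) return(x)
  if (is.numeric(x)) return(as.integer(x))
  if (is.character(x) && length(x) == 1L && nchar(x) > 1L) {
    x <- strsplit(x, "", fixed = TRUE)[[1L]]
  }
  m <- match(toupper(as.character(x)), .BASES)
  m[is.na(m)] <- 0L
  as.integer(m)
}

#' Decode integer codes back to a nucleotide string
#'
#' @param x Integer vector of codes (0 becomes `N`).
#' @return A single character string.
#' @keywords internal
decode_seq <- function(x) {
  ch <- c("N", .BASES)[x + 1L]
  paste0(ch, collapse = "")
}

# Run expr with a temporary RNG state seeded by `seed`; restores the caller's
# RNG stream afterwards so library calls do not perturb user scripts.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic child seed derived from a master seed and an index; kept well
# below 2^31.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483123) + 1L
}

# names of the 16 ordered dinucleotides in index order 4*(a-1)+b
dinuc_names <- function() {
  as.vector(t(outer(.BASES, .BASES, paste0)))
}

# 0-based index of dinucleotide CG in the 16-vector (1-based position in R)
.CG <- 7L  # (C=2, G=3) -> 4*(2-1)+3 = 7

stopifnot_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}
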