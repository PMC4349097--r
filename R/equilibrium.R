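# Equilibrium GC content: the closed form without CpG hypermutability (GC*),
# the cluster-approximation value of the full neighbour-dependent process
# (GC*_CpG), their difference to current GC, and the leading-principal-
# component slope used to compare equilibrium with current GC across windows.

#' Equilibrium GC content without CpG hypermutability
#'
#' `GC* = u_WS / (u_WS + u_SW)`, where `u_WS` is the weak-to-strong and
#' `u_SW` the strong-to-weak substitution rate with CpG-context deamination
#' excluded (see [pathway_rates()]). Scale-invariant in the rates.
#'
#' @param u_WS,u_SW Pathway rates (>= 0), vectorised.
#' @return GC* in `[0, 1]`; `NA` (with a warning) where both rates are zero.
#' @examples
#' gc_star(0.1, 0.1)        # 0.5
#' gc_star(0.002, 0.003)    # 0.4
#' @export
gc_star <- function(u_WS, u_SW) {
  if (any(u_WS < 0 | u_SW < 0, na.rm = TRUE)) {
    stop("pathway rates must be non-negative", call. = FALSE)
  }
  tot <- u_WS + u_SW
  out <- ifelse(tot > 0, u_WS / tot, NA_real_)
  if (any(tot == 0, na.rm = TRUE)) {
    warning("u_WS + u_SW = 0: equilibrium GC undefined for some input(s)")
  }
  out
}

# stationary distribution of a CTMC generator (rows sum to 0)
.stationary <- function(Q) {
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  pi <- qr.solve(A, c(rep(0, n), 1))
  pi[pi < 0 & pi > -1e-12] <- 0
  pi / sum(pi)
}

# GC fraction implied by a dinucleotide frequency vector (each site appears in
# two overlapping pairs, so average the two positions)
.gc_of_dinuc <- function(f) {
  a <- rep(1:4, each = 4); b <- rep(1:4, times = 4)
  s <- (a %in% 2:3) + (b %in% 2:3)
  sum(f * s) / 2
}

#' Equilibrium GC content under CpG hypermutability (cluster approximation)
#'
#' Stationary GC fraction of the full neighbour-dependent process, computed on
#' the 16 dinucleotide frequencies with a pair closure: the dependence of a
#' site on the neighbour outside the pair is closed through the conditional
#' frequencies `P(left = C | G)` and `P(right = G | C)` of the current pair
#' distribution (triplet frequency approximated by the product of its two
#' overlapping pair frequencies over the shared mononucleotide frequency).
#' The self-consistent fixed point is iterated until the maximum change in
#' any dinucleotide frequency falls below `tol`, with 0.5 damping if the
#' iteration oscillates.
#'
#' With `r_CpG = 0` the closure is exact and the result equals
#' [gc_star()] of the context-free pathway rates.
#'
#' @param params [substitution_params()] of the branch of interest (all seven
#'   rates enter: the S<->S and W<->W exchanges matter for the stationary CpG
#'   frequency even though they cancel for GC in a context-free model).
#' @param tol Fixed-point tolerance on dinucleotide frequencies (default
#'   1e-10).
#' @param max_iter Iteration cap (default 1e6); non-convergence is an error.
#' @return Stationary GC fraction, with attributes `dinuc_freq` (the
#'   stationary pair distribution) and `iterations`.
#' @examples
#' p <- substitution_params(0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0)
#' gc_star_cpg(p)  # 0.5
#' @export
gc_star_cpg <- function(params, tol = 1e-10, max_iter = 1e6) {
  params <- as_substitution_params(params)
  if (sum(params) == 0) stop("at least one rate must be non-zero", call. = FALSE)
  f <- rep(1 / 16, 16)
  f_prev <- NULL
  damp <- 1
  for (it in seq_len(max_iter)) {
    fCG <- f[.CG]
    fC <- sum(f[4L * (2L - 1L) + (1:4)])
    fG <- sum(f[4L * ((1:4) - 1L) + 3L])
    bL <- if (fG > 0) fCG / fG else 0
    bR <- if (fC > 0) fCG / fC else 0
    Q <- dinuc_generator_cpp(unclass(params), bL, bR)
    f_new <- .stationary(Q)
    if (!is.null(f_prev) && sum((f_new - f) * (f - f_prev)) < 0) damp <- 0.5
    f_next <- damp * f_new + (1 - damp) * f
    delta <- max(abs(f_next - f))
    f_prev <- f
    f <- f_next
    if (delta < tol) {
      gc <- .gc_of_dinuc(f)
      return(structure(gc, dinuc_freq = setNames(f, dinuc_names()),
                       iterations = it))
    }
  }
  stop(sprintf("cluster approximation did not converge in %g iterations (last delta %g)",
               max_iter, delta), call. = FALSE)
}

#' Difference between equilibrium and current GC content
#'
#' `delta_GC = GC*_CpG - GC`: negative values mean the full substitution
#' process (including CpG hypermutability) is pushing GC content below its
#' current value.
#'
#' @param gc_star_cpg Equilibrium GC under CpG hypermutability.
#' @param gc_content Current GC content.
#' @return The exact (signed) difference, vectorised.
#' @examples
#' delta_gc(0.3988, 0.4034)
#' @export
delta_gc <- function(gc_star_cpg, gc_content) {
  gc_star_cpg - gc_content
}

#' Leading principal component line through paired window statistics
#'
#' Total-least-squares line: the first principal component of the centred
#' two-column data (the direction of maximum common variation), through the
#' point of means. A slope > 1 of equilibrium GC on current GC indicates
#' reinforcement of the GC landscape, a slope < 1 erosion.
#'
#' @param x,y Numeric vectors (e.g. current GC and GC* per window), length
#'   >= 3, both with positive variance.
#' @return Named vector `slope`, `intercept`.
#' @examples
#' x <- seq(0.3, 0.5, length.out = 10)
#' leading_pc_slope(x, 2 * x + 0.1)
#' @export
leading_pc_slope <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired values", call. = FALSE)
  if (var(x) == 0 || var(y) == 0) stop("zero variance", call. = FALSE)
  S <- cov(cbind(x, y))
  v <- eigen(S, symmetric = TRUE)$vectors[, 1L]
  if (abs(v[1L]) < .Machine$double.eps) stop("leading PC is vertical", call. = FALSE)
  slope <- v[2L] / v[1L]
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}
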