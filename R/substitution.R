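# Lineage-specific, neighbour-dependent substitution model: parameter
# containers, the dinucleotide generator, transition probabilities, the
# composite likelihood over overlapping dinucleotide columns, and the ML
# fitter.

#' Substitution rate parameters for one branch
#'
#' Seven free rates per branch: the six reverse-complement-symmetric
#' context-free exchanges (each name stands for the pooled strand pair, e.g.
#' `r_AC` is A->C and T->G) plus `r_CpG`, the additional CpG->TpG (equivalently
#' CpG->CpA) deamination rate per CpG dinucleotide. All rates are expected
#' substitutions per site per branch: branch length is absorbed into the rates
#' and the branch duration is fixed at 1.
#'
#' @param r_AC,r_AG,r_AT,r_CA,r_CG,r_CT Context-free exchange rates (>= 0).
#' @param r_CpG Additional CpG deamination rate (>= 0).
#' @return A named numeric vector of class `substitution_params`.
#' @examples
#' substitution_params(r_AG = 0.012, r_CT = 0.016, r_CpG = 0.16)
#' @export
substitution_params <- function(r_AC = 0, r_AG = 0, r_AT = 0,
                                r_CA = 0, r_CG = 0, r_CT = 0, r_CpG = 0) {
  p <- c(r_AC = r_AC, r_AG = r_AG, r_AT = r_AT,
         r_CA = r_CA, r_CG = r_CG, r_CT = r_CT, r_CpG = r_CpG)
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("substitution rates must be finite and non-negative", call. = FALSE)
  }
  structure(p, class = "substitution_params")
}

.param_names <- c("r_AC", "r_AG", "r_AT", "r_CA", "r_CG", "r_CT", "r_CpG")

as_substitution_params <- function(x) {
  if (inherits(x, "substitution_params")) return(x)
  x <- unlist(x)
  if (length(x) != 7L) stop("expected 7 rates", call. = FALSE)
  if (!is.null(names(x)) && all(.param_names %in% names(x))) x <- x[.param_names]
  do.call(substitution_params, as.list(unname(x)))
}

#' Context-free 4x4 rate matrix implied by the six pooled exchange rates
#'
#' Rows/columns are ordered A, C, G, T; the G and T rows follow from the C and
#' A rows by strand symmetry (`q[x, y] = q[rc(x), rc(y)]`).
#'
#' @param params A [substitution_params()] vector.
#' @return A 4x4 numeric matrix of off-diagonal rates with zero diagonal.
#' @export
base_rate_matrix <- function(params) {
  params <- as_substitution_params(params)
  q <- matrix(0, 4, 4, dimnames = list(.BASES, .BASES))
  q["A", "C"] <- params[["r_AC"]]; q["A", "G"] <- params[["r_AG"]]
  q["A", "T"] <- params[["r_AT"]]
  q["C", "A"] <- params[["r_CA"]]; q["C", "G"] <- params[["r_CG"]]
  q["C", "T"] <- params[["r_CT"]]
  q["T", "G"] <- params[["r_AC"]]; q["T", "C"] <- params[["r_AG"]]
  q["T", "A"] <- params[["r_AT"]]
  q["G", "T"] <- params[["r_CA"]]; q["G", "C"] <- params[["r_CG"]]
  q["G", "A"] <- params[["r_CT"]]
  q
}

#' Dinucleotide rate generator of the neighbour-dependent process
#'
#' Builds the 16x16 rate operator over ordered dinucleotides. An off-diagonal
#' entry x -> y is non-zero only when the two dinucleotides differ at exactly
#' one position; it equals the context-free rate of that single-site change,
#' with `r_CpG` added on the CG->TG and CG->CA entries (the two strand
#' readings of methyl-cytosine deamination). The diagonal is minus the row
#' sum.
#'
#' The optional `boundary` argument adds the cluster-style closure used by the
#' composite likelihood for CpG events whose partner base lies outside the
#' observed pair: an extra G->A rate `r_CpG * boundary["left"]` on
#' first-position G (hidden left neighbour C) and an extra C->T rate
#' `r_CpG * boundary["right"]` on second-position C (hidden right neighbour
#' G).
#'
#' @param params A [substitution_params()] vector.
#' @param boundary `NULL` (default, plain within-pair generator) or a numeric
#'   vector with elements `left` = P(hidden left neighbour is C | first base
#'   G) and `right` = P(hidden right neighbour is G | second base C).
#' @return 16x16 matrix with dinucleotide dimnames; rows sum to zero.
#' @examples
#' Q <- build_dinucleotide_generator(substitution_params(r_CT = 0.01, r_CpG = 0.1))
#' Q["CG", "TG"]  # r_CT + r_CpG
#' Q["CA", "TA"]  # r_CT
#' @export
build_dinucleotide_generator <- function(params, boundary = NULL) {
  params <- as_substitution_params(params)
  bL <- bR <- 0
  if (!is.null(boundary)) {
    bL <- boundary[["left"]]; bR <- boundary[["right"]]
    stopifnot_prob(c(bL, bR), "boundary context probabilities")
  }
  q <- base_rate_matrix(params)
  rcpg <- params[["r_CpG"]]
  nm <- dinuc_names()
  Q <- matrix(0, 16, 16, dimnames = list(nm, nm))
  idx <- function(a, b) 4L * (a - 1L) + b
  for (a in 1:4) {
    for (b in 1:4) {
      d <- idx(a, b)
      for (a2 in 1:4) if (a2 != a) Q[d, idx(a2, b)] <- Q[d, idx(a2, b)] + q[a, a2]
      for (b2 in 1:4) if (b2 != b) Q[d, idx(a, b2)] <- Q[d, idx(a, b2)] + q[b, b2]
    }
  }
  Q["CG", "TG"] <- Q["CG", "TG"] + rcpg
  Q["CG", "CA"] <- Q["CG", "CA"] + rcpg
  if (bL > 0) for (b in 1:4) {
    Q[idx(3L, b), idx(1L, b)] <- Q[idx(3L, b), idx(1L, b)] + rcpg * bL
  }
  if (bR > 0) for (a in 1:4) {
    Q[idx(a, 2L), idx(a, 4L)] <- Q[idx(a, 2L), idx(a, 4L)] + rcpg * bR
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

#' Transition probabilities of the dinucleotide process
#'
#' Matrix exponential of the generator times the branch duration; this is what
#' makes the model account for multiple hits at a site within one branch.
#'
#' @param generator 16x16 generator from [build_dinucleotide_generator()].
#' @param duration Branch duration (default 1; rates are per branch).
#' @return Row-stochastic 16x16 matrix.
#' @export
transition_probabilities <- function(generator, duration = 1) {
  P <- as.matrix(Matrix::expm(Matrix::Matrix(generator * duration)))
  dimnames(P) <- dimnames(generator)
  P
}

# ---- root composition ------------------------------------------------------

#' Reverse-complement symmetry classes of the 16 ordered dinucleotides
#'
#' `xy` and `rc(y)rc(x)` are strand-equivalent; there are 10 classes (AT, TA,
#' CG, GC are self-equivalent).
#'
#' @return Integer vector of class ids (1..10) named by dinucleotide.
#' @export
dinuc_rc_classes <- function() {
  setNames(as.integer(dinuc_class_cpp()), dinuc_names())
}

#' Validate (and symmetrize) a root dinucleotide composition
#'
#' The model does not assume stationarity: the composition at the internal
#' node of the 3-taxon tree is free, constrained only to be a
#' reverse-complement-symmetric probability vector (`f(xy) = f(rc(y)rc(x))`).
#'
#' @param freq Numeric vector of length 16 (order AA, AC, ..., TT).
#' @param symmetrize If `TRUE`, average `freq` with its strand image instead
#'   of erroring on asymmetry.
#' @return Named frequency vector summing to 1.
#' @export
root_composition <- function(freq, symmetrize = FALSE) {
  if (length(freq) != 16L || any(!is.finite(freq)) || any(freq < 0)) {
    stop("root composition must be 16 non-negative frequencies", call. = FALSE)
  }
  f <- as.numeric(freq) / sum(freq)
  cls <- dinuc_rc_classes()
  fsym <- as.numeric(tapply(f, cls, mean))[cls]
  if (symmetrize) {
    f <- fsym
  } else if (max(abs(f - fsym)) > 1e-8) {
    stop("root composition is not reverse-complement symmetric", call. = FALSE)
  }
  setNames(f, dinuc_names())
}

# boundary context probabilities implied by a root composition
.boundary_from_root <- function(root) {
  fCG <- root[[.CG]]
  fC <- sum(root[4L * (2L - 1L) + (1:4)])   # f(C.)
  fG <- sum(root[4L * ((1:4) - 1L) + 3L])   # f(.G)
  c(left = if (fG > 0) fCG / fG else 0,
    right = if (fC > 0) fCG / fC else 0)
}

# Per-branch transition matrices for the boundary closure. The CpG partner
# of an edge position lies outside the observed pair; the closure mixes, at
# the tensor level and with one shared neighbour draw for all branches, the
# no-exposure regime with the full-exposure regimes (hidden left neighbour
# C, hidden right neighbour G). Neighbours are nearly persistent over one
# branch; their drift enters through a per-branch decay factor on the
# exposure matrices. Returns list(P0, PL, PR).
.branch_pmatrices <- function(root, params, boundary = TRUE) {
  params <- as_substitution_params(params)
  Q00 <- build_dinucleotide_generator(params)
  P00 <- transition_probabilities(Q00)
  if (!isTRUE(boundary) || params[["r_CpG"]] <= 0 || root[[.CG]] <= 0) {
    return(list(P0 = P00, PL = P00, PR = P00))
  }
  lam <- -sum(root * Q00[, .CG]) / root[[.CG]]
  fac <- if (abs(lam) > 1e-12) (1 - exp(-lam)) / lam else 1
  fac <- min(max(fac, 0.2), 2)
  PL <- transition_probabilities(
    build_dinucleotide_generator(params, c(left = 1, right = 0)))
  PR <- transition_probabilities(
    build_dinucleotide_generator(params, c(left = 0, right = 1)))
  list(P0 = P00, PL = P00 + fac * (PL - P00), PR = P00 + fac * (PR - P00))
}

# mixture weights over the shared hidden-neighbour state
.closure_weights <- function(root, boundary = TRUE) {
  if (!isTRUE(boundary)) return(c(none = 1, left = 0, right = 0))
  b0 <- .boundary_from_root(root)
  c(none = max(1 - b0[["left"]] - b0[["right"]], 0),
    left = b0[["left"]], right = b0[["right"]])
}

# ---- composite likelihood --------------------------------------------------

# dinucleotide-triple counts (length 4096) for the unambiguous overlapping
# column pairs of a triple window
.window_counts <- function(window) {
  s <- .masked_codes(window)
  count_triples_cpp(s[[1L]], s[[2L]], s[[3L]])
}

#' Composite log-likelihood of a triple alignment window
#'
#' The neighbour-dependent likelihood of a whole window is intractable
#' exactly; following the cluster-approximation family of estimators, the
#' window log-likelihood is a composite sum over overlapping dinucleotide
#' columns (positions i, i+1 both unambiguous in all three species). Each
#' column pair contributes
#' `log sum_a root(a) P_s1(a -> d1) P_s2(a -> d2) P_out(a -> do)`
#' where `a` runs over the 16 ancestral dinucleotides at the internal node of
#' the unrooted 3-taxon tree.
#'
#' @param window A [triple_window()].
#' @param rates List with elements `sister1`, `sister2`, `outgroup`, each a
#'   [substitution_params()] vector.
#' @param root Root dinucleotide composition (see [root_composition()]).
#' @param boundary If `TRUE` (default), close the model over CpG events whose
#'   partner base lies outside the observed pair: each column-pair term
#'   becomes a mixture over the hidden-neighbour state (no exposure / left
#'   neighbour C / right neighbour G, weights from the root composition, one
#'   shared draw for all three branches), with the exposure decaying at the
#'   model-implied drift of the CpG context. `FALSE` gives the literal
#'   within-pair model, which misattributes boundary-straddling CpG events
#'   to the context-free C->T rate.
#' @return The composite log-likelihood (a scalar; each term is a
#'   log-probability, hence <= 0).
#' @export
window_loglikelihood <- function(window, rates, root, boundary = TRUE) {
  counts <- .window_counts(window)
  if (sum(counts) == 0) stop("no unambiguous column pairs in window", call. = FALSE)
  root <- root_composition(root)
  Ps <- lapply(rates[c("sister1", "sister2", "outgroup")], function(p) {
    .branch_pmatrices(root, p, boundary)
  })
  w <- .closure_weights(root, boundary)
  ll <- 0
  cnt <- array(counts, dim = c(16L, 16L, 16L))
  for (dd in 1:16) {
    if (sum(cnt[, , dd]) == 0) next
    p <- matrix(0, 16L, 16L)
    for (s in c("P0", "PL", "PR")) {
      ws <- w[[match(s, c("P0", "PL", "PR"))]]
      if (ws <= 0) next
      v <- root * Ps[[3L]][[s]][, dd]
      p <- p + ws * crossprod(Ps[[1L]][[s]], v * Ps[[2L]][[s]])
    }
    nz <- cnt[, , dd] > 0
    ll <- ll + sum(cnt[, , dd][nz] * log(p[nz]))
  }
  ll
}

# ---- maximum likelihood fit ------------------------------------------------

.LOG_FLOOR <- log(1e-12)

# initial parameter vector (30 values) from pairwise divergences and the
# empirical sister dinucleotide composition
.init_par <- function(window) {
  s <- .masked_codes(window)
  ok <- s[[1L]] > 0L & s[[2L]] > 0L & s[[3L]] > 0L
  mm <- function(a, b) {
    n <- sum(ok)
    if (n == 0) return(0.01)
    max(sum(a[ok] != b[ok]) / n, 1e-4)
  }
  d12 <- mm(s[[1L]], s[[2L]]); d1o <- mm(s[[1L]], s[[3L]]); d2o <- mm(s[[2L]], s[[3L]])
  d1 <- max((d12 + d1o - d2o) / 2, 1e-4)
  d2 <- max((d12 + d2o - d1o) / 2, 1e-4)
  do <- max((d1o + d2o - d12) / 2, 1e-4)
  per_branch <- function(d) log(pmax(c(rep(d / 8, 3), rep(d / 8, 2), d / 4, 2 * d), 1e-6))
  f1 <- .dinuc_freq(s[[1L]]); f2 <- .dinuc_freq(s[[2L]])
  f <- root_composition((f1 + f2) / 2 + 1e-6, symmetrize = TRUE)
  cls <- dinuc_rc_classes()
  reps <- match(1:10, cls)                        # representative dinuc per class
  logits <- log(f[reps[-1L]] / f[reps[1L]])
  c(per_branch(d1), per_branch(d2), per_branch(do), logits)
}

.dinuc_freq <- function(codes) {
  a <- codes[-length(codes)]; b <- codes[-1L]
  ok <- a > 0L & b > 0L
  tabulate(4L * (a[ok] - 1L) + b[ok], nbins = 16L) / max(sum(ok), 1L)
}

.par_to_fit <- function(par) {
  rates <- lapply(0:2, function(k) {
    r <- exp(par[7L * k + 1:7])
    r[r <= 1e-11] <- 0                            # estimates at the floor -> 0
    do.call(substitution_params, as.list(r))
  })
  names(rates) <- c("sister1", "sister2", "outgroup")
  root <- setNames(as.numeric(root_freq_cpp(par[22:30])), dinuc_names())
  list(rates = rates, root = root)
}

#' Estimate lineage-specific substitution rates from a triple alignment
#'
#' Maximises the composite likelihood of [window_loglikelihood()] over the
#' 3 x 7 branch rates (log-parameterised to enforce positivity, floored at
#' 1e-12) and the reverse-complement-symmetric root dinucleotide composition
#' (softmax-parameterised over its 10 symmetry classes). Optimisation uses
#' quasi-Newton L-BFGS-B on a compiled objective, started from
#' divergence-based initial values, with optional random restarts; the fit is
#' deterministic given `seed`.
#'
#' Because the composite likelihood reuses each site in two overlapping column
#' pairs, no likelihood-ratio p-values are derived from it; point estimates
#' are validated by parameter recovery on simulated data.
#'
#' @param window A [triple_window()] (masks already applied if any).
#' @param n_restarts Number of random restarts beyond the data-driven start
#'   (default 3).
#' @param boundary Use the hidden-neighbour boundary closure of
#'   [window_loglikelihood()] (default `TRUE`; recommended -- without it, CpG
#'   events straddling pair boundaries inflate the context-free C->T rate).
#' @param seed Integer seed controlling the restart perturbations.
#' @param control Passed to [stats::optim()] (method `L-BFGS-B`); sensible
#'   defaults are supplied.
#' @return An object of class `triple_fit`: list with `rates` (per-branch
#'   [substitution_params()]), `root`, `logLik`, `n_pairs`, `convergence`,
#'   `boundary`, `window` metadata. Methods: [print.triple_fit()],
#'   [summary.triple_fit()], [coef.triple_fit()], [logLik.triple_fit()],
#'   [simulate.triple_fit()].
#' @export
estimate_branch_rates <- function(window, n_restarts = 3, boundary = TRUE,
                                  seed = 1L, control = list()) {
  counts <- .window_counts(window)
  if (sum(counts) == 0) stop("no unambiguous column pairs in window", call. = FALSE)
  ctrl <- modifyList(list(maxit = 1000L, factr = 1e7), control)
  fn <- function(p) cl_negloglik_cpp(p, counts, isTRUE(boundary))
  gr <- function(p) as.numeric(cl_negloglik_grad_cpp(p, counts, isTRUE(boundary)))
  p0 <- .init_par(window)
  lower <- c(rep(.LOG_FLOOR, 21L), rep(-30, 9L))
  upper <- c(rep(3, 21L), rep(30, 9L))
  starts <- list(pmin(pmax(p0, lower), upper))
  if (n_restarts > 0) {
    perturb <- with_seed(child_seed(seed, 17L), {
      lapply(seq_len(n_restarts), function(i) rnorm(30L, 0, 0.5))
    })
    starts <- c(starts, lapply(perturb, function(e) pmin(pmax(p0 + e, lower), upper)))
  }
  best <- NULL
  conv <- 1L
  for (st in starts) {
    opt <- try(optim(st, fn, gr, method = "L-BFGS-B",
                     lower = lower, upper = upper, control = ctrl), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      conv <- opt$convergence
    }
  }
  if (is.null(best)) stop("optimisation failed from all starts", call. = FALSE)
  est <- .par_to_fit(best$par)
  structure(list(
    rates = est$rates,
    root = est$root,
    logLik = -best$value,
    n_pairs = sum(counts),
    convergence = conv,
    converged = conv == 0L,
    boundary = isTRUE(boundary),
    n_starts = length(starts),
    window = list(chrom = window$chrom, start = window$start, end = window$end,
                  length = length(window$mask)),
    optim = best[c("counts", "message")]
  ), class = "triple_fit")
}

#' @rdname estimate_branch_rates
#' @param x,object A `triple_fit`.
#' @param ... Unused.
#' @export
print.triple_fit <- function(x, ...) {
  cat("Neighbour-dependent substitution model fit (composite ML)\n")
  cat(sprintf("  window: %s:%d-%d, %d column pairs\n",
              x$window$chrom, x$window$start, x$window$end, x$n_pairs))
  cat(sprintf("  log-likelihood: %.2f (%s)\n", x$logLik,
              if (x$converged) "converged" else "NOT converged"))
  print(coef(x), digits = 4)
  invisible(x)
}

#' @rdname estimate_branch_rates
#' @export
coef.triple_fit <- function(object, ...) {
  do.call(rbind, lapply(object$rates, unclass))
}

#' @rdname estimate_branch_rates
#' @export
logLik.triple_fit <- function(object, ...) {
  structure(object$logLik, df = 30L, nobs = object$n_pairs, class = "logLik")
}

#' @rdname estimate_branch_rates
#' @export
summary.triple_fit <- function(object, ...) {
  pw <- do.call(rbind, lapply(object$rates, pathway_rates))
  eq <- lapply(object$rates, function(p) {
    u <- pathway_rates(p)
    c(gc_star = gc_star(u[["u_WS"]], u[["u_SW"]]),
      gc_star_cpg = gc_star_cpg(p))
  })
  out <- list(fit = object, pathway = pw, equilibrium = do.call(rbind, eq))
  class(out) <- "summary.triple_fit"
  out
}

#' @export
print.summary.triple_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPathway rates (per nucleotide of origin):\n")
  print(x$pathway, digits = 4)
  cat("\nEquilibrium GC content (per branch):\n")
  print(x$equilibrium, digits = 4)
  invisible(x)
}

#' Simulate alignments from a fitted model
#'
#' Draws a root sequence from the fitted root dinucleotide composition (as a
#' first-order Markov chain) and evolves it down the three fitted branches,
#' giving parametric-bootstrap replicates of the window.
#'
#' @param object A `triple_fit`.
#' @param nsim Number of replicate windows.
#' @param seed Integer seed.
#' @param length Sequence length (defaults to the fitted window's length).
#' @param ... Unused.
#' @return A list of [triple_window()] objects (length `nsim`).
#' @export
simulate.triple_fit <- function(object, nsim = 1, seed = 1L, length = NULL, ...) {
  L <- if (is.null(length)) object$window$length else length
  f <- matrix(object$root, 4, 4, byrow = TRUE)    # f[a, b]
  marg <- rowSums(f)
  P <- sweep(f, 1, pmax(marg, 1e-300), "/")
  lapply(seq_len(nsim), function(i) {
    with_seed(child_seed(seed, i), {
      root <- markov_chain_cpp(P, L, marg)
      seqs <- lapply(object$rates, function(p) {
        evolve_sequence_cpp(root, base_rate_matrix(p), p[["r_CpG"]], 1)
      })
      triple_window(seqs[[1L]], seqs[[2L]], seqs[[3L]],
                    chrom = object$window$chrom, start = 0L)
    })
  })
}

#' Aggregate branch rates into W/S substitution pathways
#'
#' Pools the seven per-branch rates into the classic weak/strong pathway
#' rates: `u_WS = r_AC + r_AG` (W->S), `u_SW = r_CA + r_CT` (S->W, with
#' CpG-context deamination excluded so that S->W variation is not driven by
#' local CpG content and methylation), `u_SS = r_CG`, `u_WW = r_AT`, and
#' passes the CpG channel through as `u_CpG`.
#'
#' @param params A [substitution_params()] vector.
#' @return Named numeric vector `u_WS`, `u_SW`, `u_SS`, `u_WW`, `u_CpG`.
#' @examples
#' pathway_rates(substitution_params(r_CA = 0.01, r_CT = 0.04, r_CpG = 0.4))
#' @export
pathway_rates <- function(params) {
  p <- as_substitution_params(params)
  c(u_WS = p[["r_AC"]] + p[["r_AG"]],
    u_SW = p[["r_CA"]] + p[["r_CT"]],
    u_SS = p[["r_CG"]],
    u_WW = p[["r_AT"]],
    u_CpG = p[["r_CpG"]])
}
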