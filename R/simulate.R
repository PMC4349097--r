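# Synthetic study generator: root sequences with controlled GC and CpG
# enrichment, neighbour-dependent evolution along the 3-taxon tree, per-CpG
# bisulfite-style read counts, recombination maps, and the full on-disk
# dataset with a truth table. All distributions here are stand-ins chosen to
# match the summary statistics of the real study (the source data are
# observational and carry no generative model); the truth table labels them
# as synthetic.

#' Configuration of a synthetic study
#'
#' Defaults mirror the study conditions: 1-Mb windows, root composition with
#' GC 0.4034 and CpG observed/expected 0.21, genome-wide mean sperm CpG
#' methylation 0.41 (window means spread over roughly 0.2--0.55), read
#' coverage 28X, sister-branch divergences of a few percent with
#' `r_CpG = 10 x r_CT`, and a fully proportional methylation coupling.
#'
#' The coupling model: window `w` with methylation level `m_w` evolves with an
#' effective CpG deamination rate
#' `r_CpG(w) = r_CpG * (1 - coupling + coupling * m_w / mean_methylation)`
#' on every branch, i.e. `coupling = 1` makes the rate proportional to the
#' methylation level (deamination happens at methylated CpGs only) and
#' `coupling = 0` removes the dependence.
#'
#' @param n_windows Number of windows.
#' @param window_length Window length in bp (>= 1000).
#' @param root_gc Mean root GC fraction in (0, 1).
#' @param root_gc_sd Between-window standard deviation of the root GC
#'   fraction (Beta-distributed window means; default 0.04, reproducing the
#'   observed spread of window GC, roughly 0.32--0.55). Set 0 for
#'   homogeneous windows.
#' @param root_cpg_enrichment Mean multiplier on the root CpG dinucleotide
#'   frequency relative to `f(C) * f(G)` (0 forbids CpG).
#' @param root_cpg_enrichment_logsd Between-window log-scale standard
#'   deviation of the CpG enrichment (log-normal; default 0.25, giving the
#'   observed CpG\[o/e\] spread of roughly 0.12--0.42). Set 0 for
#'   homogeneous windows.
#' @param branch_params List `sister1`, `sister2`, `outgroup` of
#'   [substitution_params()].
#' @param mean_methylation Mean of the per-window methylation level
#'   distribution.
#' @param methylation_concentration Beta concentration of window means (larger
#'   = tighter spread).
#' @param site_concentration Beta concentration of per-site statuses around
#'   the window mean (overdispersion of single CpGs).
#' @param coupling Methylation -> CpG-rate coupling in `[0, 1]` (see above).
#' @param coverage_mean Mean reads per CpG (>= 1).
#' @param recomb_shape,recomb_scale Gamma parameters of the per-window
#'   recombination rate (cM/Mb).
#' @param seed Integer master seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_windows = 50,
                              window_length = 1e6,
                              root_gc = 0.4034,
                              root_gc_sd = 0.04,
                              root_cpg_enrichment = 0.21,
                              root_cpg_enrichment_logsd = 0.25,
                              branch_params = list(
                                sister1 = substitution_params(0.004, 0.012, 0.004,
                                                              0.006, 0.004, 0.016, 0.16),
                                sister2 = substitution_params(0.004, 0.012, 0.004,
                                                              0.006, 0.004, 0.016, 0.16),
                                outgroup = substitution_params(0.012, 0.036, 0.012,
                                                               0.018, 0.012, 0.048, 0.48)
                              ),
                              mean_methylation = 0.41,
                              methylation_concentration = 60,
                              site_concentration = 10,
                              coupling = 1,
                              coverage_mean = 28,
                              recomb_shape = 1.5,
                              recomb_scale = 0.6,
                              seed = 1L) {
  if (window_length < 1000) stop("window_length must be >= 1000", call. = FALSE)
  if (coverage_mean < 1) stop("coverage_mean must be >= 1", call. = FALSE)
  if (root_gc <= 0 || root_gc >= 1) stop("root_gc must be in (0, 1)", call. = FALSE)
  if (root_cpg_enrichment < 0) stop("root_cpg_enrichment must be >= 0", call. = FALSE)
  stopifnot_prob(c(mean_methylation, coupling), "mean_methylation and coupling")
  branch_params <- lapply(branch_params, as_substitution_params)
  stopifnot(all(c("sister1", "sister2", "outgroup") %in% names(branch_params)))
  if (root_gc_sd < 0 || root_cpg_enrichment_logsd < 0) {
    stop("between-window spread parameters must be >= 0", call. = FALSE)
  }
  structure(list(
    n_windows = as.integer(n_windows), window_length = as.integer(window_length),
    root_gc = root_gc, root_gc_sd = root_gc_sd,
    root_cpg_enrichment = root_cpg_enrichment,
    root_cpg_enrichment_logsd = root_cpg_enrichment_logsd,
    branch_params = branch_params,
    mean_methylation = mean_methylation,
    methylation_concentration = methylation_concentration,
    site_concentration = site_concentration,
    coupling = coupling, coverage_mean = coverage_mean,
    recomb_shape = recomb_shape, recomb_scale = recomb_scale,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# Stationary pair-frequency table F (4x4) with marginals pi on both axes and
# F[C, G] pinned at enrichment * pi_C * pi_G; the free cells are fitted by
# iterative proportional scaling. Returns the Markov transition matrix
# P(y | x) = F[x, y] / pi_x, whose stationary law is pi and whose expected
# dinucleotide frequencies equal F.
.root_transition <- function(root_gc, cpg_enrichment) {
  pi <- c((1 - root_gc) / 2, root_gc / 2, root_gc / 2, (1 - root_gc) / 2)
  fixed <- cpg_enrichment * pi[2L] * pi[3L]
  if (fixed > min(pi[2L], pi[3L])) {
    stop("root_cpg_enrichment too large for the requested GC content", call. = FALSE)
  }
  F <- outer(pi, pi)
  free <- matrix(TRUE, 4, 4); free[2L, 3L] <- FALSE
  F[2L, 3L] <- fixed
  for (it in 1:500) {
    rs <- rowSums(F)
    for (x in 1:4) {
      tgt <- pi[x] - if (x == 2L) fixed else 0
      cur <- sum(F[x, free[x, ]])
      F[x, free[x, ]] <- F[x, free[x, ]] * tgt / cur
    }
    cs <- colSums(F)
    for (y in 1:4) {
      tgt <- pi[y] - if (y == 3L) fixed else 0
      cur <- sum(F[free[, y], y])
      F[free[, y], y] <- F[free[, y], y] * tgt / cur
    }
    if (max(abs(rowSums(F) - pi), abs(colSums(F) - pi)) < 1e-14) break
  }
  sweep(F, 1, pi, "/")
}

.simulate_root_int <- function(length, root_gc, cpg_enrichment) {
  P <- .root_transition(root_gc, cpg_enrichment)
  pi <- c((1 - root_gc) / 2, root_gc / 2, root_gc / 2, (1 - root_gc) / 2)
  markov_chain_cpp(P, length, pi)
}

#' Simulate a root sequence with controlled GC and CpG enrichment
#'
#' Samples a first-order Markov chain whose stationary single-site law has the
#' requested GC fraction and whose CpG dinucleotide frequency equals
#' `cpg_enrichment * f(C) * f(G)` exactly in expectation (the remaining pair
#' frequencies are fitted by iterative proportional scaling to preserve the
#' marginals).
#'
#' @param length Sequence length (>= 2).
#' @param root_gc Target GC fraction in (0, 1).
#' @param cpg_enrichment CpG observed/expected multiplier (0 = no CpG at all).
#' @param seed Integer seed (the draw is deterministic given it).
#' @return A character string over A, C, G, T.
#' @export
simulate_root_sequence <- function(length, root_gc, cpg_enrichment = 1, seed = 1L) {
  if (length < 2) stop("length must be >= 2 (no dinucleotides otherwise)", call. = FALSE)
  if (root_gc <= 0 || root_gc >= 1) stop("root_gc must be in (0, 1)", call. = FALSE)
  codes <- with_seed(seed, .simulate_root_int(length, root_gc, cpg_enrichment))
  decode_seq(codes)
}

.evolve_int <- function(codes, params, duration = 1) {
  params <- as_substitution_params(params)
  evolve_sequence_cpp(codes, base_rate_matrix(params), params[["r_CpG"]], duration)
}

#' Evolve a sequence under the neighbour-dependent substitution process
#'
#' Exact event-driven (thinned) continuous-time simulation: every site mutates
#' at the six context-free exchange rates and, additionally, a C directly
#' followed by G mutates to T (and, strand-symmetrically, a G directly
#' preceded by C mutates to A) at rate `r_CpG`. The neighbour context is
#' re-evaluated after every event; sequence ends have no partner and are
#' treated as non-CpG context. Rates are expected substitutions per site for
#' the whole branch (duration 1).
#'
#' @param seq Character string or integer codes.
#' @param params A [substitution_params()] vector.
#' @param seed Integer seed.
#' @param duration Branch duration (default 1).
#' @return The descendant sequence, same representation as the input.
#' @export
evolve_sequence <- function(seq, params, seed = 1L, duration = 1) {
  chr <- is.character(seq)
  codes <- encode_seq(seq)
  if (any(codes == 0L)) stop("sequence must contain only A, C, G, T", call. = FALSE)
  out <- with_seed(seed, .evolve_int(codes, params, duration))
  if (chr) decode_seq(out) else out
}

# One window's generating state: methylation level, effective branch rates,
# recombination rate. Deterministic given (config, window_index).
.window_state <- function(config, window_index) {
  with_seed(child_seed(config$seed, window_index), {
    m <- config$mean_methylation
    k <- config$methylation_concentration
    level <- if (m <= 0 || m >= 1) m else rbeta(1, m * k, (1 - m) * k)
    fac <- 1 - config$coupling + config$coupling * level / m
    fac <- max(fac, 0)
    params <- lapply(config$branch_params, function(p) {
      p[["r_CpG"]] <- p[["r_CpG"]] * fac
      as_substitution_params(p)
    })
    recomb <- rgamma(1, shape = config$recomb_shape, scale = config$recomb_scale)
    gc <- config$root_gc
    if (config$root_gc_sd > 0) {
      kb <- gc * (1 - gc) / config$root_gc_sd^2 - 1
      gc <- min(max(rbeta(1, gc * kb, (1 - gc) * kb), 0.2), 0.7)
    }
    enr <- config$root_cpg_enrichment
    if (enr > 0 && config$root_cpg_enrichment_logsd > 0) {
      enr <- exp(rnorm(1, log(enr), config$root_cpg_enrichment_logsd))
    }
    list(level = level, rcpg_factor = fac, params = params, recomb = recomb,
         root_gc = gc, root_cpg_enrichment = enr)
  })
}

.simulate_window <- function(config, window_index) {
  st <- .window_state(config, window_index)
  win <- with_seed(child_seed(config$seed, 100000L + window_index), {
    root <- .simulate_root_int(config$window_length, st$root_gc,
                               st$root_cpg_enrichment)
    seqs <- lapply(st$params, function(p) .evolve_int(root, p))
    triple_window(seqs$sister1, seqs$sister2, seqs$outgroup,
                  chrom = sprintf("win%04d", window_index), start = 0L)
  })
  c(st, list(window = win, index = window_index))
}

#' Simulate one triple-alignment window
#'
#' Draws a root sequence at the internal node of the unrooted 3-taxon tree
#' `((sister1, sister2), outgroup)` and evolves it independently down the
#' three branches under the configured rates (with the window's effective
#' methylation-coupled CpG rate). No indels are simulated, so columns align
#' trivially and the mask starts all-`FALSE`.
#'
#' @param config A [simulation_config()].
#' @param window_index 1-based window index (determines the RNG stream).
#' @return A [triple_window()]; the generating parameters are attached as
#'   attribute `truth` (list with `level`, `rcpg_factor`, `params`).
#' @export
simulate_triple_alignment <- function(config, window_index = 1L) {
  sim <- .simulate_window(config, window_index)
  win <- sim$window
  attr(win, "truth") <- sim[c("level", "rcpg_factor", "params", "recomb",
                              "root_gc", "root_cpg_enrichment")]
  win
}

#' Simulate per-CpG bisulfite read counts for a window
#'
#' One record per CpG dinucleotide of the reference (sister1) sequence: total
#' coverage is 1 + Poisson(`coverage_mean` - 1) (so the mean is exact and
#' every record usable), the site status is drawn from a Beta distribution
#' around `mean_level` (concentration `site_concentration`), and the
#' methylated count is Binomial(total, status).
#'
#' @param window A [triple_window()] (its `sister1` is scanned for CpGs), or
#'   a bare sequence.
#' @param mean_level Window mean methylation level in `[0, 1]`.
#' @param coverage_mean Mean reads per CpG (>= 1).
#' @param seed Integer seed.
#' @param site_concentration Beta concentration of site statuses (default 10).
#' @return Data frame with columns `chrom`, `position` (0-based C
#'   coordinate), `strand`, `count_methylated`, `count_total`.
#' @export
simulate_methylation_counts <- function(window, mean_level, coverage_mean = 28,
                                        seed = 1L, site_concentration = 10) {
  stopifnot_prob(mean_level, "mean_level")
  if (inherits(window, "triple_window")) {
    codes <- window$seqs$sister1
    chrom <- window$chrom
    offset <- window$start
  } else {
    codes <- encode_seq(window)
    chrom <- "chr"
    offset <- 0L
  }
  pos <- which(codes[-length(codes)] == 2L & codes[-1L] == 3L)
  n <- length(pos)
  if (n == 0) {
    return(data.frame(chrom = character(), position = integer(),
                      strand = character(), count_methylated = integer(),
                      count_total = integer()))
  }
  with_seed(seed, {
    total <- 1L + rpois(n, max(coverage_mean - 1, 0))
    status <- if (mean_level <= 0 || mean_level >= 1) rep(mean_level, n) else
      rbeta(n, mean_level * site_concentration, (1 - mean_level) * site_concentration)
    meth <- rbinom(n, total, status)
    data.frame(chrom = chrom, position = offset + pos - 1L, strand = "+",
               count_methylated = meth, count_total = total,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a full synthetic study to disk
#'
#' Writes everything the pipeline ingests: one multi-FASTA per window
#' (records `sister1`, `sister2`, `outgroup`) under `alignments/`, a
#' methylation count table `methylation.tsv`, a BED-like recombination map
#' `recombination.tsv` (chrom, start, end, rate in cM/Mb) and a `truth.tsv`
#' with the generating parameters per window (window methylation level,
#' effective CpG rate, branch rates, true equilibrium GC) for recovery tests.
#' Windows vary in methylation level, and with `coupling > 0` the effective
#' CpG->CpA/TpG rate increases with it, reproducing the structure behind the
#' positive rate--methylation partial correlation. Byte-identical outputs for
#' a fixed config.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created; must be writable).
#' @return Invisibly, a list with the output `paths` and the `truth` data
#'   frame.
#' @export
simulate_study <- function(config, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir, call. = FALSE)
  aln_dir <- file.path(out_dir, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  meth <- vector("list", config$n_windows)
  recomb <- vector("list", config$n_windows)
  truth <- vector("list", config$n_windows)
  for (i in seq_len(config$n_windows)) {
    sim <- .simulate_window(config, i)
    win <- sim$window
    fa <- Biostrings::DNAStringSet(vapply(win$seqs, decode_seq, character(1)))
    names(fa) <- names(win$seqs)
    Biostrings::writeXStringSet(fa, file.path(aln_dir, sprintf("%s.fa", win$chrom)))
    meth[[i]] <- simulate_methylation_counts(
      win, sim$level, config$coverage_mean,
      seed = child_seed(config$seed, 200000L + i),
      site_concentration = config$site_concentration)
    recomb[[i]] <- data.frame(chrom = win$chrom, start = 0L,
                              end = config$window_length, rate = sim$recomb)
    p1 <- sim$params$sister1
    u <- pathway_rates(p1)
    truth[[i]] <- data.frame(
      chrom = win$chrom, window = i,
      methylation_level = sim$level,
      rcpg_factor = sim$rcpg_factor,
      root_gc = sim$root_gc,
      root_cpg_enrichment = sim$root_cpg_enrichment,
      r_CpG_effective = p1[["r_CpG"]],
      t(setNames(as.numeric(p1), paste0("true_", .param_names))),
      recombination_rate = sim$recomb,
      true_gc_star = gc_star(u[["u_WS"]], u[["u_SW"]]),
      true_gc_star_cpg = as.numeric(gc_star_cpg(p1)),
      generative_model = "synthetic-stand-in",
      stringsAsFactors = FALSE)
  }
  paths <- list(
    alignments = aln_dir,
    methylation = file.path(out_dir, "methylation.tsv"),
    recombination = file.path(out_dir, "recombination.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write.table(do.call(rbind, meth), paths$methylation, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(do.call(rbind, recomb), paths$recombination, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(do.call(rbind, truth), paths$truth, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(paths = paths, truth = do.call(rbind, truth)))
}
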