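# End-to-end orchestration: read a dataset (as written by simulate_study() or
# assembled from real files in the same layout), window -> mask -> filter ->
# composition -> methylation -> recombination -> rate estimation ->
# equilibria -> regressions, with a provenance manifest.

.read_alignment_dir <- function(aln_dir) {
  files <- sort(list.files(aln_dir, pattern = "\\.fa(sta)?$", full.names = TRUE))
  if (length(files) == 0) stop("no FASTA alignments found in ", aln_dir, call. = FALSE)
  lapply(files, function(f) {
    fa <- Biostrings::readDNAStringSet(f)
    if (length(fa) != 3) stop("expected 3 records in ", f, call. = FALSE)
    nm <- names(fa)
    want <- c("sister1", "sister2", "outgroup")
    if (!all(want %in% nm)) nm <- want else fa <- fa[want]
    triple_window(as.character(fa[[1]]), as.character(fa[[2]]), as.character(fa[[3]]),
                  chrom = sub("\\.fa(sta)?$", "", basename(f)), start = 0L)
  })
}

#' Run the full analysis pipeline on an on-disk dataset
#'
#' Expects the layout written by [simulate_study()]: `alignments/*.fa` (three
#' records per window), `methylation.tsv`, `recombination.tsv`, and
#' optionally `masks.bed`. Applies masks and the unambiguous-site filter,
#' computes per-window composition, methylation level/frequency and
#' recombination rate, fits the substitution model per window, derives
#' pathway rates, GC*, GC*_CpG and delta-GC, and runs the regression stage:
#' the CpG-rate model (CpG->CpA/TpG rate ~ methylation level + transformed
#' recombination rate) and the equilibrium models (GC*_CpG and delta-GC ~
#' methylation frequency + CpG\[o/e\] + transformed recombination rate), a
#' Pearson matrix of those predictors, and PCR decompositions.
#'
#' @param input_dir Dataset directory.
#' @param out_dir Output directory for the TSV reports and manifest
#'   (default: `file.path(input_dir, "results")`).
#' @param min_unambiguous Unambiguous-site filter threshold (default 10,000).
#' @param n_restarts Random restarts per window fit (default 1; the
#'   divergence-based start is reliable, restarts mainly guard against rare
#'   local optima).
#' @param boundary Boundary closure in the likelihood (default `TRUE`).
#' @param seed Integer seed (restart perturbations).
#' @return Invisibly, a list with `features` (per-window data frame),
#'   `fits`, regression objects (`mlr_rate`, `mlr_gc_star_cpg`,
#'   `mlr_delta_gc`, `pearson`, `pcr_gc_star_cpg`, `pcr_delta_gc`) and the
#'   output `paths`. Reports are also written as TSV plus `manifest.json`.
#' @export
run_pipeline <- function(input_dir, out_dir = file.path(input_dir, "results"),
                         min_unambiguous = 10000, n_restarts = 1,
                         boundary = TRUE, seed = 1L) {
  meth_path <- file.path(input_dir, "methylation.tsv")
  rec_path <- file.path(input_dir, "recombination.tsv")
  mask_path <- file.path(input_dir, "masks.bed")
  windows <- .read_alignment_dir(file.path(input_dir, "alignments"))
  masks <- if (file.exists(mask_path)) read_bed(mask_path) else NULL
  windows <- lapply(windows, apply_masks, mask_intervals = masks)
  windows <- filter_windows(windows, min_unambiguous)
  if (length(windows) == 0) {
    stop("pipeline aborted: no window passes the unambiguous-site filter (",
         min_unambiguous, ")", call. = FALSE)
  }
  meth <- read_methylation_table(meth_path)
  rec <- read_bed(rec_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  fits <- vector("list", length(windows))
  rows <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    comp <- composition(w)
    wm <- meth[meth$chrom == w$chrom &
                 meth$position >= w$start & meth$position < w$end, , drop = FALSE]
    # restrict to CpGs at unmasked positions of the reference
    if (nrow(wm) > 0) {
      rel <- wm$position - w$start + 1L
      keep <- !w$mask[rel] & !w$mask[pmin(rel + 1L, length(w$mask))]
      wm <- wm[keep, , drop = FALSE]
    }
    level <- window_methylation_level(wm)
    fit <- tryCatch(
      estimate_branch_rates(w, n_restarts = n_restarts, boundary = boundary,
                            seed = child_seed(seed, i)),
      error = function(e) {
        warning(sprintf("window %s: rate estimation failed (%s); excluded",
                        w$chrom, conditionMessage(e)))
        NULL
      })
    fits[[i]] <- fit
    p1 <- if (is.null(fit)) NULL else fit$rates$sister1
    u <- if (is.null(p1)) rep(NA_real_, 5) else pathway_rates(p1)
    gcs <- if (is.null(p1)) NA_real_ else gc_star(u[["u_WS"]], u[["u_SW"]])
    gcsc <- if (is.null(p1)) NA_real_ else as.numeric(gc_star_cpg(p1))
    rows[[i]] <- data.frame(
      chrom = w$chrom, start = w$start, end = w$end,
      n_unambiguous = n_unambiguous(w),
      gc_content = comp$gc_content, cpg_content = comp$cpg_content,
      cpg_oe = comp$cpg_oe,
      methylation_level = level,
      methylation_frequency = methylation_frequency(level, comp$cpg_content),
      recombination_rate = window_recombination_rate(w, rec),
      u_WS = u[[1]], u_SW = u[[2]], u_SS = u[[3]], u_WW = u[[4]],
      u_CpG = u[[5]],
      gc_star = gcs, gc_star_cpg = gcsc,
      delta_gc = delta_gc(gcsc, comp$gc_content),
      logLik = if (is.null(fit)) NA_real_ else fit$logLik,
      converged = if (is.null(fit)) FALSE else fit$converged,
      stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, rows)
  features$recomb_t <- transform_recombination(features$recombination_rate)

  try_stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      warning(sprintf("regression stage '%s' skipped: %s", what,
                      conditionMessage(e)))
      NULL
    })
  }
  mlr_rate <- try_stage("u_CpG MLR", mlr_partial(
    features[, c("methylation_level", "recomb_t")], features$u_CpG))
  Xeq <- features[, c("methylation_frequency", "cpg_oe", "recomb_t")]
  mlr_gcsc <- try_stage("GC*_CpG MLR", mlr_partial(Xeq, features$gc_star_cpg))
  mlr_dgc <- try_stage("delta-GC MLR", mlr_partial(Xeq, features$delta_gc))
  pears <- try_stage("Pearson matrix", pearson_matrix(Xeq))
  pcr_gcsc <- try_stage("GC*_CpG PCR", pcr(Xeq, features$gc_star_cpg))
  pcr_dgc <- try_stage("delta-GC PCR", pcr(Xeq, features$delta_gc))

  paths <- list(
    features = file.path(out_dir, "features.tsv"),
    rates = file.path(out_dir, "rates.tsv"),
    regressions = file.path(out_dir, "regressions.tsv"),
    pcr = file.path(out_dir, "pcr.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write.table(features, paths$features, sep = "\t", quote = FALSE, row.names = FALSE)
  rates_tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    if (is.null(fits[[i]])) return(NULL)
    co <- coef(fits[[i]])
    data.frame(chrom = windows[[i]]$chrom,
               branch = rownames(co), as.data.frame(co),
               logLik = fits[[i]]$logLik, converged = fits[[i]]$converged,
               row.names = NULL)
  }))
  write.table(rates_tab, paths$rates, sep = "\t", quote = FALSE, row.names = FALSE)
  mlrs <- list(u_CpG = mlr_rate, gc_star_cpg = mlr_gcsc, delta_gc = mlr_dgc)
  reg_tab <- do.call(rbind, lapply(names(mlrs), function(nm) {
    m <- mlrs[[nm]]
    if (is.null(m)) return(NULL)
    cbind(model = nm, m$partial, r_squared = m$r.squared, n = m$n)
  }))
  if (!is.null(reg_tab)) {
    write.table(reg_tab, paths$regressions, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  pcrs <- list(gc_star_cpg = pcr_gcsc, delta_gc = pcr_dgc)
  pcr_tab <- do.call(rbind, lapply(names(pcrs), function(nm) {
    p <- pcrs[[nm]]
    if (is.null(p)) return(NULL)
    data.frame(model = nm, pc = colnames(p$loadings),
               variance_share = p$variance_share, p_value = p$p_value,
               t(p$contribution), row.names = NULL)
  }))
  if (!is.null(pcr_tab)) {
    write.table(pcr_tab, paths$pcr, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "gcstar",
    version = as.character(utils::packageVersion("gcstar")),
    seed = seed,
    min_unambiguous = min_unambiguous,
    n_restarts = n_restarts,
    boundary = boundary,
    n_windows_in = length(fits),
    n_windows_used = sum(features$converged),
    inputs = as.list(tools::md5sum(c(meth_path, rec_path)))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(features = features, fits = fits,
                 mlr_rate = mlr_rate, mlr_gc_star_cpg = mlr_gcsc,
                 mlr_delta_gc = mlr_dgc, pearson = pears,
                 pcr_gc_star_cpg = pcr_gcsc, pcr_delta_gc = pcr_dgc,
                 paths = paths))
}
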