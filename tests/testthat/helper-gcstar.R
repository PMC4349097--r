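# shared helpers: small random parameter draws and toy alignments

rand_params <- function(seed, scale = 0.05, rcpg = NULL) {
  set.seed(seed)
  r <- runif(6, 0.2, 1) * scale
  if (is.null(rcpg)) rcpg <- runif(1, 0.5, 2) * scale * 5
  substitution_params(r[1], r[2], r[3], r[4], r[5], r[6], rcpg)
}

rand_root <- function(seed) {
  set.seed(seed)
  root_composition(runif(16, 0.2, 1), symmetrize = TRUE)
}

# brute-force composite log-likelihood: explicit loop over column pairs and
# the 16 ancestral dinucleotides, independent of the vectorised implementation
brute_loglik <- function(window, rates, root, boundary = TRUE) {
  Ps <- lapply(rates[c("sister1", "sister2", "outgroup")], function(p) {
    gcstar:::.branch_pmatrices(root, p, boundary)
  })
  w <- gcstar:::.closure_weights(root, boundary)
  s <- gcstar:::.masked_codes(window)
  di <- function(x, i) 4L * (x[i] - 1L) + x[i + 1L]
  ll <- 0
  for (i in seq_len(length(window$mask) - 1L)) {
    codes <- c(s[[1]][i], s[[1]][i + 1], s[[2]][i], s[[2]][i + 1],
               s[[3]][i], s[[3]][i + 1])
    if (any(codes < 1L)) next
    term <- 0
    for (k in 1:3) {                 # hidden-neighbour regimes
      if (w[[k]] <= 0) next
      mat <- c("P0", "PL", "PR")[k]
      for (a in 1:16) {
        term <- term + w[[k]] * root[a] * Ps[[1]][[mat]][a, di(s[[1]], i)] *
          Ps[[2]][[mat]][a, di(s[[2]], i)] * Ps[[3]][[mat]][a, di(s[[3]], i)]
      }
    }
    ll <- ll + log(term)
  }
  unname(ll)
}

count_cpg <- function(seq) {
  codes <- gcstar:::encode_seq(seq)
  sum(codes[-length(codes)] == 2L & codes[-1L] == 3L)
}

rel_err <- function(est, truth) abs(est - truth) / truth
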