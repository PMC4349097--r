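# dinucleotide generator, transition probabilities, composite likelihood and
# the ML fitter

test_that("the generator follows the single-change construction rule", {
  p <- substitution_params(r_CT = 0.01, r_CpG = 0.1)
  Q <- build_dinucleotide_generator(p)
  expect_equal(Q["CG", "TG"], 0.11)
  expect_equal(Q["CG", "CA"], 0.11)   # G->A reading of the same deamination
  expect_equal(Q["CA", "TA"], 0.01)
  # two-position changes are impossible
  expect_equal(Q["AA", "CC"], 0)

  expect_true(all(build_dinucleotide_generator(substitution_params()) == 0))

  for (seed in 1:4) {
    Qr <- build_dinucleotide_generator(rand_params(seed))
    expect_lt(max(abs(rowSums(Qr))), 1e-14)
    expect_true(all(Qr - diag(diag(Qr)) >= 0))
  }
})

test_that("R and compiled generators agree, with and without boundary terms", {
  for (seed in 1:3) {
    p <- rand_params(seed)
    b <- c(left = 0.04, right = 0.05)
    expect_equal(unname(build_dinucleotide_generator(p)),
                 unname(gcstar:::dinuc_generator_cpp(unclass(p), 0, 0)))
    expect_equal(unname(build_dinucleotide_generator(p, b)),
                 unname(gcstar:::dinuc_generator_cpp(unclass(p), 0.04, 0.05)))
  }
})

test_that("transition probabilities are a stochastic matrix exponential", {
  expect_equal(transition_probabilities(build_dinucleotide_generator(substitution_params())),
               diag(16), ignore_attr = TRUE)
  p <- rand_params(5)
  Q <- build_dinucleotide_generator(p)
  P <- transition_probabilities(Q)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  expect_true(all(P >= 0))
  # small-duration limit: P ~ I + Q t with O(t^2) error
  t <- 1e-4
  Pt <- transition_probabilities(Q, duration = t)
  expect_lt(max(abs(Pt - diag(16) - Q * t)), 16 * max(abs(Q))^2 * t^2)
})

test_that("composite likelihood equals brute-force ancestor enumeration", {
  set.seed(71)
  for (k in 1:5) {
    rates <- list(sister1 = rand_params(k), sister2 = rand_params(k + 10),
                  outgroup = rand_params(k + 20, scale = 0.1))
    root <- rand_root(k + 30)
    n <- sample(3:8, 1)
    mk <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
    w <- triple_window(mk(), mk(), mk())
    for (boundary in c(TRUE, FALSE)) {
      expect_equal(window_loglikelihood(w, rates, root, boundary = boundary),
                   brute_loglik(w, rates, root, boundary = boundary),
                   tolerance = 1e-12)
    }
  }
})

test_that("composite likelihood has its closed forms and additivity", {
  s <- "ACGTTGCA"
  w <- triple_window(s, s, s)
  zero <- list(sister1 = substitution_params(), sister2 = substitution_params(),
               outgroup = substitution_params())
  root <- root_composition(gcstar:::.dinuc_freq(gcstar:::encode_seq(s)) + 1e-9,
                           symmetrize = TRUE)
  ll <- window_loglikelihood(w, zero, root, boundary = FALSE)
  codes <- gcstar:::encode_seq(s)
  din <- 4L * (codes[-length(codes)] - 1L) + codes[-1L]
  expect_equal(ll, sum(log(root[din])), tolerance = 1e-12)
  expect_lte(ll, 0)

  rates <- list(sister1 = rand_params(1), sister2 = rand_params(2),
                outgroup = rand_params(3))
  rr <- rand_root(4)
  w1 <- triple_window("ACGTAAC", "ACGTAGC", "ATGTAAC")
  # concatenating a window with itself doubles every pair count except the
  # junction pair, so compare against explicit duplication of the counts
  ll1 <- window_loglikelihood(w1, rates, rr)
  w2 <- triple_window(strrep("ACGTAAC", 2), strrep("ACGTAGC", 2), strrep("ATGTAAC", 2))
  wj <- triple_window("CA", "CA", "CA")   # the junction columns
  expect_equal(2 * ll1 + window_loglikelihood(wj, rates, rr),
               window_loglikelihood(w2, rates, rr), tolerance = 1e-10)
})

test_that("the compiled objective matches the R likelihood path", {
  set.seed(81)
  cfg <- simulation_config(n_windows = 1, window_length = 5000, seed = 81)
  w <- simulate_triple_alignment(cfg, 1)
  p <- lapply(1:3, function(k) rand_params(k, scale = 0.03))
  names(p) <- c("sister1", "sister2", "outgroup")
  root <- rand_root(9)
  cls <- dinuc_rc_classes()
  par <- c(log(unlist(lapply(p, unclass), use.names = FALSE)),
           log(root[match(2:10, cls)] / root[match(1, cls)]))
  counts <- gcstar:::.window_counts(w)
  for (boundary in c(TRUE, FALSE)) {
    expect_equal(-gcstar:::cl_negloglik_cpp(par, counts, boundary),
                 window_loglikelihood(w, p, root, boundary = boundary),
                 tolerance = 1e-8)
  }
})

test_that("pathway rates aggregate the exchanges with CpG kept separate", {
  expect_equal(pathway_rates(substitution_params(r_AC = 0.01, r_AG = 0.03))[["u_WS"]],
               0.04)
  u <- pathway_rates(substitution_params(r_CA = 0.01, r_CT = 0.04, r_CpG = 0.4))
  expect_equal(u[["u_SW"]], 0.05)   # CpG channel excluded
  expect_equal(u[["u_CpG"]], 0.4)
  rho <- 0.007
  u2 <- pathway_rates(substitution_params(rho, rho, rho, rho, rho, rho, 0))
  expect_equal(u2[["u_WS"]], u2[["u_SW"]])
  expect_equal(u2[["u_WS"]], 2 * rho)
})

test_that("fits recover the truth and shrink with window length", {
  lengths <- c(3e4, 1.2e5, 4.8e5)
  errs <- sapply(seq_along(lengths), function(i) {
    cfg <- simulation_config(n_windows = 1, window_length = lengths[i], seed = 90)
    w <- simulate_triple_alignment(cfg, 1)
    fit <- estimate_branch_rates(w, n_restarts = 0)
    truth <- attr(w, "truth")$params
    sqrt(mean(unlist(lapply(names(truth), function(br)
      ((unclass(fit$rates[[br]]) - unclass(truth[[br]])) / unclass(truth[[br]]))^2))))
  })
  # rms relative error roughly ~ 1/sqrt(L): a 16x longer window should at
  # least halve it
  expect_lt(errs[3], errs[1] / 2)
  expect_lt(errs[3], 0.1)
})

test_that("relabelling the sisters swaps the branch estimates", {
  cfg <- simulation_config(
    n_windows = 1, window_length = 1e5, seed = 91, coupling = 0,
    branch_params = list(
      sister1 = substitution_params(0.002, 0.006, 0.002, 0.003, 0.002, 0.008, 0.08),
      sister2 = substitution_params(0.006, 0.02, 0.006, 0.01, 0.006, 0.025, 0.25),
      outgroup = substitution_params(0.012, 0.036, 0.012, 0.018, 0.012, 0.048, 0.48)))
  w <- simulate_triple_alignment(cfg, 1)
  swapped <- triple_window(w$seqs$sister2, w$seqs$sister1, w$seqs$outgroup,
                           chrom = w$chrom)
  f1 <- estimate_branch_rates(w, n_restarts = 0)
  f2 <- estimate_branch_rates(swapped, n_restarts = 0)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
  expect_equal(unclass(f1$rates$sister1), unclass(f2$rates$sister2), tolerance = 1e-3)
  expect_equal(unclass(f1$rates$sister2), unclass(f2$rates$sister1), tolerance = 1e-3)
})

test_that("degenerate windows drive the rates to the zero boundary", {
  s <- simulate_root_sequence(20000, 0.4, 0.3, seed = 92)
  w <- triple_window(s, s, s)
  fit <- estimate_branch_rates(w, n_restarts = 0)
  expect_lt(max(coef(fit)), 1e-3)
  # root symmetry holds by construction
  cls <- dinuc_rc_classes()
  f <- fit$root
  rc_image <- ave(f, cls)
  expect_equal(unname(f), unname(rc_image), tolerance = 1e-12)
})

test_that("a zero CpG channel in truth is not estimated as positive", {
  base <- substitution_params(0.004, 0.012, 0.004, 0.006, 0.004, 0.016, 0)
  cfg <- simulation_config(n_windows = 1, window_length = 2e5, seed = 93,
                           coupling = 0,
                           branch_params = list(sister1 = base, sister2 = base,
                                                outgroup = base))
  w <- simulate_triple_alignment(cfg, 1)
  fit <- estimate_branch_rates(w, n_restarts = 0)
  expect_lt(fit$rates$sister1[["r_CpG"]], 0.004)   # far below the r_CT scale
})

test_that("the composite likelihood is locally concave at the optimum", {
  cfg <- simulation_config(n_windows = 1, window_length = 3e5, seed = 94)
  w <- simulate_triple_alignment(cfg, 1)
  fit <- estimate_branch_rates(w, n_restarts = 0)
  root <- fit$root
  ll_at <- function(rates1) {
    window_loglikelihood(w, list(sister1 = rates1, sister2 = fit$rates$sister2,
                                 outgroup = fit$rates$outgroup), root)
  }
  ll0 <- ll_at(fit$rates$sister1)
  for (k in 1:7) {
    for (fac in c(0.9, 1.1)) {
      p <- unclass(fit$rates$sister1)
      p[k] <- p[k] * fac
      expect_lt(ll_at(do.call(substitution_params, as.list(p))), ll0)
    }
  }
})

test_that("triple_fit methods expose the model sensibly", {
  cfg <- simulation_config(n_windows = 1, window_length = 3e4, seed = 95)
  w <- simulate_triple_alignment(cfg, 1)
  fit <- estimate_branch_rates(w, n_restarts = 0)
  co <- coef(fit)
  expect_equal(dim(co), c(3L, 7L))
  expect_equal(rownames(co), c("sister1", "sister2", "outgroup"))
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(attr(ll, "nobs"), fit$n_pairs)
  expect_output(print(fit), "composite ML")
  sm <- summary(fit)
  expect_true(all(is.finite(sm$equilibrium)))
  reps <- simulate(fit, nsim = 2, seed = 3, length = 5000)
  expect_length(reps, 2)
  expect_s3_class(reps[[1]], "triple_window")
  expect_length(reps[[1]]$mask, 5000)
  expect_identical(simulate(fit, seed = 3, length = 2000)[[1]],
                   simulate(fit, seed = 3, length = 2000)[[1]])
})
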