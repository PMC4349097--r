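---
title: "Methods: neighbour-dependent substitution rates and equilibrium GC content"
author: "gcstar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neighbour-dependent substitution rates and equilibrium GC content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcstar)
```

## The problem

CpG dinucleotides in vertebrate germlines are methylated, and methylated
cytosines deaminate to thymine roughly an order of magnitude faster than
unmethylated ones. This CpG hypermutability removes G+C from the genome
wherever methylated CpGs exist, so any statement about where the GC content
of a genomic region is heading — its *equilibrium* GC content — depends on
whether the substitution model knows about it. `gcstar` implements the full
chain of analysis: estimate lineage-specific, neighbour-dependent
substitution rates from three-species alignment windows; convert them into
two equilibrium GC estimates, one blind to CpG hypermutability (GC\*) and
one incorporating it (GC\*~CpG~); summarise bisulfite methylation maps into
window-level methylation levels and frequencies; and relate rates and
equilibria to methylation and recombination by multiple linear regression
and principal component regression.

## The substitution model

Substitutions are parameterised per branch of the unrooted 3-taxon tree
((sister1, sister2), outgroup) by seven rates:

* six reverse-complement-symmetric context-free exchanges, named by one
  strand of each pooled pair (`r_AC` for A→C ≡ T→G, `r_AG`, `r_AT`, `r_CA`,
  `r_CG`, `r_CT`), and
* one additional neighbour-dependent channel `r_CpG`: a C directly followed
  by G gains extra C→T rate (equivalently, by strand symmetry, the G gains
  extra G→A), i.e. CpG → TpG/CpA.

Rates are *expected substitutions per site per branch*; branch length is
absorbed into the rates and the branch duration is fixed at 1, matching the
interpretation of a substitution frequency per nucleotide of origin along a
specific branch. The model is non-stationary: the dinucleotide composition
at the internal node is free (constrained only to be a
reverse-complement-symmetric probability vector over the 16 ordered
dinucleotides, 9 free parameters), so ancestral composition is estimated,
not assumed to be at equilibrium. Multiple hits are handled through the
matrix exponential of the 16×16 dinucleotide generator
(`build_dinucleotide_generator()`, `transition_probabilities()`).

### Composite likelihood and the boundary closure

The exact likelihood of a neighbour-dependent process over a whole sequence
is intractable, so `window_loglikelihood()` uses a composite likelihood over
*overlapping dinucleotide columns*: for every position pair (i, i+1) that is
unambiguous in all three species, the probability of the observed
dinucleotide triple is summed over the 16 ancestral dinucleotides at the
internal node. Each site appears in two pairs; this double counting is
deliberate and accepted — point estimates remain consistent, and no
likelihood-ratio p-values are ever derived from the composite score.

A dinucleotide pair does not see the CpG partners of its edge positions: the
left neighbour of its first base and the right neighbour of its second base
are outside the pair. Ignoring this (the `boundary = FALSE` model)
misattributes those CpG deamination events to the context-free C→T rate and
biases `r_CT` upward by roughly `f(CpG)/f(C) × r_CpG / 2` — around 20% under
realistic rate ratios, which is far outside the accuracy we require. The
closure used by default treats the hidden neighbour as a mixture, with one
shared draw for all three branches (the neighbour state is a property of the
ancestor): with probability `f(CpG)/f(·G)` the left neighbour is a C and the
first-position G carries full deamination exposure; with probability
`f(CpG)/f(C·)` the right neighbour is a G and the second-position C does;
otherwise there is no exposure. Because a neighbour is nearly persistent
over one branch at these divergences, mixing *transition matrices* rather
than averaging *rates* is the right first-order treatment; the slow drift of
the CpG context along a branch is captured by damping the exposure matrices
with the factor `(1 − e^{−λ})/λ`, where λ is the model-implied relative rate
of change of the CpG frequency at the root. The closure was validated
against the exact stochastic simulator: on 1-Mb windows at study-like
divergences the fitter recovers all context-free rates within ~5% and
`r_CpG` within ~8% relative error (tolerances used in the tests are 10% and
15%).

`estimate_branch_rates()` maximises the composite likelihood over the 3 × 7
log-rates (floored at 1e-12; estimates at the floor are reported as 0) and
the 9 root-composition logits with L-BFGS-B on a compiled objective, from a
divergence-based start plus `n_restarts` random restarts (default 3; the
pipeline uses 1 because the data-driven start is reliable and windows are
many). Convergence uses the optimizer's default function-improvement
criterion at `factr = 1e7` (≈ 2e-9 relative).

## Equilibrium GC content

With the strong/weak pathway rates `u_WS = r_AC + r_AG` and
`u_SW = r_CA + r_CT` (CpG-context deamination deliberately excluded from
`u_SW`), the equilibrium GC content of the context-free model is the closed
form

$$GC^* = \frac{u_{W\to S}}{u_{W\to S} + u_{S\to W}}.$$

GC\*~CpG~ is the stationary GC fraction of the *full* neighbour-dependent
process and has no closed form. `gc_star_cpg()` computes it by a
dinucleotide cluster approximation: the 16 pair frequencies evolve under the
pair generator, with the dependence of an edge position on its outside
neighbour closed through the standard pair closure (triplet frequency ≈
product of its two overlapping pair frequencies over the shared
mononucleotide frequency), which turns the boundary CpG flux into rates
`r_CpG · f(CG)/f(G)` and `r_CpG · f(CG)/f(C)` built from the *current* pair
distribution. The self-consistent fixed point is iterated to a maximum
frequency change below 1e-10 (damping 0.5 on oscillation; non-convergence
within 1e6 iterations is an error). Two exact properties anchor the
implementation: with `r_CpG = 0` the closure is exact and reduces to GC\*
(verified to 1e-8), and the stochastic simulator is the authority otherwise
— the fixed point agrees with long-run Monte-Carlo GC within 3 Monte-Carlo
standard errors across a parameter grid including strong CpG channels.

```{r equilibrium-example}
p <- substitution_params(0.004, 0.012, 0.004, 0.006, 0.004, 0.016, 0.16)
u <- pathway_rates(p)
c(gc_star = gc_star(u[["u_WS"]], u[["u_SW"]]),
  gc_star_cpg = as.numeric(gc_star_cpg(p)))
```

The CpG channel lowers the equilibrium by several GC percentage points, and
`delta_gc(gc_star_cpg, gc)` — equilibrium minus current GC — is the measure
used to ask whether methylation is eroding GC content. The Monte-Carlo
check runs each grid point to stationarity with a duration of 8 relaxation
times, `8/(u_WS + u_SW)`, so that the initial composition (GC 0.5) has
decayed by e^−8.

For comparing equilibrium with current GC across windows,
`leading_pc_slope()` fits the leading principal component of the centred
two-column data — a total-least-squares line through the means, appropriate
because both axes carry error. A slope above 1 means the GC landscape is
being reinforced, below 1 eroded.

## Methylation

`read_methylation_table()` ingests per-CpG bisulfite counts (chrom, 0-based
position, strand, methylated count, total count); minus-strand records are
mapped to the plus-strand C of the CpG and, by default, the two strands of
one dinucleotide are merged by summing counts, since CpG methylation is
palindromic and the dinucleotide is the unit of analysis (per-strand records
can be kept with `merge_strands = FALSE`). The site status is the
non-converted read fraction. The window methylation level is the
*pooled-count* ratio

$$L_{mCpG} = \frac{\sum_{\Omega} x_{mCpG}}{\sum_{\Omega}(x_{mCpG} + x_{CpG})},$$

i.e. coverage-weighted, not the mean of per-site ratios — the two disagree
whenever coverage varies (pooling {(1,1), (0,99)} gives 0.01, not 0.5). The
minimum usable coverage is 1 read, configurable. The methylation
*frequency* of a window is the exact product of its level and its CpG
content: the density of methylated CpGs, which is what should matter for the
regional impact of hypermutability.

## Windows, masks, composition, recombination

Coordinates are 0-based half-open throughout (BED convention). An
"unambiguous" column has A/C/G/T in all three species and lies outside the
mask — the strictest natural reading; windows with fewer than 10,000
unambiguous sites are dropped (`filter_windows()`). Composition is computed
on the reference (sister1) sequence over unmasked sites; CpG content counts
genome-adjacent unmasked pairs only, and CpG[o/e] divides by `f(C)·f(G)`
from the same sites. The window recombination rate is the mean of the
marker-interval rates weighted by physical overlap with the window; windows
without map coverage get a missing value and drop out of the regressions
listwise.

## Regression stage

Recombination rates are transformed as `log10(rate + 1)` to reduce skew.
`mlr_partial()` reports per-predictor partial correlations
`sign(b)·sqrt(t²/(t² + df))` with two-sided t p-values — algebraically
identical to the Pearson correlation of the residuals of response and
predictor on the remaining predictors, an identity the tests enforce at
1e-10. `pcr()` Z-transforms the predictors, extracts principal components of
their correlation matrix, regresses the response on all component scores
jointly, and decomposes variance: because scores are orthogonal, each PC's
share of response variance is its squared correlation with the response and
the shares sum to the full-model R²; within a PC, variable contributions are
squared loadings (summing to 1). Significance is judged at 0.05 with no
multiple-testing correction, matching the analysis this package reproduces;
a "significant PC" is one whose joint-regression t-test falls below 0.05
(the criterion is configurable by reading `p_value` directly). PC signs are
fixed by making each component's largest loading positive, for
reproducibility.

## The synthetic-data generator

Real inputs to this analysis (whole-genome EPO alignments, a sperm
methylome, genetic maps) are observational and genome-scale, so the package
ships a generator that emulates their statistical structure at desk scale
and makes every downstream stage testable against known truth
(`simulation_config()`, `simulate_study()`).

* **Root sequences**: first-order Markov chains whose stationary law hits a
  target GC and whose CpG frequency is exactly `enrichment × f(C)·f(G)`
  (remaining pair frequencies fitted by iterative proportional scaling so
  the marginals stay put). Defaults: GC 0.4034, CpG[o/e] 0.21 — the
  genome-wide averages of the bird genome the analysis targets.
* **Between-window heterogeneity**: window root GC is Beta-distributed
  (sd 0.04, spanning roughly 0.32–0.55) and window CpG enrichment
  log-normal (log-sd 0.25, spanning roughly 0.12–0.42), reproducing the
  printed per-window ranges of GC and CpG[o/e]. This heterogeneity is not
  cosmetic: methylation frequency varies across windows mostly through CpG
  content, and the ΔGC regressions have no detectable signal without it.
* **Evolution**: an exact event-driven (thinned) Gillespie simulation of the
  full neighbour-dependent process, re-evaluating CpG context after every
  event; sequence ends are non-CpG context; no indels (the analysis only
  uses unambiguous columns). Sister branches default to divergence ≈ 0.05
  substitutions/site with `r_CpG = 0.16 = 10 × r_CT`; the outgroup branch is
  3× longer.
* **Methylation**: window mean levels are Beta-distributed with mean 0.41
  and concentration 60 (range ≈ 0.2–0.55); per-site statuses are Beta
  around the window mean (concentration 10) for realistic overdispersion;
  coverage is 1 + Poisson(27) per CpG (mean 28, minimum 1) and methylated
  counts are binomial.
* **Coupling**: the effective CpG rate of window w is
  `r_CpG · (1 − c + c·m_w/m̄)` on all three branches. `c = 1` (default) is
  the mechanistic reading — deamination happens at methylated CpGs only, so
  the rate is proportional to the methylation level; `c = 0` severs the
  link and serves as the null condition for false-positive checks.
* **Recombination**: per-window Gamma(1.5, scale 0.6) cM/Mb, independent of
  methylation — the generator does not claim the covariance structure of
  real genomes, only marginal realism.

What passing tests on these data do **not** show: robustness to alignment
error, indels, non-equilibrium base-composition gradients, CpG islands,
conversion-efficiency artefacts in bisulfite data, or the real covariance
between recombination and base composition. The truth table written by
`simulate_study()` carries a `generative_model = "synthetic-stand-in"`
column as a reminder.

## Problem sizes and numerical choices

The test-suite and acceptance runs use: 1-Mb single windows (5 seeds) for
parameter recovery; 200-kb sequences, 5 parameter sets, 8 relaxation times
for the equilibrium Monte-Carlo oracle; and 10 + 10 replicate studies of 50
windows × 50 kb for the coupling-pattern and null checks — sizes chosen so
the whole battery completes in minutes while every check retains clear
statistical margin. Other numerics: rates floored at 1e-12 (floor reported
as 0); fixed-point tolerance 1e-10 with 0.5 damping on oscillation;
optimizer `factr = 1e7`, up to 1000 iterations; exposure-decay factor
clamped to [0.2, 2]; composite-likelihood cell probabilities floored at
1e-300 before logging. All simulation entry points take explicit integer
seeds, restore the caller's RNG state, and derive per-window streams from
the master seed, so every advertised output is bit-reproducible.

## Known limitations

* The composite likelihood is an approximation; its sampling variance is
  not the inverse information, so no standard errors or likelihood-ratio
  tests are offered for the rate estimates.
* The boundary closure is first-order in the neighbour exposure; residual
  rate biases of a few percent remain at high divergence or extreme CpG
  enrichment.
* Outgroup-branch rates are estimated but never used downstream; equilibria
  always use the reference (sister1) branch.
* `gc_star_cpg()` assumes the seven-rate strand-symmetric model; rate
  variation within a window (e.g. CpG islands) is out of scope.
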