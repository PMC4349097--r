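// Core numerics: neighbour-dependent sequence evolution, root-sequence
// sampling, dinucleotide-triple counting, and the composite negative
// log-likelihood over overlapping dinucleotide columns of a 3-taxon alignment.
//
// Nucleotide encoding throughout: A=1, C=2, G=3, T=4; 0 marks a masked or
// ambiguous position. Dinucleotide index (0-based): 4*a + b with a,b in 0..3.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int rc0(int x) { return 3 - x; }          // 0-based complement
static inline int din(int a, int b) { return 4 * a + b; }

// 4x4 context-free rate matrix from the six reverse-complement-symmetric
// pooled rates (rAC, rAG, rAT, rCA, rCG, rCT): q[x][y] for x != y.
static void base_rates(const double* r, double q[4][4]) {
  for (int x = 0; x < 4; ++x)
    for (int y = 0; y < 4; ++y) q[x][y] = 0.0;
  // A=0, C=1, G=2, T=3
  q[0][1] = r[0]; q[0][2] = r[1]; q[0][3] = r[2];       // A->C, A->G, A->T
  q[1][0] = r[3]; q[1][2] = r[4]; q[1][3] = r[5];       // C->A, C->G, C->T
  // T and G rows by strand symmetry: q[x][y] = q[rc(x)][rc(y)]
  q[3][2] = r[0]; q[3][1] = r[1]; q[3][0] = r[2];       // T->G, T->C, T->A
  q[2][3] = r[3]; q[2][1] = r[4]; q[2][0] = r[5];       // G->T, G->C, G->A
}

// 16x16 dinucleotide generator; rates = (rAC,rAG,rAT,rCA,rCG,rCT,rCpG),
// bL = P(hidden left neighbour is C | first base is G),
// bR = P(hidden right neighbour is G | second base is C). Set bL=bR=0 for the
// plain within-pair generator.
static arma::mat dinuc_generator(const double* rates, double bL, double bR) {
  double q[4][4];
  base_rates(rates, q);
  const double rcpg = rates[6];
  arma::mat Q(16, 16, arma::fill::zeros);
  for (int a = 0; a < 4; ++a) {
    for (int b = 0; b < 4; ++b) {
      const int d = din(a, b);
      for (int a2 = 0; a2 < 4; ++a2)
        if (a2 != a) Q(d, din(a2, b)) += q[a][a2];
      for (int b2 = 0; b2 < 4; ++b2)
        if (b2 != b) Q(d, din(a, b2)) += q[b][b2];
    }
  }
  // CpG deamination within the pair: CG -> TG and CG -> CA
  Q(din(1, 2), din(3, 2)) += rcpg;
  Q(din(1, 2), din(1, 0)) += rcpg;
  // boundary closure: first-position G with hidden left C, second-position C
  // with hidden right G
  if (bL > 0.0)
    for (int b = 0; b < 4; ++b) Q(din(2, b), din(0, b)) += rcpg * bL;
  if (bR > 0.0)
    for (int a = 0; a < 4; ++a) Q(din(a, 1), din(a, 3)) += rcpg * bR;
  Q.diag() -= arma::sum(Q, 1);
  return Q;
}

// [[Rcpp::export]]
arma::mat dinuc_generator_cpp(const arma::vec& rates, double bL, double bR) {
  return dinuc_generator(rates.memptr(), bL, bR);
}

// Reverse-complement symmetry classes of the 16 ordered dinucleotides:
// d and 4*rc(b)+rc(a) are strand-equivalent. Returns 0-based class ids in a
// stable order (10 classes).
static void dinuc_classes(int cls[16], int* n_cls) {
  int next = 0;
  int seen[16];
  for (int d = 0; d < 16; ++d) seen[d] = -1;
  for (int d = 0; d < 16; ++d) {
    const int a = d / 4, b = d % 4;
    const int rcd = din(rc0(b), rc0(a));
    const int rep = d < rcd ? d : rcd;
    if (seen[rep] < 0) seen[rep] = next++;
    cls[d] = seen[rep];
  }
  *n_cls = next;
}

// [[Rcpp::export]]
IntegerVector dinuc_class_cpp() {
  int cls[16], n;
  dinuc_classes(cls, &n);
  IntegerVector out(16);
  for (int d = 0; d < 16; ++d) out[d] = cls[d] + 1;
  return out;
}

// Root dinucleotide frequencies from 9 free logits (class 0 pinned at 0).
static arma::vec root_from_logits(const double* logits) {
  int cls[16], n;
  dinuc_classes(cls, &n);
  arma::vec w(n);
  w[0] = 0.0;
  for (int c = 1; c < n; ++c) w[c] = logits[c - 1];
  w -= w.max();
  arma::vec f(16);
  double tot = 0.0;
  for (int d = 0; d < 16; ++d) { f[d] = std::exp(w[cls[d]]); tot += f[d]; }
  return f / tot;
}

// [[Rcpp::export]]
arma::vec root_freq_cpp(const arma::vec& logits) {
  return root_from_logits(logits.memptr());
}

// Composite negative log-likelihood.
// par: 7 log-rates per branch (sister1, sister2, outgroup) then 9 root logits.
// counts: length-4096 vector of dinucleotide-triple counts indexed
// d1 + 16*d2 + 256*do (0-based).
static double cl_nll(const arma::vec& par, const arma::vec& counts, bool boundary) {
  double r1[7], r2[7], ro[7];
  for (int k = 0; k < 7; ++k) {
    r1[k] = std::exp(par[k]);
    r2[k] = std::exp(par[7 + k]);
    ro[k] = std::exp(par[14 + k]);
  }
  arma::vec root = root_from_logits(par.memptr() + 21);
  double bL = 0.0, bR = 0.0;
  if (boundary) {
    double fCG = root[din(1, 2)], fCdot = 0.0, fdotG = 0.0;
    for (int b = 0; b < 4; ++b) fCdot += root[din(1, b)];
    for (int a = 0; a < 4; ++a) fdotG += root[din(a, 2)];
    bR = fCdot > 0 ? fCG / fCdot : 0.0;
    bL = fdotG > 0 ? fCG / fdotG : 0.0;
  }
  // branch-time-averaged boundary context: the hidden-neighbour CpG
  // frequency decays (or grows) along the branch at the model-implied rate,
  // so scale the root-based context by (1 - exp(-lambda)) / lambda
  // Boundary closure as a neighbour-state mixture shared across branches:
  // with probability bL (bR) the hidden left (right) neighbour of the
  // ancestral pair is the CpG partner, and all three branches then carry the
  // full deamination exposure at that edge position (neighbours are nearly
  // persistent over one branch; their drift enters through a per-branch
  // decay factor on the exposure matrix).
  const int CG = din(1, 2);
  auto Pset = [&](const double* r, arma::mat* P) {
    arma::mat Q00 = dinuc_generator(r, 0.0, 0.0);
    P[0] = arma::expmat(Q00);
    if (!boundary || r[6] <= 0.0) {
      P[1] = P[0]; P[2] = P[0];
      return;
    }
    double fac = 1.0;
    if (root[CG] > 0) {
      double lam = -arma::dot(root, Q00.col(CG)) / root[CG];
      if (std::fabs(lam) > 1e-12) fac = (1.0 - std::exp(-lam)) / lam;
      if (fac < 0.2) fac = 0.2;
      if (fac > 2.0) fac = 2.0;
    }
    arma::mat QL = dinuc_generator(r, 1.0, 0.0);
    arma::mat QR = dinuc_generator(r, 0.0, 1.0);
    P[1] = P[0] + fac * (arma::expmat(QL) - P[0]);
    P[2] = P[0] + fac * (arma::expmat(QR) - P[0]);
  };
  arma::mat P1[3], P2[3], Po[3];
  Pset(r1, P1); Pset(r2, P2); Pset(ro, Po);
  double w[3] = {1.0, 0.0, 0.0};
  if (boundary) {
    w[1] = bL; w[2] = bR;
    w[0] = 1.0 - bL - bR;
    if (w[0] < 0.0) w[0] = 0.0;
  }
  double nll = 0.0;
  arma::mat p(16, 16);
  for (int dd = 0; dd < 16; ++dd) {
    bool any = false;
    for (int d2 = 0; d2 < 16 && !any; ++d2)
      for (int d1 = 0; d1 < 16; ++d1)
        if (counts[d1 + 16 * d2 + 256 * dd] > 0.0) { any = true; break; }
    if (!any) continue;
    p.zeros();
    for (int s = 0; s < 3; ++s) {
      if (w[s] <= 0.0) continue;
      arma::vec v = root % Po[s].col(dd);
      p += w[s] * (P1[s].t() * arma::diagmat(v) * P2[s]);
    }
    for (int d2 = 0; d2 < 16; ++d2) {
      for (int d1 = 0; d1 < 16; ++d1) {
        const double n = counts[d1 + 16 * d2 + 256 * dd];
        if (n > 0.0) {
          double pv = p(d1, d2);
          if (pv < 1e-300) pv = 1e-300;
          nll -= n * std::log(pv);
        }
      }
    }
  }
  return nll;
}

// [[Rcpp::export]]
double cl_negloglik_cpp(const arma::vec& par, const arma::vec& counts, bool boundary) {
  return cl_nll(par, counts, boundary);
}

// [[Rcpp::export]]
arma::vec cl_negloglik_grad_cpp(const arma::vec& par, const arma::vec& counts,
                                bool boundary, double h = 1e-5) {
  arma::vec g(par.n_elem);
  arma::vec p = par;
  for (arma::uword i = 0; i < par.n_elem; ++i) {
    const double x0 = p[i];
    p[i] = x0 + h; const double fp = cl_nll(p, counts, boundary);
    p[i] = x0 - h; const double fm = cl_nll(p, counts, boundary);
    p[i] = x0;
    g[i] = (fp - fm) / (2.0 * h);
  }
  return g;
}

// Count dinucleotide triples over overlapping column pairs (i, i+1); a pair is
// used only if all six bases are unambiguous (coded 1..4).
// [[Rcpp::export]]
NumericVector count_triples_cpp(const IntegerVector& s1, const IntegerVector& s2,
                                const IntegerVector& so) {
  const int L = s1.size();
  if (s2.size() != L || so.size() != L) stop("sequences differ in length");
  NumericVector counts(4096);
  for (int i = 0; i + 1 < L; ++i) {
    const int a1 = s1[i], b1 = s1[i + 1];
    const int a2 = s2[i], b2 = s2[i + 1];
    const int ao = so[i], bo = so[i + 1];
    if (a1 < 1 || b1 < 1 || a2 < 1 || b2 < 1 || ao < 1 || bo < 1) continue;
    if (a1 > 4 || b1 > 4 || a2 > 4 || b2 > 4 || ao > 4 || bo > 4) continue;
    const int d1 = din(a1 - 1, b1 - 1);
    const int d2 = din(a2 - 1, b2 - 1);
    const int dd = din(ao - 1, bo - 1);
    counts[d1 + 16 * d2 + 256 * dd] += 1.0;
  }
  return counts;
}

// Exact event-driven evolution of a sequence under the neighbour-dependent
// process (thinning against the maximal per-site rate). Uses R's RNG.
// q: 4x4 off-diagonal context-free rates; rcpg: extra CpG->TpG/CpA rate;
// tmax: branch duration (rates are per unit time).
// [[Rcpp::export]]
IntegerVector evolve_sequence_cpp(const IntegerVector& seq, const NumericMatrix& q,
                                  double rcpg, double tmax) {
  const int L = seq.size();
  IntegerVector s = clone(seq);
  double rowtot[4];
  double qm[4][4];
  double rmax = 0.0;
  for (int x = 0; x < 4; ++x) {
    rowtot[x] = 0.0;
    for (int y = 0; y < 4; ++y) {
      qm[x][y] = q(x, y);
      if (x != y) rowtot[x] += qm[x][y];
    }
    if (rowtot[x] > rmax) rmax = rowtot[x];
  }
  rmax += rcpg;
  if (rmax <= 0.0 || tmax <= 0.0) return s;
  double t = 0.0;
  const double scale = 1.0 / (static_cast<double>(L) * rmax);
  for (;;) {
    t += R::exp_rand() * scale;
    if (t > tmax) break;
    int i = static_cast<int>(R::unif_rand() * L);
    if (i >= L) i = L - 1;
    const int x = s[i] - 1;            // 0-based current base
    double extra = 0.0;
    int extra_target = -1;
    if (x == 1 && i + 1 < L && s[i + 1] == 3) {       // CpG: C -> T
      extra = rcpg; extra_target = 3;
    } else if (x == 2 && i > 0 && s[i - 1] == 2) {    // CpG: G -> A
      extra = rcpg; extra_target = 0;
    }
    const double u = R::unif_rand() * rmax;
    double acc = 0.0;
    int target = -1;
    for (int y = 0; y < 4; ++y) {
      if (y == x) continue;
      acc += qm[x][y];
      if (u < acc) { target = y; break; }
    }
    if (target < 0 && extra > 0.0) {
      acc += extra;
      if (u < acc) target = extra_target;
    }
    if (target >= 0) s[i] = target + 1;
  }
  return s;
}

// Sample a first-order Markov chain of length n with transition matrix P
// (rows = current base) and initial distribution init. Uses R's RNG.
// [[Rcpp::export]]
IntegerVector markov_chain_cpp(const NumericMatrix& P, int n, const NumericVector& init) {
  IntegerVector s(n);
  double cum[4][4];
  for (int x = 0; x < 4; ++x) {
    double c = 0.0;
    for (int y = 0; y < 4; ++y) { c += P(x, y); cum[x][y] = c; }
  }
  double ci[4];
  double c0 = 0.0;
  for (int y = 0; y < 4; ++y) { c0 += init[y]; ci[y] = c0; }
  double u = R::unif_rand() * c0;
  int cur = 0;
  while (cur < 3 && u > ci[cur]) ++cur;
  s[0] = cur + 1;
  for (int i = 1; i < n; ++i) {
    u = R::unif_rand() * cum[cur][3];
    int y = 0;
    while (y < 3 && u > cum[cur][y]) ++y;
    s[i] = y + 1;
    cur = y;
  }
  return s;
}
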