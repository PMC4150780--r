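// Thermodynamic core: intermolecular duplex MFE (stacks, bulges, internal
// loops; no intramolecular pairs, no multiloops) and single-sequence
// Boltzmann ensemble (inside/outside partition function over pseudoknot-free
// structures with an affine multiloop model), plus constrained folding and
// stochastic traceback. All ensemble arithmetic is in log space.
//
// Bases are encoded A=0, C=1, G=2, U=3. All indices here are 1-based
// internally; interfaces use R integer vectors of codes.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();
static const double E_INF = 1e30; // energy of a disallowed motif

struct EModel {
  double stack[6][6];
  std::vector<double> hairpin, bulge, internal_; // [size], index 0 unused
  double extrap;
  int tabmax;
  double term_au, dup_init, ml_a, ml_b, ml_c, RT;
  int min_h, max_side;
};

// pair index: AU=0 UA=1 CG=2 GC=3 GU=4 UG=5, -1 if not allowed
static inline int pidx(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

// terminal AU/GU penalty applies unless the pair is CG/GC
static inline bool weak_pair(int pi) { return pi != 2 && pi != 3; }

static EModel parse_model(const List& model) {
  EModel m;
  NumericMatrix st = model["stack"];
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) m.stack[i][j] = st(i, j);
  NumericVector h = model["hairpin"], b = model["bulge"], il = model["internal"];
  m.tabmax = h.size();
  m.hairpin.assign(m.tabmax + 1, E_INF);
  m.bulge.assign(m.tabmax + 1, E_INF);
  m.internal_.assign(m.tabmax + 1, E_INF);
  for (int s = 1; s <= m.tabmax; ++s) {
    if (!NumericVector::is_na(h[s - 1])) m.hairpin[s] = h[s - 1];
    if (!NumericVector::is_na(b[s - 1])) m.bulge[s] = b[s - 1];
    if (!NumericVector::is_na(il[s - 1])) m.internal_[s] = il[s - 1];
  }
  m.extrap = as<double>(model["loop_extrap"]);
  m.term_au = as<double>(model["terminal_au"]);
  m.dup_init = as<double>(model["duplex_init"]);
  m.ml_a = as<double>(model["ml_init"]);
  m.ml_b = as<double>(model["ml_branch"]);
  m.ml_c = as<double>(model["ml_unpaired"]);
  m.RT = as<double>(model["RT"]);
  m.min_h = as<int>(model["min_hairpin"]);
  m.max_side = as<int>(model["max_loop_side"]);
  return m;
}

static inline double loopE(const std::vector<double>& tab, int size,
                           const EModel& m) {
  if (size <= 0) return E_INF;
  if (size <= m.tabmax) return tab[size];
  return tab[m.tabmax] + m.extrap * std::log((double)size / m.tabmax);
}

// energy of the two-pair motif (i,j) closing (k,l): k-i-1 / j-l-1 unpaired
static inline double interiorE(int pi_out, int pi_in, int l1, int l2,
                               const EModel& m) {
  if (l1 > m.max_side || l2 > m.max_side) return E_INF;
  if (l1 == 0 && l2 == 0) return m.stack[pi_out][pi_in];
  if (l1 == 0 || l2 == 0) return loopE(m.bulge, l1 + l2, m);
  return loopE(m.internal_, l1 + l2, m);
}

static inline double lse(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  if (a < b) std::swap(a, b);
  return a + std::log1p(std::exp(b - a));
}

// ---------------------------------------------------------------------------
// Duplex MFE
// ---------------------------------------------------------------------------

// Hybrid = monotone antiparallel pairing between miRNA (5'->3') and target:
// pairs (i1<i2<...) on miRNA with (j1>j2>...) on target. Energy =
// duplex_init + terminal penalties at both end pairs + stack/bulge/internal
// terms between consecutive pairs.
//
// D[i][j] = best energy of a hybrid whose 3'-most miRNA pair is (i,j),
// including init and the terminal penalty of the first pair only.
// [[Rcpp::export]]
List cpp_duplex_mfe(IntegerVector mi, IntegerVector tg, List model) {
  EModel m = parse_model(model);
  int M = mi.size(), T = tg.size();
  std::vector<std::vector<double> > D(M + 1, std::vector<double>(T + 1, E_INF));
  std::vector<std::vector<int> > pre_i(M + 1, std::vector<int>(T + 1, 0)),
      pre_j(M + 1, std::vector<int>(T + 1, 0));
  for (int i = 1; i <= M; ++i) {
    for (int j = T; j >= 1; --j) {
      int pi = pidx(mi[i - 1], tg[j - 1]);
      if (pi < 0) continue;
      double best = m.dup_init + (weak_pair(pi) ? m.term_au : 0.0);
      int bi = 0, bj = 0; // 0,0 = hybrid starts here
      for (int ip = std::max(1, i - m.max_side - 1); ip < i; ++ip) {
        for (int jp = j + 1; jp <= std::min(T, j + m.max_side + 1); ++jp) {
          if (D[ip][jp] >= E_INF / 2) continue;
          int a = i - ip - 1, b = jp - j - 1;
          int pio = pidx(mi[ip - 1], tg[jp - 1]);
          double g = interiorE(pio, pi, a, b, m);
          if (g >= E_INF / 2) continue;
          double cand = D[ip][jp] + g;
          // tie-break: prefer smaller total gap, then larger ip (3'-most)
          if (cand < best - 1e-12 ||
              (std::fabs(cand - best) <= 1e-12 && bi != 0 &&
               (a + b < (i - bi - 1) + (bj - j - 1) ||
                ((a + b) == (i - bi - 1) + (bj - j - 1) && ip > bi)))) {
            best = cand; bi = ip; bj = jp;
          }
        }
      }
      D[i][j] = best; pre_i[i][j] = bi; pre_j[i][j] = bj;
    }
  }
  // closing: add terminal penalty at the last pair; tie-break on
  // (energy, smallest target index j, smallest miRNA index i)
  double bestE = E_INF; int ei = 0, ej = 0;
  for (int j = 1; j <= T; ++j) {
    for (int i = 1; i <= M; ++i) {
      if (D[i][j] >= E_INF / 2) continue;
      int pi = pidx(mi[i - 1], tg[j - 1]);
      double e = D[i][j] + (weak_pair(pi) ? m.term_au : 0.0);
      if (e < bestE - 1e-12) { bestE = e; ei = i; ej = j; }
    }
  }
  if (ei == 0 || bestE > 0.0)
    return List::create(_["found"] = false, _["dG"] = NA_REAL,
                        _["pairs"] = IntegerMatrix(0, 2));
  std::vector<std::pair<int,int> > pr;
  int ci = ei, cj = ej;
  while (ci != 0) {
    pr.push_back(std::make_pair(ci, cj));
    int ni = pre_i[ci][cj], nj = pre_j[ci][cj];
    ci = ni; cj = nj;
  }
  IntegerMatrix pm(pr.size(), 2);
  for (int k = (int)pr.size() - 1, r = 0; k >= 0; --k, ++r) {
    pm(r, 0) = pr[k].first; pm(r, 1) = pr[k].second;
  }
  return List::create(_["found"] = true, _["dG"] = bestE, _["pairs"] = pm);
}

// ---------------------------------------------------------------------------
// Partition function (inside / outside), constraint mask, sampling
// ---------------------------------------------------------------------------

struct PF {
  int n;
  EModel m;
  std::vector<int> s;          // 1-based codes
  std::vector<char> mask;      // 1-based, true = forced unpaired
  std::vector<double> b, m1, mm, qf, qr; // log-space
  double lnZ;
  inline int id(int i, int j) const { return (i - 1) * n + (j - 1); }
  inline bool pairable(int i, int j) const {
    if (j - i - 1 < m.min_h) return false;
    if (mask[i] || mask[j]) return false;
    return pidx(s[i], s[j]) >= 0;
  }
  inline double lw(double E) const { return E >= E_INF / 2 ? NEG_INF : -E / m.RT; }
};

static void pf_inside(PF& p) {
  int n = p.n;
  const EModel& m = p.m;
  p.b.assign((size_t)n * n, NEG_INF);
  p.m1.assign((size_t)n * n, NEG_INF);
  p.mm.assign((size_t)n * n, NEG_INF);
  double la = p.lw(m.ml_a), lb = p.lw(m.ml_b), lc = p.lw(m.ml_c);
  for (int sp = m.min_h + 1; sp <= n - 1; ++sp) {
    for (int i = 1; i + sp <= n; ++i) {
      int j = i + sp;
      if (p.pairable(i, j)) {
        int pio = pidx(p.s[i], p.s[j]);
        double acc = p.lw(loopE(m.hairpin, j - i - 1, m));
        // interior loops / stacks / bulges
        int kmax = std::min(i + m.max_side + 1, j - 1);
        for (int k = i + 1; k <= kmax; ++k) {
          int lmin = std::max(k + m.min_h + 1, j - 1 - m.max_side);
          for (int l = lmin; l <= j - 1; ++l) {
            double bi = p.b[p.id(k, l)];
            if (bi == NEG_INF) continue;
            int pin = pidx(p.s[k], p.s[l]);
            double g = interiorE(pio, pin, k - i - 1, j - l - 1, m);
            if (g >= E_INF / 2) continue;
            acc = lse(acc, -g / m.RT + bi);
          }
        }
        // multiloop: closing pair + >=2 branches inside
        for (int u = i + 2; u <= j - 2; ++u) {
          double a1 = p.mm[p.id(i + 1, u - 1)], a2 = p.m1[p.id(u, j - 1)];
          if (a1 == NEG_INF || a2 == NEG_INF) continue;
          acc = lse(acc, la + lb + a1 + a2);
        }
        p.b[p.id(i, j)] = acc;
      }
      // m1: exactly one branch starting at i, trailing unpaired to j
      {
        double acc = NEG_INF;
        for (int l = i + m.min_h + 1; l <= j; ++l) {
          double bi = p.b[p.id(i, l)];
          if (bi == NEG_INF) continue;
          acc = lse(acc, bi + lb + lc * (j - l));
        }
        p.m1[p.id(i, j)] = acc;
      }
      // m: one or more branches on [i, j]
      {
        double acc = NEG_INF;
        for (int k = i; k <= j; ++k) {
          double m1v = p.m1[p.id(k, j)];
          if (m1v == NEG_INF) continue;
          acc = lse(acc, lc * (k - i) + m1v);
          if (k > i) {
            double mv = p.mm[p.id(i, k - 1)];
            if (mv != NEG_INF) acc = lse(acc, mv + m1v);
          }
        }
        p.mm[p.id(i, j)] = acc;
      }
    }
  }
  // exterior prefix / suffix
  p.qf.assign(n + 2, 0.0);
  p.qr.assign(n + 2, 0.0);
  for (int j = 1; j <= n; ++j) {
    double acc = p.qf[j - 1];
    for (int k = 1; k <= j; ++k) {
      double bv = p.b[p.id(k, j)];
      if (bv != NEG_INF) acc = lse(acc, p.qf[k - 1] + bv);
    }
    p.qf[j] = acc;
  }
  for (int i = n; i >= 1; --i) {
    double acc = p.qr[i + 1];
    for (int l = i; l <= n; ++l) {
      double bv = p.b[p.id(i, l)];
      if (bv != NEG_INF) acc = lse(acc, bv + p.qr[l + 1]);
    }
    p.qr[i] = acc;
  }
  p.lnZ = p.qf[n];
}

// outside pass -> per-nucleotide unpaired probabilities
static NumericVector pf_outside_pup(PF& p) {
  int n = p.n;
  const EModel& m = p.m;
  double la = p.lw(m.ml_a), lb = p.lw(m.ml_b), lc = p.lw(m.ml_c);
  std::vector<double> bh((size_t)n * n, NEG_INF), mh((size_t)n * n, NEG_INF),
      m1h((size_t)n * n, NEG_INF);
  NumericVector pu(n);
  for (int i = 0; i < n; ++i) pu[i] = 1.0;
  for (int sp = n - 1; sp >= m.min_h + 1; --sp) {
    for (int i = 1; i + sp <= n; ++i) {
      int j = i + sp;
      size_t c = p.id(i, j);
      // push from finalized mh(i,j) through the m recursion
      if (mh[c] != NEG_INF) {
        for (int k = i; k <= j; ++k) {
          if (p.m1[p.id(k, j)] == NEG_INF) continue;
          m1h[p.id(k, j)] = lse(m1h[p.id(k, j)], mh[c] + lc * (k - i));
          if (k > i) {
            double mv = p.mm[p.id(i, k - 1)];
            if (mv != NEG_INF) {
              m1h[p.id(k, j)] = lse(m1h[p.id(k, j)], mh[c] + mv);
              mh[p.id(i, k - 1)] = lse(mh[p.id(i, k - 1)],
                                       mh[c] + p.m1[p.id(k, j)]);
            }
          }
        }
      }
      // push from finalized m1h(i,j) through the m1 definition
      if (m1h[c] != NEG_INF) {
        for (int l = i + m.min_h + 1; l <= j; ++l) {
          if (p.b[p.id(i, l)] == NEG_INF) continue;
          bh[p.id(i, l)] = lse(bh[p.id(i, l)], m1h[c] + lb + lc * (j - l));
        }
      }
      if (!p.pairable(i, j) || p.b[c] == NEG_INF) continue;
      // exterior-loop context
      bh[c] = lse(bh[c], p.qf[i - 1] + p.qr[j + 1]);
      if (bh[c] == NEG_INF) continue;
      int pio = pidx(p.s[i], p.s[j]);
      // (i,j) closes an interior loop around (k,l)
      int kmax = std::min(i + m.max_side + 1, j - 1);
      for (int k = i + 1; k <= kmax; ++k) {
        int lmin = std::max(k + m.min_h + 1, j - 1 - m.max_side);
        for (int l = lmin; l <= j - 1; ++l) {
          if (p.b[p.id(k, l)] == NEG_INF) continue;
          int pin = pidx(p.s[k], p.s[l]);
          double g = interiorE(pio, pin, k - i - 1, j - l - 1, m);
          if (g >= E_INF / 2) continue;
          bh[p.id(k, l)] = lse(bh[p.id(k, l)], bh[c] - g / m.RT);
        }
      }
      // (i,j) closes a multiloop
      for (int u = i + 2; u <= j - 2; ++u) {
        double a1 = p.mm[p.id(i + 1, u - 1)], a2 = p.m1[p.id(u, j - 1)];
        if (a1 != NEG_INF)
          m1h[p.id(u, j - 1)] = lse(m1h[p.id(u, j - 1)], bh[c] + la + lb + a1);
        if (a2 != NEG_INF)
          mh[p.id(i + 1, u - 1)] = lse(mh[p.id(i + 1, u - 1)],
                                       bh[c] + la + lb + a2);
      }
    }
  }
  std::vector<double> paired(n + 1, 0.0);
  for (int i = 1; i <= n; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      size_t c = p.id(i, j);
      if (p.b[c] == NEG_INF || bh[c] == NEG_INF) continue;
      double pij = std::exp(p.b[c] + bh[c] - p.lnZ);
      paired[i] += pij;
      paired[j] += pij;
    }
  }
  for (int i = 1; i <= n; ++i) {
    double v = 1.0 - paired[i];
    if (v < 0) v = 0; else if (v > 1) v = 1;
    pu[i - 1] = v;
  }
  return pu;
}

// [[Rcpp::export]]
List cpp_pfold(IntegerVector seq, List model, LogicalVector forceUnpaired,
               bool wantPup) {
  PF p;
  p.n = seq.size();
  p.m = parse_model(model);
  p.s.assign(p.n + 1, -1);
  p.mask.assign(p.n + 1, 0);
  for (int i = 1; i <= p.n; ++i) {
    p.s[i] = seq[i - 1];
    p.mask[i] = forceUnpaired.size() ? (bool)forceUnpaired[i - 1] : false;
  }
  pf_inside(p);
  // internal consistency: forward and backward exterior sums must agree
  if (std::fabs(p.lnZ - p.qr[1]) > 1e-6 * (1.0 + std::fabs(p.lnZ)))
    stop("partition function inconsistency (qf vs qr)");
  List out = List::create(_["logZ"] = p.lnZ, _["pUnpaired"] = R_NilValue);
  if (wantPup) {
    NumericVector pu = pf_outside_pup(p);
    for (int i = 1; i <= p.n; ++i)
      if (p.mask[i] && pu[i - 1] < 1.0) pu[i - 1] = 1.0;
    out["pUnpaired"] = pu;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Stochastic traceback (Boltzmann sampling) from the inside matrices
// ---------------------------------------------------------------------------

struct Sampler {
  PF* p;
  double la, lb, lc;
  std::vector<int>* pairof; // 1-based partner vector, 0 = unpaired

  double runif() { return unif_rand(); }

  void sample_b(int i, int j);

  void sample_m1(int i, int j) {
    const EModel& m = p->m;
    double tot = p->m1[p->id(i, j)];
    double r = runif(), acc = 0.0;
    for (int l = i + m.min_h + 1; l <= j; ++l) {
      double bv = p->b[p->id(i, l)];
      if (bv == NEG_INF) continue;
      acc += std::exp(bv + lb + lc * (j - l) - tot);
      if (r <= acc || l == j) { sample_b(i, l); return; }
    }
  }

  void sample_m(int i, int j) {
    double tot = p->mm[p->id(i, j)];
    double r = runif(), acc = 0.0;
    for (int k = i; k <= j; ++k) {
      double m1v = p->m1[p->id(k, j)];
      if (m1v == NEG_INF) continue;
      acc += std::exp(lc * (k - i) + m1v - tot);
      if (r <= acc) { sample_m1(k, j); return; }
      if (k > i) {
        double mv = p->mm[p->id(i, k - 1)];
        if (mv != NEG_INF) {
          acc += std::exp(mv + m1v - tot);
          if (r <= acc) { sample_m(i, k - 1); sample_m1(k, j); return; }
        }
      }
    }
    // numerical fallback: last valid single-branch term
    for (int k = j; k >= i; --k)
      if (p->m1[p->id(k, j)] != NEG_INF) { sample_m1(k, j); return; }
  }

  void sample_exterior() {
    int j = p->n;
    while (j >= 1) {
      double tot = p->qf[j];
      double r = runif();
      double acc = std::exp(p->qf[j - 1] - tot);
      if (r <= acc) { --j; continue; }
      bool done = false;
      for (int k = 1; k <= j; ++k) {
        double bv = p->b[p->id(k, j)];
        if (bv == NEG_INF) continue;
        acc += std::exp(p->qf[k - 1] + bv - tot);
        if (r <= acc) { sample_b(k, j); j = k - 1; done = true; break; }
      }
      if (!done) --j; // numerical slack: treat as unpaired
    }
  }
};

void Sampler::sample_b(int i, int j) {
  const EModel& m = p->m;
  (*pairof)[i] = j; (*pairof)[j] = i;
  double tot = p->b[p->id(i, j)];
  int pio = pidx(p->s[i], p->s[j]);
  double r = runif();
  double acc = std::exp(p->lw(loopE(m.hairpin, j - i - 1, m)) - tot);
  if (r <= acc) return; // hairpin
  int kmax = std::min(i + m.max_side + 1, j - 1);
  for (int k = i + 1; k <= kmax; ++k) {
    int lmin = std::max(k + m.min_h + 1, j - 1 - m.max_side);
    for (int l = lmin; l <= j - 1; ++l) {
      double bv = p->b[p->id(k, l)];
      if (bv == NEG_INF) continue;
      int pin = pidx(p->s[k], p->s[l]);
      double g = interiorE(pio, pin, k - i - 1, j - l - 1, m);
      if (g >= E_INF / 2) continue;
      acc += std::exp(-g / m.RT + bv - tot);
      if (r <= acc) { sample_b(k, l); return; }
    }
  }
  for (int u = i + 2; u <= j - 2; ++u) {
    double a1 = p->mm[p->id(i + 1, u - 1)], a2 = p->m1[p->id(u, j - 1)];
    if (a1 == NEG_INF || a2 == NEG_INF) continue;
    acc += std::exp(la + lb + a1 + a2 - tot);
    if (r <= acc) { sample_m(i + 1, u - 1); sample_m1(u, j - 1); return; }
  }
  // numerical fallback: hairpin
}

// [[Rcpp::export]]
CharacterVector cpp_sample_structures(IntegerVector seq, List model, int n) {
  PF p;
  p.n = seq.size();
  p.m = parse_model(model);
  p.s.assign(p.n + 1, -1);
  p.mask.assign(p.n + 1, 0);
  for (int i = 1; i <= p.n; ++i) p.s[i] = seq[i - 1];
  pf_inside(p);
  Sampler sm;
  sm.p = &p;
  sm.la = p.lw(p.m.ml_a); sm.lb = p.lw(p.m.ml_b); sm.lc = p.lw(p.m.ml_c);
  CharacterVector out(n);
  std::vector<int> pairof;
  for (int t = 0; t < n; ++t) {
    pairof.assign(p.n + 1, 0);
    sm.pairof = &pairof;
    sm.sample_exterior();
    std::string db(p.n, '.');
    for (int i = 1; i <= p.n; ++i) {
      if (pairof[i] > i) { db[i - 1] = '('; db[pairof[i] - 1] = ')'; }
    }
    out[t] = db;
  }
  return out;
}
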