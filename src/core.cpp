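// Core landscape machinery: pair+stack energy model, MFE / partition
// function dynamic programming with per-pair soft constraints, stochastic
// backtracking, exhaustive enumeration, single base-pair move set and
// gradient walks.
//
// Conventions: sequences arrive as integer codes A=0, C=1, G=2, U=3;
// positions are 0-based here, 1-based at the R interface. Base-model
// energies are integer centi-kcal/mol so that comparisons and gradient-walk
// tie-breaking are exact; guiding-potential entries are real-valued
// kcal/mol and enter where a pair is formed.

#include <Rcpp.h>
#include <string>
#include <vector>
#include <map>
#include <unordered_map>
#include <cmath>

using namespace Rcpp;

static const int E_DISALLOWED = 1000000;  // sentinel in the 4x4 pair table
static const double E_INF = 1e15;         // min-plus infinity (centi-kcal)
static const int MIN_HAIRPIN_SPAN = 4;    // j - i >= 4: >=3 unpaired in a hairpin

struct EModel {
  int pe[4][4];
  int stack;  // centi-kcal per stacked adjacency
};

static EModel makeModel(const IntegerMatrix& pairE, int stackCenti) {
  if (pairE.nrow() != 4 || pairE.ncol() != 4)
    stop("pair energy table must be 4x4");
  EModel m;
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b)
      m.pe[a][b] = pairE(a, b);
  m.stack = stackCenti;
  return m;
}

static inline bool pairAllowed(const EModel& m, int a, int b) {
  return m.pe[a][b] != E_DISALLOWED;
}

static std::vector<int> ptFromDb(const std::string& db) {
  int n = (int)db.size();
  std::vector<int> pt(n, -1), open;
  for (int i = 0; i < n; ++i) {
    char c = db[i];
    if (c == '(') {
      open.push_back(i);
    } else if (c == ')') {
      if (open.empty()) stop("unbalanced brackets in dot-bracket string");
      int j = open.back();
      open.pop_back();
      pt[j] = i;
      pt[i] = j;
    } else if (c != '.') {
      stop("dot-bracket strings may only contain '(', ')' and '.'");
    }
  }
  if (!open.empty()) stop("unbalanced brackets in dot-bracket string");
  return pt;
}

static std::string dbFromPt(const std::vector<int>& pt) {
  std::string db(pt.size(), '.');
  for (size_t i = 0; i < pt.size(); ++i) {
    if (pt[i] >= 0) db[i] = ((int)i < pt[i]) ? '(' : ')';
  }
  return db;
}

// base-model energy in centi-kcal plus potential term in kcal
static inline double energyCenti(const std::vector<int>& seq,
                                 const std::vector<int>& pt,
                                 const EModel& m,
                                 const NumericMatrix& pot) {
  int n = (int)pt.size();
  long base = 0;
  double p = 0.0;
  bool hasPot = pot.nrow() > 0;
  for (int i = 0; i < n; ++i) {
    int j = pt[i];
    if (j > i) {
      base += m.pe[seq[i]][seq[j]];
      if (i + 1 < j - 1 && pt[i + 1] == j - 1) base += m.stack;
      if (hasPot) p += pot(i, j);
    }
  }
  return (double)base + 100.0 * p;
}

// [[Rcpp::export]]
double energy_cpp(IntegerVector seq, std::string db, IntegerMatrix pairE,
                  int stackCenti, NumericMatrix pot) {
  EModel m = makeModel(pairE, stackCenti);
  std::vector<int> s(seq.begin(), seq.end());
  std::vector<int> pt = ptFromDb(db);
  if ((int)pt.size() != (int)s.size()) stop("structure/sequence length mismatch");
  return energyCenti(s, pt, m, pot) / 100.0;
}

// ---------------------------------------------------------------------------
// MFE folding with lexicographically minimal traceback among co-optimal
// structures ('(' < ')' < '.', plain byte order).

struct MfeCtx {
  int n;
  const std::vector<int>* seq;
  const EModel* m;
  const NumericMatrix* pot;
  const LogicalMatrix* forbidden;
  std::vector<double> M, Mnp, Mp;  // centi-kcal
  std::map<long long, std::string> memo;

  inline double& at(std::vector<double>& t, int i, int j) { return t[(size_t)i * n + j]; }
  inline double getM(int i, int j) const { return (i > j) ? 0.0 : M[(size_t)i * n + j]; }
  inline double getMnp(int i, int j) const { return (i > j) ? 0.0 : Mnp[(size_t)i * n + j]; }
  inline double getMp(int i, int j) const { return (i > j) ? E_INF : Mp[(size_t)i * n + j]; }

  inline bool pairOk(int i, int j) const {
    if (j - i < MIN_HAIRPIN_SPAN) return false;
    if (!pairAllowed(*m, (*seq)[i], (*seq)[j])) return false;
    if (forbidden->nrow() > 0 && ((*forbidden)(i, j) || (*forbidden)(j, i))) return false;
    return true;
  }
  inline double wPair(int i, int j) const {
    double w = (double)m->pe[(*seq)[i]][(*seq)[j]];
    if (pot->nrow() > 0) w += 100.0 * (*pot)(i, j);
    return w;
  }

  void fill() {
    M.assign((size_t)n * n, 0.0);
    Mnp.assign((size_t)n * n, 0.0);
    Mp.assign((size_t)n * n, E_INF);
    for (int len = 1; len <= n; ++len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        if (len <= MIN_HAIRPIN_SPAN) continue;  // zeros/INF already correct
        double mp = E_INF;
        if (pairOk(i, j)) {
          double inside = std::min(getMnp(i + 1, j - 1),
                                   (double)m->stack + getMp(i + 1, j - 1));
          mp = wPair(i, j) + inside;
        }
        double mnp = getM(i + 1, j);
        for (int k = i + MIN_HAIRPIN_SPAN; k <= j - 1; ++k) {
          double v = getMp(i, k);
          if (v >= E_INF) continue;
          v += getM(k + 1, j);
          if (v < mnp) mnp = v;
        }
        at(Mp, i, j) = mp;
        at(Mnp, i, j) = mnp;
        at(M, i, j) = std::min(mnp, mp);
      }
    }
  }

  // tab: 0 = any, 1 = not-(i,j)-paired, 2 = (i,j) paired
  std::string lex(int tab, int i, int j) {
    if (i > j) return "";
    long long key = ((long long)tab * n + i) * n + j;
    auto it = memo.find(key);
    if (it != memo.end()) return it->second;
    std::string best;
    if (tab == 2) {
      // recompute the inside optimum from the stored candidate expressions:
      // subtracting wPair from Mp is not exact in floating point
      double a = getMnp(i + 1, j - 1);
      double b = (double)m->stack + getMp(i + 1, j - 1);
      double target = std::min(a, b);
      if (a == target) {
        best = lex(1, i + 1, j - 1);
        if (b == target) {
          std::string cand = lex(2, i + 1, j - 1);
          if (cand < best) best = cand;
        }
      } else {
        best = lex(2, i + 1, j - 1);
      }
      best = "(" + best + ")";
    } else {
      int len = j - i + 1;
      if (len <= MIN_HAIRPIN_SPAN) {
        best = std::string(len, '.');
      } else {
        double target = (tab == 0) ? getM(i, j) : getMnp(i, j);
        int kmax = (tab == 0) ? j : j - 1;
        bool have = false;
        for (int k = i + MIN_HAIRPIN_SPAN; k <= kmax; ++k) {
          double v = getMp(i, k);
          if (v >= E_INF) continue;
          if (v + getM(k + 1, j) == target) {
            std::string cand = lex(2, i, k) + lex(0, k + 1, j);
            if (!have || cand < best) best = cand;
            have = true;
          }
        }
        if (!have) best = "." + lex(0, i + 1, j);  // '(' always beats '.'
      }
    }
    memo[key] = best;
    return best;
  }
};

// [[Rcpp::export]]
List mfe_cpp(IntegerVector seq, IntegerMatrix pairE, int stackCenti,
             NumericMatrix pot, LogicalMatrix forbidden) {
  std::vector<int> s(seq.begin(), seq.end());
  EModel m = makeModel(pairE, stackCenti);
  MfeCtx ctx;
  ctx.n = (int)s.size();
  ctx.seq = &s;
  ctx.m = &m;
  ctx.pot = &pot;
  ctx.forbidden = &forbidden;
  ctx.fill();
  std::string db = (ctx.n > 0) ? ctx.lex(0, 0, ctx.n - 1) : "";
  double e = (ctx.n > 0) ? ctx.getM(0, ctx.n - 1) : 0.0;
  return List::create(_["db"] = db, _["energy"] = e / 100.0);
}

// ---------------------------------------------------------------------------
// Partition function with per-nucleotide rescaling (scale factor exp(lnq)
// per base, anchored at the MFE by the caller) and stochastic backtracking.

// [[Rcpp::export]]
List pf_cpp(IntegerVector seq, IntegerMatrix pairE, int stackCenti,
            NumericMatrix pot, double beta, double lnq) {
  std::vector<int> s(seq.begin(), seq.end());
  EModel m = makeModel(pairE, stackCenti);
  int n = (int)s.size();
  double invq = std::exp(-lnq);
  double wstack = std::exp(-beta * m.stack / 100.0);
  NumericMatrix Z(n, n), Zp(n, n), Znp(n, n);
  for (int len = 1; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      if (len <= MIN_HAIRPIN_SPAN) {
        double v = std::pow(invq, len);
        Z(i, j) = Znp(i, j) = v;
        Zp(i, j) = 0.0;
        continue;
      }
      double znp = invq * Z(i + 1, j);
      for (int k = i + MIN_HAIRPIN_SPAN; k <= j - 1; ++k) {
        if (Zp(i, k) > 0.0) znp += Zp(i, k) * Z(k + 1, j);
      }
      double zp = 0.0;
      if (pairAllowed(m, s[i], s[j])) {
        double e = m.pe[s[i]][s[j]] / 100.0;
        if (pot.nrow() > 0) e += pot(i, j);
        double wp = std::exp(-beta * e) * invq * invq;
        double inner = (j - 1 - (i + 1) >= MIN_HAIRPIN_SPAN)
                           ? (Znp(i + 1, j - 1) + wstack * Zp(i + 1, j - 1))
                           : std::pow(invq, j - i - 1);
        zp = wp * inner;
      }
      Zp(i, j) = zp;
      Znp(i, j) = znp;
      Z(i, j) = znp + zp;
      if (!R_finite(Z(i, j)))
        stop("partition function overflow; rescaling failed");
    }
  }
  double logZ = (n > 0) ? std::log(Z(0, n - 1)) + n * lnq : 0.0;
  return List::create(_["logZ"] = logZ, _["Z"] = Z, _["Zp"] = Zp,
                      _["Znp"] = Znp);
}

struct SampleCtx {
  int n;
  const std::vector<int>* seq;
  const EModel* m;
  const NumericMatrix* pot;
  double beta, invq, wstack;
  const NumericMatrix *Z, *Zp, *Znp;
  std::vector<int> pt;

  inline double getZ(int i, int j) const { return (i > j) ? 1.0 : (*Z)(i, j); }

  inline double wPair(int i, int j) const {
    double e = m->pe[(*seq)[i]][(*seq)[j]] / 100.0;
    if (pot->nrow() > 0) e += (*pot)(i, j);
    return std::exp(-beta * e) * invq * invq;
  }

  void samplePair(int i, int j) {
    pt[i] = j;
    pt[j] = i;
    int a = i + 1, b = j - 1;
    if (b - a < MIN_HAIRPIN_SPAN) return;  // inside forced unpaired
    double zn = (*Znp)(a, b), zs = wstack * (*Zp)(a, b);
    double r = unif_rand() * (zn + zs);
    if (r <= zn || zs <= 0.0) sampleNp(a, b);
    else samplePair(a, b);
  }

  // region [i,j] conditioned on (i,j) not being a pair (tab Znp);
  // withEndPair=true samples from Z (all structures) instead
  void sampleRegion(int i, int j, bool withEndPair) {
    while (true) {
      if (i > j || j - i < MIN_HAIRPIN_SPAN) return;
      double total = withEndPair ? (*Z)(i, j) : (*Znp)(i, j);
      double r = unif_rand() * total;
      double w = invq * getZ(i + 1, j);
      if (r <= w) { ++i; withEndPair = true; continue; }
      r -= w;
      int kmax = withEndPair ? j : j - 1;
      int kpick = -1;
      for (int k = i + MIN_HAIRPIN_SPAN; k <= kmax; ++k) {
        double wk = (*Zp)(i, k);
        if (wk <= 0.0) continue;
        wk *= getZ(k + 1, j);
        kpick = k;
        r -= wk;
        if (r <= 0.0) break;
      }
      if (kpick < 0) { ++i; withEndPair = true; continue; }  // fp safety
      samplePair(i, kpick);
      i = kpick + 1;
      withEndPair = true;
    }
  }
  void sampleNp(int i, int j) { sampleRegion(i, j, false); }
};

// [[Rcpp::export]]
CharacterVector sample_cpp(IntegerVector seq, IntegerMatrix pairE,
                           int stackCenti, NumericMatrix pot, double beta,
                           double lnq, NumericMatrix Z, NumericMatrix Zp,
                           NumericMatrix Znp, int count) {
  std::vector<int> s(seq.begin(), seq.end());
  EModel m = makeModel(pairE, stackCenti);
  SampleCtx ctx;
  ctx.n = (int)s.size();
  ctx.seq = &s;
  ctx.m = &m;
  ctx.pot = &pot;
  ctx.beta = beta;
  ctx.invq = std::exp(-lnq);
  ctx.wstack = std::exp(-beta * m.stack / 100.0);
  ctx.Z = &Z;
  ctx.Zp = &Zp;
  ctx.Znp = &Znp;
  CharacterVector out(count);
  for (int d = 0; d < count; ++d) {
    ctx.pt.assign(ctx.n, -1);
    if (ctx.n > 0) ctx.sampleRegion(0, ctx.n - 1, true);
    out[d] = dbFromPt(ctx.pt);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exhaustive enumeration of the conformation space.

struct EnumCtx {
  int n;
  const std::vector<int>* seq;
  const EModel* m;
  const NumericMatrix* pot;
  double ceiling;
  std::vector<int> pt;
  std::vector<int> closeStack;
  std::vector<std::string> dbs;
  std::vector<double> energies;

  void emit() {
    if ((double)dbs.size() >= ceiling)
      stop("enumeration ceiling of %.0f structures exceeded", ceiling);
    dbs.push_back(dbFromPt(pt));
    energies.push_back(energyCenti(*seq, pt, *m, *pot) / 100.0);
  }

  void rec(int i) {
    if (i == n) { emit(); return; }
    if (!closeStack.empty() && closeStack.back() == i) {
      int c = closeStack.back();
      closeStack.pop_back();
      rec(i + 1);
      closeStack.push_back(c);
      return;
    }
    rec(i + 1);  // i unpaired
    int bound = closeStack.empty() ? n : closeStack.back();
    for (int k = i + MIN_HAIRPIN_SPAN; k < bound; ++k) {
      if (!pairAllowed(*m, (*seq)[i], (*seq)[k])) continue;
      pt[i] = k;
      pt[k] = i;
      closeStack.push_back(k);
      rec(i + 1);
      closeStack.pop_back();
      pt[i] = -1;
      pt[k] = -1;
    }
  }
};

// [[Rcpp::export]]
List enumerate_cpp(IntegerVector seq, IntegerMatrix pairE, int stackCenti,
                   NumericMatrix pot, double ceiling) {
  std::vector<int> s(seq.begin(), seq.end());
  EModel m = makeModel(pairE, stackCenti);
  EnumCtx ctx;
  ctx.n = (int)s.size();
  ctx.seq = &s;
  ctx.m = &m;
  ctx.pot = &pot;
  ctx.ceiling = ceiling;
  ctx.pt.assign(ctx.n, -1);
  if (ctx.n > 0) ctx.rec(0); else ctx.emit();
  return List::create(_["db"] = wrap(ctx.dbs), _["energy"] = wrap(ctx.energies));
}

// ---------------------------------------------------------------------------
// Move set (single base-pair insertion/removal) and gradient walks.

static void collectNeighbors(const std::vector<int>& seq,
                             const std::vector<int>& pt, const EModel& m,
                             const NumericMatrix& pot,
                             std::vector<std::vector<int> >& out) {
  int n = (int)pt.size();
  // removals
  for (int i = 0; i < n; ++i) {
    int j = pt[i];
    if (j > i) {
      std::vector<int> q(pt);
      q[i] = -1;
      q[j] = -1;
      out.push_back(q);
    }
  }
  // insertions
  std::vector<std::pair<int, int> > pairs;
  for (int i = 0; i < n; ++i)
    if (pt[i] > i) pairs.push_back(std::make_pair(i, pt[i]));
  for (int i = 0; i < n; ++i) {
    if (pt[i] >= 0) continue;
    for (int j = i + MIN_HAIRPIN_SPAN; j < n; ++j) {
      if (pt[j] >= 0) continue;
      if (!pairAllowed(m, seq[i], seq[j])) continue;
      bool cross = false;
      for (size_t p = 0; p < pairs.size(); ++p) {
        int a = pairs[p].first, b = pairs[p].second;
        if ((a < i && i < b && b < j) || (i < a && a < j && j < b)) {
          cross = true;
          break;
        }
      }
      if (cross) continue;
      std::vector<int> q(pt);
      q[i] = j;
      q[j] = i;
      out.push_back(q);
    }
  }
  (void)pot;
}

// [[Rcpp::export]]
List neighbors_cpp(IntegerVector seq, std::string db, IntegerMatrix pairE,
                   int stackCenti, NumericMatrix pot) {
  std::vector<int> s(seq.begin(), seq.end());
  EModel m = makeModel(pairE, stackCenti);
  std::vector<int> pt = ptFromDb(db);
  if (pt.size() != s.size()) stop("structure/sequence length mismatch");
  std::vector<std::vector<int> > nb;
  collectNeighbors(s, pt, m, pot, nb);
  CharacterVector dbs(nb.size());
  NumericVector es(nb.size());
  for (size_t k = 0; k < nb.size(); ++k) {
    dbs[k] = dbFromPt(nb[k]);
    es[k] = energyCenti(s, nb[k], m, pot) / 100.0;
  }
  return List::create(_["db"] = dbs, _["energy"] = es);
}

// one steepest-descent step; returns false at a local minimum
static bool walkStep(const std::vector<int>& seq, std::vector<int>& pt,
                     double& eCur, const EModel& m, const NumericMatrix& pot) {
  std::vector<std::vector<int> > nb;
  collectNeighbors(seq, pt, m, pot, nb);
  double best = eCur;
  std::string bestDb;
  int bestIdx = -1;
  for (size_t k = 0; k < nb.size(); ++k) {
    double e = energyCenti(seq, nb[k], m, pot);
    if (e < best) {
      best = e;
      bestDb = dbFromPt(nb[k]);
      bestIdx = (int)k;
    } else if (bestIdx >= 0 && e == best) {
      std::string db = dbFromPt(nb[k]);
      if (db < bestDb) {
        bestDb = db;
        bestIdx = (int)k;
      }
    }
  }
  if (bestIdx < 0) return false;
  pt = nb[bestIdx];
  eCur = best;
  return true;
}

// [[Rcpp::export]]
std::string gradient_walk_cpp(IntegerVector seq, std::string db,
                              IntegerMatrix pairE, int stackCenti,
                              NumericMatrix pot) {
  std::vector<int> s(seq.begin(), seq.end());
  EModel m = makeModel(pairE, stackCenti);
  std::vector<int> pt = ptFromDb(db);
  if (pt.size() != s.size()) stop("structure/sequence length mismatch");
  double e = energyCenti(s, pt, m, pot);
  while (walkStep(s, pt, e, m, pot)) {
  }
  return dbFromPt(pt);
}

// walk many structures, memoising every visited structure -> minimum
// [[Rcpp::export]]
CharacterVector gradient_walk_many_cpp(IntegerVector seq, CharacterVector dbs,
                                       IntegerMatrix pairE, int stackCenti,
                                       NumericMatrix pot) {
  std::vector<int> s(seq.begin(), seq.end());
  EModel m = makeModel(pairE, stackCenti);
  std::unordered_map<std::string, std::string> cache;
  CharacterVector out(dbs.size());
  for (int d = 0; d < dbs.size(); ++d) {
    std::string start = as<std::string>(dbs[d]);
    auto hit = cache.find(start);
    if (hit != cache.end()) {
      out[d] = hit->second;
      continue;
    }
    std::vector<int> pt = ptFromDb(start);
    if (pt.size() != s.size()) stop("structure/sequence length mismatch");
    double e = energyCenti(s, pt, m, pot);
    std::vector<std::string> path;
    path.push_back(start);
    std::string minDb = start;
    while (true) {
      if (!walkStep(s, pt, e, m, pot)) {
        minDb = dbFromPt(pt);
        break;
      }
      std::string cur = dbFromPt(pt);
      auto h2 = cache.find(cur);
      if (h2 != cache.end()) {
        minDb = h2->second;
        break;
      }
      path.push_back(cur);
    }
    for (size_t p = 0; p < path.size(); ++p) cache[path[p]] = minDb;
    out[d] = minDb;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Base-pair distance

// [[Rcpp::export]]
int bp_distance_cpp(std::string db1, std::string db2) {
  std::vector<int> p1 = ptFromDb(db1), p2 = ptFromDb(db2);
  if (p1.size() != p2.size()) stop("structures must have equal length");
  int n1 = 0, n2 = 0, common = 0;
  for (size_t i = 0; i < p1.size(); ++i) {
    if (p1[i] > (int)i) ++n1;
    if (p2[i] > (int)i) ++n2;
    if (p1[i] > (int)i && p1[i] == p2[i]) ++common;
  }
  return n1 + n2 - 2 * common;
}

// [[Rcpp::export]]
IntegerVector bp_distance_batch_cpp(CharacterVector dbs, std::string ref) {
  std::vector<int> pr = ptFromDb(ref);
  IntegerVector out(dbs.size());
  for (int d = 0; d < dbs.size(); ++d) {
    std::vector<int> p = ptFromDb(as<std::string>(dbs[d]));
    if (p.size() != pr.size()) stop("structures must have equal length");
    int n1 = 0, n2 = 0, common = 0;
    for (size_t i = 0; i < p.size(); ++i) {
      if (p[i] > (int)i) ++n1;
      if (pr[i] > (int)i) ++n2;
      if (p[i] > (int)i && p[i] == pr[i]) ++common;
    }
    out[d] = n1 + n2 - 2 * common;
  }
  return out;
}
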