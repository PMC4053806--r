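#include <Rcpp.h>
#include <queue>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

// Built-in secondary-structure folder: Nussinov-style minimisation with a
// stacking-aware score, plus exact best-first (Wuchty-style) enumeration of
// all suboptimal structures within an energy threshold.
//
// Score model (arbitrary units, negative = stable): every pair pays an
// opening penalty p_open; a pair directly stacked on another receives a
// bonus equal to minus the mean strength of the two pairs (GC/AU/GU
// strengths s_gc/s_au/s_gu). With the defaults an isolated pair is never
// favorable, mimicking the "no lonely pairs" behavior of thermodynamic
// folders, while stacked helices gain roughly -(strength - p_open) per
// added pair. Hairpin loops require at least `min_loop` unpaired
// nucleotides. 'N' never pairs. Setting p_open = -1 and all strengths to 0
// recovers the plain maximum-pairing (Nussinov) score.
//
// Matrices:
//   W(i,j)  best score over all structures on [i,j]
//   V(i,j)  best score given (i,j) paired
// Decomposition (unambiguous, so enumeration emits each structure once):
//   W(i,j) = min( W(i+1,j), min_k V(i,k) + W(k+1,j) )
//   V(i,j) = e_pair(i,j) + min( V(i+1,j-1) + e_stack, Wx(i+1,j-1) )
//   Wx(a,b) = W-like but excluding the case where (a,b) pair with each other
//             (that case is handled, with the stack bonus, by the V branch)

static const double INF = std::numeric_limits<double>::infinity();

struct FoldCtx {
  int n;
  std::vector<int> s;             // 0=A 1=C 2=G 3=U 4=N
  double p_open, s_gc, s_au, s_gu;
  int min_loop;
  std::vector<double> W, V, WX;
  double& w(int i, int j) { return W[i * n + j]; }
  double& v(int i, int j) { return V[i * n + j]; }
  double& wxref(int i, int j) { return WX[i * n + j]; }
  double wat(int i, int j) const { return (i > j) ? 0.0 : W[i * n + j]; }
  double vat(int i, int j) const { return (i < 0 || j >= n || i >= j) ? INF : V[i * n + j]; }
  double strength(int i, int j) const {
    int a = s[i], b = s[j];
    if ((a == 2 && b == 1) || (a == 1 && b == 2)) return s_gc;
    if ((a == 0 && b == 3) || (a == 3 && b == 0)) return s_au;
    if ((a == 2 && b == 3) || (a == 3 && b == 2)) return s_gu;
    return INF;
  }
  bool canPair(int i, int j) const {
    return j - i - 1 >= min_loop && strength(i, j) < INF;
  }
  double pairE(int i, int j) const {
    return canPair(i, j) ? p_open : INF;
  }
  // stacking bonus when (i+1, j-1) is paired directly under (i, j)
  double stackB(int i, int j) const {
    return -(strength(i, j) + strength(i + 1, j - 1)) / 2.0;
  }
  // Wx(a,b): best over structures on [a,b] where a is unpaired or pairs k < b
  double wx(int a, int b) const {
    if (a > b) return 0.0;
    return WX[a * n + b];
  }
};

static void fill_dp(FoldCtx& C) {
  int n = C.n;
  C.W.assign((size_t)n * n, 0.0);
  C.V.assign((size_t)n * n, INF);
  C.WX.assign((size_t)n * n, 0.0);
  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      if (C.canPair(i, j)) {
        double stk = (C.vat(i + 1, j - 1) < INF)
          ? C.vat(i + 1, j - 1) + C.stackB(i, j) : INF;
        double inner = std::min(stk, C.wx(i + 1, j - 1));
        C.v(i, j) = C.pairE(i, j) + inner;
      }
      double best = C.wat(i + 1, j);
      double bestx = best;   // Wx: same cases except k == j
      for (int k = i + C.min_loop + 1; k <= j; ++k) {
        double vv = C.vat(i, k);
        if (vv < INF) {
          double cand = vv + C.wat(k + 1, j);
          if (cand < best) best = cand;
          if (k < j && cand < bestx) bestx = cand;
        }
      }
      C.w(i, j) = best;
      C.wxref(i, j) = bestx;
    }
  }
}

// ---- best-first enumeration -------------------------------------------------

enum TaskKind { TW = 0, TV = 1, TX = 2 };

struct Task { int kind, i, j; };

struct EnumState {
  double fixed;                  // energy of decisions taken so far
  double bound;                  // fixed + sum of optimal task completions
  long id;                       // insertion order, for deterministic ties
  std::vector<std::pair<int,int> > pairs;
  std::vector<Task> tasks;
};

struct StateCmp {
  bool operator()(const EnumState& a, const EnumState& b) const {
    if (a.bound != b.bound) return a.bound > b.bound;
    return a.id > b.id;
  }
};

static double task_value(const FoldCtx& C, const Task& t) {
  switch (t.kind) {
    case TW: return C.wat(t.i, t.j);
    case TV: return C.vat(t.i, t.j);
    default: return C.wx(t.i, t.j);
  }
}

// [[Rcpp::export(name = ".fold_enumerate")]]
List fold_enumerate(std::string seq,
                    double threshold,
                    int max_structures,
                    double p_open = 1.5, double s_gc = 4.5,
                    double s_au = 3.5, double s_gu = 2.5,
                    int min_loop = 3) {
  FoldCtx C;
  C.n = (int)seq.size();
  C.p_open = p_open; C.s_gc = s_gc; C.s_au = s_au; C.s_gu = s_gu;
  C.min_loop = min_loop;
  C.s.resize(C.n);
  for (int i = 0; i < C.n; ++i) {
    switch (seq[i]) {
      case 'A': C.s[i] = 0; break;
      case 'C': C.s[i] = 1; break;
      case 'G': C.s[i] = 2; break;
      case 'U': case 'T': C.s[i] = 3; break;
      default:  C.s[i] = 4; break;
    }
  }
  double mfe = 0.0;
  if (C.n >= 2) {
    fill_dp(C);
    mfe = C.wat(0, C.n - 1);
  }

  List out_structs;
  NumericVector energies;
  std::vector<double> evec;
  std::vector<std::vector<std::pair<int,int> > > pvec;

  std::priority_queue<EnumState, std::vector<EnumState>, StateCmp> pq;
  long next_id = 0;
  EnumState root;
  root.fixed = 0.0;
  root.bound = mfe;
  root.id = next_id++;
  if (C.n >= 2) root.tasks.push_back(Task{TW, 0, C.n - 1});
  pq.push(root);

  while (!pq.empty() && (int)pvec.size() < max_structures) {
    EnumState st = pq.top(); pq.pop();
    if (st.bound > threshold + 1e-9) break;
    if (st.tasks.empty()) {
      pvec.push_back(st.pairs);
      evec.push_back(st.bound);
      continue;
    }
    Task t = st.tasks.back();
    st.tasks.pop_back();

    if (t.kind == TV) {
      // commit the pair (t.i, t.j)
      EnumState base = st;
      base.pairs.push_back(std::make_pair(t.i, t.j));
      base.fixed += C.pairE(t.i, t.j);
      int a = t.i + 1, b = t.j - 1;
      // branch 1: inner pair stacked directly
      if (C.vat(a, b) < INF) {
        EnumState nb = base;
        nb.fixed += C.stackB(t.i, t.j);
        nb.tasks.push_back(Task{TV, a, b});
        nb.bound = nb.fixed;
        for (size_t q = 0; q < nb.tasks.size(); ++q) nb.bound += task_value(C, nb.tasks[q]);
        nb.id = next_id++;
        pq.push(nb);
      }
      // branch 2: anything else inside
      {
        EnumState nb = base;
        nb.tasks.push_back(Task{TX, a, b});
        nb.bound = nb.fixed;
        for (size_t q = 0; q < nb.tasks.size(); ++q) nb.bound += task_value(C, nb.tasks[q]);
        nb.id = next_id++;
        pq.push(nb);
      }
      continue;
    }

    int i = t.i, j = t.j;
    if ((t.kind == TW && i > j)) {
      st.bound = st.fixed;
      for (size_t q = 0; q < st.tasks.size(); ++q) st.bound += task_value(C, st.tasks[q]);
      st.id = next_id++;
      pq.push(st);
      continue;
    }
    // branch: i unpaired
    {
      EnumState nb = st;
      if (t.kind == TW) { if (i <= j) nb.tasks.push_back(Task{TW, i + 1, j}); }
      else { nb.tasks.push_back(Task{TW, i + 1, j}); }
      nb.bound = nb.fixed;
      for (size_t q = 0; q < nb.tasks.size(); ++q) nb.bound += task_value(C, nb.tasks[q]);
      nb.id = next_id++;
      pq.push(nb);
    }
    // branches: i pairs k (for TX, k < j; for TW, k <= j)
    int kmax = (t.kind == TX) ? j - 1 : j;
    for (int k = i + C.min_loop + 1; k <= kmax; ++k) {
      if (C.vat(i, k) < INF) {
        EnumState nb = st;
        nb.tasks.push_back(Task{TW, k + 1, j});
        nb.tasks.push_back(Task{TV, i, k});
        nb.bound = nb.fixed;
        for (size_t q = 0; q < nb.tasks.size(); ++q) nb.bound += task_value(C, nb.tasks[q]);
        nb.id = next_id++;
        pq.push(nb);
      }
    }
  }

  // empty sequence or nothing enumerated: the open structure
  if (pvec.empty()) {
    pvec.push_back(std::vector<std::pair<int,int> >());
    evec.push_back(0.0);
  }

  int m = (int)pvec.size();
  List structs(m);
  NumericVector en(m);
  for (int q = 0; q < m; ++q) {
    int np = (int)pvec[q].size();
    IntegerMatrix pm(np, 2);
    for (int r = 0; r < np; ++r) {
      pm(r, 0) = pvec[q][r].first + 1;   // 1-based for R
      pm(r, 1) = pvec[q][r].second + 1;
    }
    structs[q] = pm;
    en[q] = evec[q];
  }
  return List::create(_["mfe"] = mfe, _["pairs"] = structs, _["energy"] = en);
}

// [[Rcpp::export(name = ".fold_mfe")]]
double fold_mfe(std::string seq,
                double p_open = 1.5, double s_gc = 4.5,
                double s_au = 3.5, double s_gu = 2.5, int min_loop = 3) {
  List r = fold_enumerate(seq, -INF, 1, p_open, s_gc, s_au, s_gu, min_loop);
  return as<double>(r["mfe"]);
}
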