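// Minimum-free-energy folding of a single RNA under a simplified
// nearest-neighbour model: Watson-Crick + G:U pairs, stacking energies for
// directly adjacent pairs, flat loop penalties (hairpin, bulge/internal),
// zero multiloop/exterior terms, nested structures only, hairpin loops >= 3.
// Ties are broken toward fewer pairs, then by a fixed traceback option order.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();
const double EPS = 1e-7;

struct En {
  double e;
  int p;  // number of pairs, the first-order tie-break
};

inline bool better(const En& a, const En& b) {
  if (a.e < b.e - EPS) return true;
  if (a.e > b.e + EPS) return false;
  return a.p < b.p;
}

inline bool same(const En& a, const En& b) {
  return std::fabs(a.e - b.e) <= EPS && a.p == b.p;
}

inline En add(const En& a, const En& b) {
  En r;
  r.e = a.e + b.e;
  r.p = a.p + b.p;
  return r;
}

// bases: A=0, C=1, G=2, U=3, N=4 (N never pairs)
// pair types: 0 AU, 1 UA, 2 CG, 3 GC, 4 GU, 5 UG, -1 none
inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

struct Model {
  // 4x4 stacking table over WC pair types (outer x inner); any stack
  // involving a G:U pair uses the single gu_stack term instead.
  double stack[4][4];
  double gu_stack;
  double hairpin_pen;
  double loop_pen;  // bulge / internal loop, per loop
  int min_hairpin;
  int max_loop;

  double stack_energy(int outer_pt, int inner_pt) const {
    if (outer_pt >= 4 || inner_pt >= 4) return gu_stack;
    return stack[outer_pt][inner_pt];
  }
};

class Folder {
 public:
  Folder(const std::vector<int>& s, const Model& m) : s_(s), m_(m), n_((int)s.size()) {
    size_t nn = (size_t)n_ * n_;
    V_.assign(nn, En{INF, 0});
    M1_.assign(nn, En{INF, 0});
    M2_.assign(nn, En{INF, 0});
    W_.assign(n_ > 0 ? n_ : 1, En{0.0, 0});
    partner_.assign(n_, -1);
  }

  void run() {
    if (n_ == 0) return;
    fill();
    traceback();
  }

  double mfe() const { return n_ ? W_[n_ - 1].e : 0.0; }
  int npairs() const { return n_ ? W_[n_ - 1].p : 0; }
  const std::vector<int>& partner() const { return partner_; }

 private:
  const std::vector<int>& s_;
  Model m_;
  int n_;
  std::vector<En> V_, M1_, M2_;
  std::vector<En> W_;
  std::vector<int> partner_;

  inline size_t ix(int i, int j) const { return (size_t)i * n_ + j; }
  inline bool can_pair(int i, int j) const {
    return pair_type(s_[i], s_[j]) >= 0 && (j - i - 1) >= m_.min_hairpin;
  }

  En compV(int i, int j) const {
    // assumes can_pair(i, j)
    En best{m_.hairpin_pen, 1};
    // stack on the immediately inner pair
    if (i + 1 < j - 1 && can_pair(i + 1, j - 1) && V_[ix(i + 1, j - 1)].e < INF) {
      En cand{m_.stack_energy(pair_type(s_[i], s_[j]), pair_type(s_[i + 1], s_[j - 1])) +
                  V_[ix(i + 1, j - 1)].e,
              1 + V_[ix(i + 1, j - 1)].p};
      if (better(cand, best)) best = cand;
    }
    // bulge / internal loop closing exactly one inner pair (k, l)
    for (int k = i + 1; k <= j - 2; ++k) {
      int l1 = k - i - 1;
      if (l1 > m_.max_loop) break;
      for (int l = j - 1; l > k; --l) {
        int l2 = j - l - 1;
        if (l1 + l2 < 1) continue;  // (i+1, j-1) is the stack case
        if (l1 + l2 > m_.max_loop) break;
        const En& inner = V_[ix(k, l)];
        if (inner.e >= INF) continue;
        En cand{m_.loop_pen + inner.e, 1 + inner.p};
        if (better(cand, best)) best = cand;
      }
    }
    // multiloop: >= 2 inner branches, no closing penalty under this model
    if (i + 1 <= j - 1) {
      const En& m2 = M2_[ix(i + 1, j - 1)];
      if (m2.e < INF) {
        En cand{m2.e, 1 + m2.p};
        if (better(cand, best)) best = cand;
      }
    }
    return best;
  }

  void fill() {
    for (int span = m_.min_hairpin + 1; span < n_; ++span) {
      for (int i = 0; i + span < n_; ++i) {
        int j = i + span;
        if (can_pair(i, j)) V_[ix(i, j)] = compV(i, j);
        // M1: >= 1 branch on [i, j]
        En best{INF, 0};
        if (j > i && M1_[ix(i, j - 1)].e < INF) best = M1_[ix(i, j - 1)];
        for (int k = i; k <= j - m_.min_hairpin - 1; ++k) {
          const En& v = V_[ix(k, j)];
          if (v.e >= INF) continue;
          En pre{0.0, 0};
          if (k > i && M1_[ix(i, k - 1)].e < INF && better(M1_[ix(i, k - 1)], pre))
            pre = M1_[ix(i, k - 1)];
          En cand = add(pre, v);
          if (better(cand, best)) best = cand;
        }
        M1_[ix(i, j)] = best;
        // M2: >= 2 branches on [i, j]
        En best2{INF, 0};
        if (j > i && M2_[ix(i, j - 1)].e < INF) best2 = M2_[ix(i, j - 1)];
        for (int k = i + m_.min_hairpin + 2; k <= j - m_.min_hairpin - 1; ++k) {
          const En& v = V_[ix(k, j)];
          if (v.e >= INF) continue;
          const En& pre = M1_[ix(i, k - 1)];
          if (pre.e >= INF) continue;
          En cand = add(pre, v);
          if (better(cand, best2)) best2 = cand;
        }
        M2_[ix(i, j)] = best2;
      }
    }
    // exterior
    for (int j = 0; j < n_; ++j) {
      En best = (j > 0) ? W_[j - 1] : En{0.0, 0};
      for (int k = 0; k <= j - m_.min_hairpin - 1; ++k) {
        const En& v = V_[ix(k, j)];
        if (v.e >= INF) continue;
        En pre = (k > 0) ? W_[k - 1] : En{0.0, 0};
        En cand = add(pre, v);
        if (better(cand, best)) best = cand;
      }
      W_[j] = best;
    }
  }

  struct Frame {
    char type;  // 'W', 'V', '1', '2'
    int i, j;
  };

  void traceback() {
    if (n_ == 0) return;
    std::vector<Frame> st;
    st.push_back(Frame{'W', 0, n_ - 1});
    while (!st.empty()) {
      Frame f = st.back();
      st.pop_back();
      if (f.type == 'W') {
        int j = f.j;
        while (j >= 0) {
          En here = W_[j];
          En prev = (j > 0) ? W_[j - 1] : En{0.0, 0};
          if (same(here, prev)) {
            --j;
            continue;
          }
          bool found = false;
          for (int k = 0; k <= j - m_.min_hairpin - 1 && !found; ++k) {
            const En& v = V_[ix(k, j)];
            if (v.e >= INF) continue;
            En pre = (k > 0) ? W_[k - 1] : En{0.0, 0};
            if (same(add(pre, v), here)) {
              st.push_back(Frame{'V', k, j});
              j = k - 1;
              found = true;
            }
          }
          if (!found) --j;  // defensive; should not happen
        }
      } else if (f.type == 'V') {
        trace_V(f.i, f.j, st);
      } else if (f.type == '1') {
        trace_M(f.i, f.j, st, false);
      } else {
        trace_M(f.i, f.j, st, true);
      }
    }
  }

  void trace_V(int i, int j, std::vector<Frame>& st) {
    partner_[i] = j;
    partner_[j] = i;
    En here = V_[ix(i, j)];
    // hairpin
    if (same(here, En{m_.hairpin_pen, 1})) return;
    // stack
    if (i + 1 < j - 1 && can_pair(i + 1, j - 1) && V_[ix(i + 1, j - 1)].e < INF) {
      En cand{m_.stack_energy(pair_type(s_[i], s_[j]), pair_type(s_[i + 1], s_[j - 1])) +
                  V_[ix(i + 1, j - 1)].e,
              1 + V_[ix(i + 1, j - 1)].p};
      if (same(cand, here)) {
        st.push_back(Frame{'V', i + 1, j - 1});
        return;
      }
    }
    // internal / bulge
    for (int k = i + 1; k <= j - 2; ++k) {
      int l1 = k - i - 1;
      if (l1 > m_.max_loop) break;
      for (int l = j - 1; l > k; --l) {
        int l2 = j - l - 1;
        if (l1 + l2 < 1) continue;
        if (l1 + l2 > m_.max_loop) break;
        const En& inner = V_[ix(k, l)];
        if (inner.e >= INF) continue;
        En cand{m_.loop_pen + inner.e, 1 + inner.p};
        if (same(cand, here)) {
          st.push_back(Frame{'V', k, l});
          return;
        }
      }
    }
    // multiloop
    if (i + 1 <= j - 1 && M2_[ix(i + 1, j - 1)].e < INF) {
      En cand{M2_[ix(i + 1, j - 1)].e, 1 + M2_[ix(i + 1, j - 1)].p};
      if (same(cand, here)) st.push_back(Frame{'2', i + 1, j - 1});
    }
  }

  void trace_M(int i, int j, std::vector<Frame>& st, bool two) {
    while (j >= i) {
      const En& here = two ? M2_[ix(i, j)] : M1_[ix(i, j)];
      if (here.e >= INF) return;
      if (j > i) {
        const En& prev = two ? M2_[ix(i, j - 1)] : M1_[ix(i, j - 1)];
        if (prev.e < INF && same(here, prev)) {
          --j;
          continue;
        }
      }
      if (two) {
        for (int k = i + m_.min_hairpin + 2; k <= j - m_.min_hairpin - 1; ++k) {
          const En& v = V_[ix(k, j)];
          if (v.e >= INF) continue;
          const En& pre = M1_[ix(i, k - 1)];
          if (pre.e >= INF) continue;
          if (same(add(pre, v), here)) {
            st.push_back(Frame{'V', k, j});
            st.push_back(Frame{'1', i, k - 1});
            return;
          }
        }
        return;  // defensive
      } else {
        for (int k = i; k <= j - m_.min_hairpin - 1; ++k) {
          const En& v = V_[ix(k, j)];
          if (v.e >= INF) continue;
          En pre{0.0, 0};
          bool pre_m1 = false;
          if (k > i && M1_[ix(i, k - 1)].e < INF && better(M1_[ix(i, k - 1)], En{0.0, 0})) {
            pre = M1_[ix(i, k - 1)];
            pre_m1 = true;
          }
          if (same(add(pre, v), here)) {
            st.push_back(Frame{'V', k, j});
            if (pre_m1) {
              st.push_back(Frame{'1', i, k - 1});
            }
            return;
          }
        }
        return;  // defensive
      }
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".fold_engine")]]
List fold_engine(IntegerVector seq_codes, NumericMatrix stack_table, double gu_stack,
                 double hairpin_penalty, double loop_penalty, int min_hairpin,
                 int max_loop) {
  int n = seq_codes.size();
  if (stack_table.nrow() != 4 || stack_table.ncol() != 4)
    stop("stacking table must be 4 x 4");
  Model m;
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) m.stack[a][b] = stack_table(a, b);
  m.gu_stack = gu_stack;
  m.hairpin_pen = hairpin_penalty;
  m.loop_pen = loop_penalty;
  m.min_hairpin = min_hairpin;
  m.max_loop = max_loop;

  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    int c = seq_codes[i];
    if (c < 0 || c > 4) stop("sequence codes must be in 0..4");
    s[i] = c;
  }

  Folder f(s, m);
  f.run();

  IntegerVector pt(n, 0);
  std::string db(n, '.');
  const std::vector<int>& partner = f.partner();
  for (int i = 0; i < n; ++i) {
    if (partner[i] >= 0) {
      pt[i] = partner[i] + 1;  // 1-based, 0 = unpaired
      db[i] = (partner[i] > i) ? '(' : ')';
    }
  }
  return List::create(_["structure"] = db, _["mfe"] = f.mfe(),
                      _["pair_table"] = pt, _["n_pairs"] = f.npairs());
}
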