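// Structure MCMC over per-child fragment assignments under a joint
// acyclicity constraint.  Each of the M returned networks is the end state
// of an independent chain started from the empty network (fragment 0 of
// every child must be the empty fragment).
//
// Two move types with the fragment-product posterior as target:
//  * single-child Gibbs: mask out fragments whose parent set intersects the
//    descendants of the child, draw among the feasible ones with
//    probability proportional to exp(score - max score);
//  * pair-block Gibbs: jointly resample the fragments of a random pair of
//    children from their exact joint conditional.  Single-child updates
//    cannot reverse an edge between two strongly dependent variables (the
//    intermediate edge-free state has negligible probability), so this
//    move is what lets the chain cross between equivalent orientations.
//    It enumerates |F_i| x |F_j| combinations and is only applied when
//    that product is at most max_pair_combos.
//
// Parent sets are bitmasks in flat contiguous arrays (64-bit words, W words
// per mask) so the hot loops stream through memory.  Randomness comes from
// R's RNG, so set.seed() upstream makes the output deterministic.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Sampler {
  int n, W;
  std::vector<int> nf;                 // fragments per child
  std::vector<size_t> off;             // mask offset per child (words)
  std::vector<uint64_t> mask;          // all fragment parent masks, flat
  std::vector<std::vector<double> > wgt;
  std::vector<int> choice;
  std::vector<uint64_t> cur;           // current parent mask per child, flat
  std::vector<int> stack;
  std::vector<uint64_t> reach, reach2;
  std::vector<double> cum;
  std::vector<int> feas, feas2;

  const uint64_t* fmask(int c, int j) const { return &mask[off[c] + (size_t)j * W]; }

  static bool inter(const uint64_t* a, const uint64_t* b, int W) {
    for (int k = 0; k < W; ++k)
      if (a[k] & b[k]) return true;
    return false;
  }

  void set_choice(int c, int j) {
    choice[c] = j;
    const uint64_t* m = fmask(c, j);
    for (int k = 0; k < W; ++k) cur[(size_t)c * W + k] = m[k];
  }

  // nodes reachable from v (incl. v) following current edges, skipping the
  // parent sets of children drop1/drop2 (being resampled)
  void reach_from(int v, std::vector<uint64_t>& out, int drop1 = -1,
                  int drop2 = -1) {
    std::fill(out.begin(), out.end(), 0);
    int top = 0;
    stack[top++] = v;
    out[v >> 6] |= (uint64_t(1) << (v & 63));
    while (top > 0) {
      int x = stack[--top];
      const int word = x >> 6;
      const uint64_t bit = uint64_t(1) << (x & 63);
      for (int c = 0; c < n; ++c) {
        if (c == drop1 || c == drop2) continue;
        if ((cur[(size_t)c * W + word] & bit) &&
            !((out[c >> 6] >> (c & 63)) & 1)) {
          out[c >> 6] |= (uint64_t(1) << (c & 63));
          stack[top++] = c;
        }
      }
    }
  }

  void update_child(int c) {
    reach_from(c, reach);
    const int m = nf[c];
    const double* w = wgt[c].data();
    cum.clear();
    feas.clear();
    double tot = 0.0;
    const uint64_t* base = &mask[off[c]];
    for (int j = 0; j < m; ++j) {
      if (!inter(base + (size_t)j * W, reach.data(), W)) {
        tot += w[j];
        cum.push_back(tot);
        feas.push_back(j);
      }
    }
    double u = unif_rand() * tot;
    int pick = feas[0];
    for (size_t j = 0; j < cum.size(); ++j)
      if (u <= cum[j]) { pick = feas[j]; break; }
    set_choice(c, pick);
  }

  // joint conditional over (fragment_i, fragment_j); rest graph drops both
  // children's parent sets.  Adding S_i -> i and S_j -> j creates a cycle
  // iff a parent of i is reachable from i or a parent of j from j, where
  // reachability may hop through the other child's new edges.
  void update_pair(int i, int j) {
    reach_from(i, reach, i, j);
    reach_from(j, reach2, i, j);
    const int ni = nf[i], njf = nf[j];
    cum.clear(); feas.clear(); feas2.clear();
    double tot = 0.0;
    for (int a = 0; a < ni; ++a) {
      const uint64_t* Si = fmask(i, a);
      const bool si_ri = inter(Si, reach.data(), W);
      const bool si_rj = inter(Si, reach2.data(), W);
      for (int b = 0; b < njf; ++b) {
        const uint64_t* Sj = fmask(j, b);
        bool cyc = si_ri ||
                   (inter(Sj, reach.data(), W) && si_rj);
        if (!cyc)
          cyc = inter(Sj, reach2.data(), W) ||
                (si_rj && inter(Sj, reach.data(), W));
        if (cyc) continue;
        tot += wgt[i][a] * wgt[j][b];
        cum.push_back(tot);
        feas.push_back(a);
        feas2.push_back(b);
      }
    }
    double u = unif_rand() * tot;
    int pick = 0;
    for (size_t k = 0; k < cum.size(); ++k)
      if (u <= cum[k]) { pick = (int)k; break; }
    set_choice(i, feas[pick]);
    set_choice(j, feas2[pick]);
  }
};

}  // namespace

// [[Rcpp::export]]
IntegerMatrix gibbs_sample_networks(List frag_parents, List frag_weights,
                                    int n_nodes, int n_networks,
                                    int burn_in, int max_pair_combos) {
  Sampler s;
  const int n = n_nodes;
  s.n = n;
  s.W = (n + 63) / 64;
  s.stack.resize(n);
  s.choice.resize(n);
  s.cur.assign((size_t)n * s.W, 0);
  s.reach.resize(s.W);
  s.reach2.resize(s.W);
  s.nf.resize(n);
  s.off.resize(n);
  size_t total = 0;
  for (int c = 0; c < n; ++c) {
    List pf = frag_parents[c];
    s.nf[c] = pf.size();
    s.off[c] = total;
    total += (size_t)s.nf[c] * s.W;
  }
  s.mask.assign(total, 0);
  for (int c = 0; c < n; ++c) {
    List pf = frag_parents[c];
    NumericVector wv = frag_weights[c];
    if (s.nf[c] != wv.size()) stop("parents/weights length mismatch");
    s.wgt.push_back(std::vector<double>(wv.begin(), wv.end()));
    for (int j = 0; j < s.nf[c]; ++j) {
      IntegerVector pv = pf[j];
      for (int k = 0; k < pv.size(); ++k) {
        if (pv[k] < 0 || pv[k] >= n) stop("parent index out of range");
        s.mask[s.off[c] + (size_t)j * s.W + (pv[k] >> 6)] |=
          (uint64_t(1) << (pv[k] & 63));
      }
    }
    IntegerVector first = pf[0];
    if (s.nf[c] < 1 || first.size() != 0)
      stop("fragment 0 of every child must be the empty fragment");
  }

  IntegerMatrix out(n_networks, n);
  std::vector<int> order(n);
  for (int c = 0; c < n; ++c) order[c] = c;

  RNGScope scope;
  for (int m = 0; m < n_networks; ++m) {
    for (int c = 0; c < n; ++c) s.set_choice(c, 0);  // empty start
    for (int sweep = 0; sweep < burn_in; ++sweep) {
      // random scan order (Fisher-Yates via R's RNG)
      for (int k = n - 1; k > 0; --k) {
        int l = (int)(unif_rand() * (k + 1));
        if (l > k) l = k;
        std::swap(order[k], order[l]);
      }
      for (int k = 0; k < n; ++k) s.update_child(order[k]);
      if (n >= 2) {
        int i = (int)(unif_rand() * n);
        int j = (int)(unif_rand() * (n - 1));
        if (j >= i) ++j;
        if (i < n && j < n &&
            (double)s.nf[i] * s.nf[j] <= max_pair_combos)
          s.update_pair(i, j);
      }
    }
    for (int c = 0; c < n; ++c) out(m, c) = s.choice[c] + 1;  // 1-based
    if (m % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
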