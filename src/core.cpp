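// Core kernels: exact-distance pair statistics (with O(local) incremental
// updates under a double-edge swap), Metropolis-Hastings rewiring chains for
// distance-1 and distance-2 degree correlations, Newman-Ziff union-find
// percolation, and configuration-model simplicity repair.
//
// All randomness is drawn from R's RNG (RNGScope), so set.seed() on the R
// side controls every kernel. Node ids are 0-based here; R wrappers convert.

#include <Rcpp.h>
#include <unordered_set>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

typedef long long ll;

inline ll ekey(int a, int b) {
  if (a > b) std::swap(a, b);
  return (ll)a * 0x40000000LL + b;
}

struct Graph {
  int n;
  std::vector<int> eu, ev;                 // edge endpoints
  std::vector<std::unordered_set<int> > adj;
  std::vector<int> deg;

  int m() const { return (int)eu.size(); }

  void build(int n_, const IntegerMatrix& edges) {
    n = n_;
    int mm = edges.nrow();
    eu.resize(mm); ev.resize(mm);
    adj.assign(n, std::unordered_set<int>());
    deg.assign(n, 0);
    for (int e = 0; e < mm; ++e) {
      int a = edges(e, 0), b = edges(e, 1);
      if (a < 0 || b < 0 || a >= n || b >= n)
        stop("edge endpoint out of range");
      if (a == b) stop("self-loop in input edge list");
      if (adj[a].count(b)) stop("duplicate edge in input edge list");
      eu[e] = a; ev[e] = b;
      adj[a].insert(b); adj[b].insert(a);
      deg[a]++; deg[b]++;
    }
  }

  bool has_edge(int a, int b) const { return adj[a].count(b) > 0; }
};

// Sufficient statistics over ORDERED node pairs at exact distance l:
// npairs = 2 M(l), S1 = sum k_i, S2 = sum k_i^2, S11 = sum k_i k_j.
struct PairStats {
  double npairs, S1, S2, S11;
  PairStats() : npairs(0), S1(0), S2(0), S11(0) {}
  void add_unordered(double ka, double kb) {
    npairs += 2; S1 += ka + kb; S2 += ka * ka + kb * kb; S11 += 2 * ka * kb;
  }
  double variance() const {
    if (npairs == 0) return 0;
    double mu = S1 / npairs;
    return S2 / npairs - mu * mu;
  }
  double r() const {  // NaN when undefined
    if (npairs == 0) return R_NaN;
    double mu = S1 / npairs;
    double var = S2 / npairs - mu * mu;
    if (var <= 0) return R_NaN;
    return (S11 / npairs - mu * mu) / var;
  }
};

// Nodes at exact shortest-path distance l from v (truncated BFS).
void frontier_at(const Graph& g, int v, int l, std::vector<int>& out,
                 std::vector<int>& mark, int stamp) {
  out.clear();
  if (l == 0) { out.push_back(v); return; }
  std::vector<int> cur, nxt;
  cur.push_back(v);
  mark[v] = stamp;
  for (int d = 0; d < l; ++d) {
    nxt.clear();
    for (size_t i = 0; i < cur.size(); ++i) {
      int x = cur[i];
      for (std::unordered_set<int>::const_iterator it = g.adj[x].begin();
           it != g.adj[x].end(); ++it) {
        if (mark[*it] != stamp) { mark[*it] = stamp; nxt.push_back(*it); }
      }
    }
    cur.swap(nxt);
    if (cur.empty()) break;
  }
  out = cur;
}

// Full recomputation of PairStats at distance l (each unordered pair found
// twice, once from each endpoint; add_unordered from the smaller id only).
PairStats full_stats(const Graph& g, int l) {
  PairStats st;
  std::vector<int> mark(g.n, -1), fr;
  if (l == 1) {
    for (int e = 0; e < g.m(); ++e)
      st.add_unordered(g.deg[g.eu[e]], g.deg[g.ev[e]]);
    return st;
  }
  for (int v = 0; v < g.n; ++v) {
    frontier_at(g, v, l, fr, mark, v);
    for (size_t i = 0; i < fr.size(); ++i)
      if (fr[i] > v) st.add_unordered(g.deg[v], g.deg[fr[i]]);
  }
  return st;
}

// Distance-2 partners of x: non-neighbours sharing >=1 common neighbour.
void d2_set(const Graph& g, int x, std::vector<int>& out,
            std::vector<int>& mark, int stamp) {
  out.clear();
  for (std::unordered_set<int>::const_iterator it = g.adj[x].begin();
       it != g.adj[x].end(); ++it) {
    int y = *it;
    for (std::unordered_set<int>::const_iterator jt = g.adj[y].begin();
         jt != g.adj[y].end(); ++jt) {
      int w = *jt;
      if (w == x || g.adj[x].count(w)) continue;
      if (mark[w] != stamp) { mark[w] = stamp; out.push_back(w); }
    }
  }
}

// Contribution to the distance-2 PairStats of all unordered pairs with at
// least one endpoint among the (sorted, unique) nodes in A. Pairs with both
// endpoints in A are counted once.
PairStats local_d2_contrib(const Graph& g, const std::vector<int>& A,
                           std::vector<int>& mark, int& stamp) {
  PairStats st;
  std::vector<int> d2;
  for (size_t i = 0; i < A.size(); ++i) {
    int x = A[i];
    ++stamp;
    d2_set(g, x, d2, mark, stamp);
    for (size_t j = 0; j < d2.size(); ++j) {
      int w = d2[j];
      bool winA = std::binary_search(A.begin(), A.end(), w);
      if (winA && w < x) continue;  // counted from the smaller endpoint
      st.add_unordered(g.deg[x], g.deg[w]);
    }
  }
  return st;
}

struct SwapMove {
  int e1, e2, u1, u2, v1, v2;
  int oe1u, oe1v, oe2u, oe2v;  // stored endpoints before apply (for revert)
};

// Apply the swap (u1,u2),(v1,v2) -> (u1,v2),(v1,u2), normalizing the stored
// orientation of the two edges to the drawn one; the previously stored
// orientation is recorded on s for exact revert.
void apply_swap(Graph& g, SwapMove& s) {
  s.oe1u = g.eu[s.e1]; s.oe1v = g.ev[s.e1];
  s.oe2u = g.eu[s.e2]; s.oe2v = g.ev[s.e2];
  g.adj[s.u1].erase(s.u2); g.adj[s.u2].erase(s.u1);
  g.adj[s.v1].erase(s.v2); g.adj[s.v2].erase(s.v1);
  g.adj[s.u1].insert(s.v2); g.adj[s.v2].insert(s.u1);
  g.adj[s.v1].insert(s.u2); g.adj[s.u2].insert(s.v1);
  g.eu[s.e1] = s.u1; g.ev[s.e1] = s.v2;
  g.eu[s.e2] = s.v1; g.ev[s.e2] = s.u2;
}

void revert_swap(Graph& g, const SwapMove& s) {
  g.adj[s.u1].erase(s.v2); g.adj[s.v2].erase(s.u1);
  g.adj[s.v1].erase(s.u2); g.adj[s.u2].erase(s.v1);
  g.adj[s.u1].insert(s.u2); g.adj[s.u2].insert(s.u1);
  g.adj[s.v1].insert(s.v2); g.adj[s.v2].insert(s.v1);
  g.eu[s.e1] = s.oe1u; g.ev[s.e1] = s.oe1v;
  g.eu[s.e2] = s.oe2u; g.ev[s.e2] = s.oe2v;
}

// Structural admissibility of a proposed swap; 0 = ok, 1 = self-loop,
// 2 = multi-edge, 3 = degenerate/no-op (same edge twice or identical edge
// set after the swap).
int swap_violation(const Graph& g, const SwapMove& s) {
  if (s.e1 == s.e2) return 3;
  if (s.u1 == s.v1 || s.u2 == s.v2) return 3;   // replacement equals removal
  if (s.u1 == s.v2 || s.v1 == s.u2) return 1;   // would create a loop
  if (g.has_edge(s.u1, s.v2) || g.has_edge(s.v1, s.u2)) return 2;
  return 0;
}

std::vector<int> endpoints_unique(const SwapMove& s) {
  std::vector<int> A;
  A.push_back(s.u1); A.push_back(s.u2); A.push_back(s.v1); A.push_back(s.v2);
  std::sort(A.begin(), A.end());
  A.erase(std::unique(A.begin(), A.end()), A.end());
  return A;
}

// Ordered-endpoint buckets indexed by source degree, for the degree-matched
// edge draw of the distance-2 chain. Slot id = 2*edge + orientation.
struct DegreeBuckets {
  std::vector<std::vector<int> > bydeg;  // degree -> slots
  std::vector<int> pos;                  // slot -> index within its bucket

  int slot_source(const Graph& g, int slot) const {
    return (slot & 1) ? g.ev[slot >> 1] : g.eu[slot >> 1];
  }
  void build(const Graph& g) {
    int maxd = 0;
    for (int i = 0; i < g.n; ++i) maxd = std::max(maxd, g.deg[i]);
    bydeg.assign(maxd + 1, std::vector<int>());
    pos.assign(2 * g.m(), 0);
    for (int s = 0; s < 2 * g.m(); ++s) {
      int d = g.deg[slot_source(g, s)];
      pos[s] = (int)bydeg[d].size();
      bydeg[d].push_back(s);
    }
  }
  void move_slot(int slot, int dfrom, int dto) {
    if (dfrom == dto) return;
    std::vector<int>& B = bydeg[dfrom];
    int i = pos[slot], last = B.back();
    B[i] = last; pos[last] = i; B.pop_back();
    pos[slot] = (int)bydeg[dto].size();
    bydeg[dto].push_back(slot);
  }
  // After apply_swap the stored endpoints of e1,e2 are (u1,v2),(v1,u2);
  // move each of the four slots from the bucket of its previous stored
  // source's degree to that of the new one (degrees themselves are static).
  void update_for_swap(const Graph& g, const SwapMove& s) {
    move_slot(2 * s.e1,     g.deg[s.oe1u], g.deg[s.u1]);
    move_slot(2 * s.e1 + 1, g.deg[s.oe1v], g.deg[s.v2]);
    move_slot(2 * s.e2,     g.deg[s.oe2u], g.deg[s.v1]);
    move_slot(2 * s.e2 + 1, g.deg[s.oe2v], g.deg[s.u2]);
  }
};

inline int runif_int(int k) {  // uniform on 0..k-1
  int r;
  do { r = (int)(unif_rand() * k); } while (r >= k);
  return r;
}

IntegerMatrix edges_of(const Graph& g) {
  IntegerMatrix out(g.m(), 2);
  for (int e = 0; e < g.m(); ++e) { out(e, 0) = g.eu[e]; out(e, 1) = g.ev[e]; }
  return out;
}

}  // namespace

// [[Rcpp::export]]
List cpp_pair_stats(int n, IntegerMatrix edges, int l) {
  Graph g; g.build(n, edges);
  PairStats st = full_stats(g, l);
  return List::create(_["n_pairs"] = st.npairs, _["S1"] = st.S1,
                      _["S2"] = st.S2, _["S11"] = st.S11,
                      _["variance"] = st.variance(), _["r"] = st.r());
}

// [[Rcpp::export]]
IntegerMatrix cpp_distance_pairs(int n, IntegerMatrix edges, int l) {
  Graph g; g.build(n, edges);
  std::vector<int> mark(g.n, -1), fr, out;
  for (int v = 0; v < g.n; ++v) {
    frontier_at(g, v, l, fr, mark, v);
    for (size_t i = 0; i < fr.size(); ++i)
      if (fr[i] > v) { out.push_back(v); out.push_back(fr[i]); }
  }
  IntegerMatrix res((int)out.size() / 2, 2);
  for (int i = 0; i < res.nrow(); ++i) {
    res(i, 0) = out[2 * i]; res(i, 1) = out[2 * i + 1];
  }
  return res;
}

// [[Rcpp::export]]
IntegerVector cpp_neighbors_at_distance(int n, IntegerMatrix edges, int v,
                                        int l) {
  Graph g; g.build(n, edges);
  std::vector<int> mark(g.n, -1), fr;
  frontier_at(g, v, l, fr, mark, 0);
  std::sort(fr.begin(), fr.end());
  return wrap(fr);
}

// Preview r at distance l after the swap (u1,u2),(v1,v2) -> (u1,v2),(v1,u2),
// computed by the same incremental path the rewiring chain uses. Errors on
// inadmissible swaps.
// [[Rcpp::export]]
List cpp_delta_r_swap(int n, IntegerMatrix edges, int l,
                      IntegerVector e1, IntegerVector e2) {
  Graph g; g.build(n, edges);
  SwapMove s;
  s.u1 = e1[0]; s.u2 = e1[1]; s.v1 = e2[0]; s.v2 = e2[1];
  if (!g.has_edge(s.u1, s.u2) || !g.has_edge(s.v1, s.v2))
    stop("edge not present in graph");
  // locate edge indices for orientation bookkeeping
  s.e1 = -1; s.e2 = -1;
  for (int e = 0; e < g.m(); ++e) {
    if (ekey(g.eu[e], g.ev[e]) == ekey(s.u1, s.u2)) s.e1 = e;
    if (ekey(g.eu[e], g.ev[e]) == ekey(s.v1, s.v2)) s.e2 = e;
  }
  int viol = swap_violation(g, s);
  if (viol == 1) stop("inadmissible swap: self-loop");
  if (viol == 2) stop("inadmissible swap: multi-edge");
  if (viol == 3) stop("inadmissible swap: degenerate proposal");
  PairStats st = full_stats(g, l);
  PairStats nxt = st;
  if (l == 1) {
    double ku1 = g.deg[s.u1], ku2 = g.deg[s.u2];
    double kv1 = g.deg[s.v1], kv2 = g.deg[s.v2];
    nxt.S11 += 2 * (ku1 * kv2 + kv1 * ku2 - ku1 * ku2 - kv1 * kv2);
  } else if (l == 2) {
    std::vector<int> mark(g.n, -1);
    int stamp = 0;
    std::vector<int> A = endpoints_unique(s);
    PairStats before = local_d2_contrib(g, A, mark, stamp);
    apply_swap(g, s);
    PairStats after = local_d2_contrib(g, A, mark, stamp);
    revert_swap(g, s);
    nxt.npairs += after.npairs - before.npairs;
    nxt.S1 += after.S1 - before.S1;
    nxt.S2 += after.S2 - before.S2;
    nxt.S11 += after.S11 - before.S11;
  } else {
    stop("incremental update implemented for l = 1 and l = 2 only");
  }
  return List::create(_["r_prev"] = st.r(), _["r_next"] = nxt.r(),
                      _["n_pairs"] = nxt.npairs, _["S1"] = nxt.S1,
                      _["S2"] = nxt.S2, _["S11"] = nxt.S11);
}

// Metropolis-Hastings rewiring chain.
//   distance 1: two uniform ordered edges; preserves the degree sequence.
//   distance 2: ordered edge (u1,u2) then an ordered edge (v1,v2) with
//               deg(v1) = deg(u1); additionally preserves P(k,k'|l=1).
// Acceptance min(1, exp(sign * J * (r_next - r_prev))) with sign = +1 by
// default (positive J biases r positive) or -1 under flip_sign.
// [[Rcpp::export]]
List cpp_rewire(int n, IntegerMatrix edges, int distance, double J,
                double budget, double lazy_prob, double full_every,
                double trace_every, bool flip_sign, bool audit) {
  if (distance != 1 && distance != 2) stop("distance must be 1 or 2");
  Graph g; g.build(n, edges);
  if (g.m() < 2) stop("need at least two edges to rewire");
  RNGScope scope;
  double sign = flip_sign ? -1.0 : 1.0;

  PairStats st = full_stats(g, distance);
  DegreeBuckets buckets;
  if (distance == 2) buckets.build(g);

  std::vector<int> mark(g.n, -1);
  int stamp = 0;

  double n_applied = 0, n_lazy = 0, n_struct = 0, n_metro = 0;
  double accepted_since_recompute = 0;
  double audit_max = 0;

  std::vector<double> tr_t, tr_r1, tr_r2, tr_state;
  int two_m = 2 * g.m();
  double since_trace = 0;
  // order-independent fingerprint of the current edge set (diagnostics;
  // collisions are irrelevant for the tiny state spaces it is used on)
  auto state_hash = [&g]() {
    double h = 0;
    for (int e = 0; e < g.m(); ++e) {
      double k = (double)ekey(g.eu[e], g.ev[e]);
      h += k * k;
    }
    return h;
  };

  for (double t = 1; t <= budget; t += 1) {
    bool lazy = (unif_rand() < lazy_prob);
    if (!lazy) {
      int slot1 = runif_int(two_m);
      SwapMove s;
      s.e1 = slot1 >> 1;
      if (slot1 & 1) { s.u1 = g.ev[s.e1]; s.u2 = g.eu[s.e1]; }
      else           { s.u1 = g.eu[s.e1]; s.u2 = g.ev[s.e1]; }
      int slot2;
      if (distance == 1) {
        slot2 = runif_int(two_m);
      } else {
        const std::vector<int>& B = buckets.bydeg[g.deg[s.u1]];
        slot2 = B[runif_int((int)B.size())];
      }
      s.e2 = slot2 >> 1;
      if (slot2 & 1) { s.v1 = g.ev[s.e2]; s.v2 = g.eu[s.e2]; }
      else           { s.v1 = g.eu[s.e2]; s.v2 = g.ev[s.e2]; }

      int viol = swap_violation(g, s);
      if (viol != 0) {
        n_struct += 1;
      } else {
        double r_prev = st.r();
        PairStats nxt = st;
        bool applied_preview = false;
        if (distance == 1) {
          double ku1 = g.deg[s.u1], ku2 = g.deg[s.u2];
          double kv1 = g.deg[s.v1], kv2 = g.deg[s.v2];
          nxt.S11 += 2 * (ku1 * kv2 + kv1 * ku2 - ku1 * ku2 - kv1 * kv2);
        } else {
          std::vector<int> A = endpoints_unique(s);
          PairStats before = local_d2_contrib(g, A, mark, stamp);
          apply_swap(g, s);
          applied_preview = true;
          PairStats after = local_d2_contrib(g, A, mark, stamp);
          nxt.npairs += after.npairs - before.npairs;
          nxt.S1 += after.S1 - before.S1;
          nxt.S2 += after.S2 - before.S2;
          nxt.S11 += after.S11 - before.S11;
        }
        double r_next = nxt.r();
        // transient zero-variance states (possible only on near-degenerate
        // toy graphs) are treated as r = 0 inside the chain
        if (!R_finite(r_prev)) r_prev = 0;
        if (!R_finite(r_next)) r_next = 0;
        double logp = sign * J * (r_next - r_prev);
        bool accept = (logp >= 0) || (unif_rand() < std::exp(logp));
        if (accept) {
          if (!applied_preview) apply_swap(g, s);
          if (distance == 2) buckets.update_for_swap(g, s);
          st = nxt;
          n_applied += 1;
          accepted_since_recompute += 1;
          if (audit) {
            PairStats chk = full_stats(g, distance);
            audit_max = std::max(audit_max,
              std::max(std::fabs(chk.S11 - st.S11) /
                         std::max(1.0, std::fabs(chk.S11)),
                       std::fabs(chk.npairs - st.npairs)));
            double ra = chk.r(), rb = st.r();
            if (R_finite(ra) && R_finite(rb))
              audit_max = std::max(audit_max, std::fabs(ra - rb));
          }
          if (full_every > 0 && accepted_since_recompute >= full_every) {
            PairStats chk = full_stats(g, distance);
            if (std::fabs(chk.npairs - st.npairs) > 0.5)
              stop("corrupted state: incremental pair count diverged");
            st = chk;
            accepted_since_recompute = 0;
          }
        } else {
          if (applied_preview) revert_swap(g, s);
          n_metro += 1;
        }
      }
    } else {
      n_lazy += 1;
    }
    if (trace_every > 0 && ++since_trace >= trace_every) {
      since_trace = 0;
      PairStats s1 = full_stats(g, 1), s2 = full_stats(g, 2);
      tr_t.push_back(t); tr_r1.push_back(s1.r()); tr_r2.push_back(s2.r());
      tr_state.push_back(state_hash());
    }
  }

  PairStats f1 = full_stats(g, 1), f2 = full_stats(g, 2);
  return List::create(
    _["edges"] = edges_of(g),
    _["r1"] = f1.r(), _["r2"] = f2.r(),
    _["counts"] = NumericVector::create(
      _["applied"] = n_applied, _["rejected_lazy"] = n_lazy,
      _["rejected_structural"] = n_struct, _["rejected_metropolis"] = n_metro),
    _["trace"] = DataFrame::create(_["proposal_index"] = tr_t,
                                   _["r1"] = tr_r1, _["r2"] = tr_r2,
                                   _["state"] = tr_state),
    _["audit_max_discrepancy"] = audit_max);
}

// Empirical draw counts for ordered-edge sampling (slot = 2*edge + orient).
// [[Rcpp::export]]
NumericVector cpp_sample_ordered_edges(int n_edges, double draws) {
  RNGScope scope;
  NumericVector counts(2 * n_edges);
  for (double i = 0; i < draws; i += 1) counts[runif_int(2 * n_edges)] += 1;
  return counts;
}

namespace {

struct UnionFind {
  std::vector<int> parent, size;
  int largest;
  void init(int n) {
    parent.resize(n); size.assign(n, 1);
    for (int i = 0; i < n; ++i) parent[i] = i;
    largest = 1;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a; size[a] += size[b];
    if (size[a] > largest) largest = size[a];
  }
};

// One Newman-Ziff pass; plan is the ADDITION order (reverse of removal).
// mode 0: edge occupation (all nodes always present); N_LCC at n=0 is 1.
// mode 1: node occupation; N_LCC at n=0 is 0.
void nz_run(const Graph& g, const std::vector<int>& plan, int mode,
            std::vector<int>& out) {
  UnionFind uf; uf.init(g.n);
  out.clear();
  if (mode == 0) {
    if ((int)plan.size() != g.m()) stop("edge plan length must equal M");
    out.push_back(g.n >= 1 ? 1 : 0);
    for (size_t i = 0; i < plan.size(); ++i) {
      int e = plan[i];
      uf.unite(g.eu[e], g.ev[e]);
      out.push_back(uf.largest);
    }
  } else {
    if ((int)plan.size() != g.n) stop("node plan length must equal N");
    std::vector<char> present(g.n, 0);
    int lcc = 0;
    out.push_back(0);
    for (size_t i = 0; i < plan.size(); ++i) {
      int v = plan[i];
      if (present[v]) stop("node repeated in plan");
      present[v] = 1;
      for (std::unordered_set<int>::const_iterator it = g.adj[v].begin();
           it != g.adj[v].end(); ++it) {
        if (present[*it]) uf.unite(v, *it);
      }
      int best = uf.size[uf.find(v)];
      if (best > lcc) lcc = best;
      out.push_back(lcc);
    }
  }
}

}  // namespace

// [[Rcpp::export]]
IntegerVector cpp_newman_ziff(int n, IntegerMatrix edges, IntegerVector plan,
                              int mode) {
  Graph g; g.build(n, edges);
  std::vector<int> p(plan.begin(), plan.end()), out;
  nz_run(g, p, mode, out);
  return wrap(out);
}

// Ensemble accumulation of first and second moments of N_LCC on the
// occupation-number grid. mode: 0 random edge, 1 random node, 2 targeted
// (static initial-degree order, removal by decreasing degree = addition by
// nondecreasing degree, ties broken uniformly per run).
// [[Rcpp::export]]
List cpp_percolation_ensemble(int n, IntegerMatrix edges, int mode,
                              int n_runs) {
  Graph g; g.build(n, edges);
  RNGScope scope;
  int grid = (mode == 0 ? g.m() : g.n) + 1;
  std::vector<double> s1(grid, 0), s2(grid, 0);
  std::vector<int> plan, out;
  int nel = (mode == 0) ? g.m() : g.n;
  plan.resize(nel);
  std::vector<double> key(nel);

  for (int run = 0; run < n_runs; ++run) {
    for (int i = 0; i < nel; ++i) plan[i] = i;
    if (mode == 2) {
      // addition order: nondecreasing initial degree, uniform tie-break
      for (int i = 0; i < nel; ++i) key[i] = g.deg[i] + unif_rand() * 0.5;
      std::vector<int>& pl = plan;
      std::sort(pl.begin(), pl.end(),
                [&key](int a, int b) { return key[a] < key[b]; });
    } else {
      for (int i = nel - 1; i > 0; --i)
        std::swap(plan[i], plan[runif_int(i + 1)]);
    }
    nz_run(g, plan, mode == 0 ? 0 : 1, out);
    for (int i = 0; i < grid; ++i) {
      s1[i] += out[i];
      s2[i] += (double)out[i] * out[i];
    }
  }
  return List::create(_["sum_lcc"] = wrap(s1), _["sum_lcc2"] = wrap(s2),
                      _["n_runs"] = n_runs, _["grid"] = grid);
}

// Repair self-loops and duplicate edges left by uniform stub matching, by
// degree-preserving double-edge swaps against uniformly chosen partner
// edges. The degree sequence is preserved exactly.
// [[Rcpp::export]]
IntegerMatrix cpp_simplify_by_swaps(int n, IntegerMatrix edges,
                                    double max_attempts) {
  RNGScope scope;
  int m = edges.nrow();
  std::vector<int> eu(m), ev(m);
  std::unordered_map<ll, int> mult;
  std::vector<int> bad;  // indices of offending edges (refreshed lazily)
  for (int e = 0; e < m; ++e) {
    eu[e] = edges(e, 0); ev[e] = edges(e, 1);
    mult[ekey(eu[e], ev[e])] += 1;
  }
  auto is_bad = [&](int e) {
    return eu[e] == ev[e] || mult[ekey(eu[e], ev[e])] > 1;
  };
  for (int e = 0; e < m; ++e) if (is_bad(e)) bad.push_back(e);

  double attempts = 0;
  while (!bad.empty()) {
    if (attempts++ > max_attempts)
      stop("simplicity repair did not converge");
    int bi = runif_int((int)bad.size());
    int e = bad[bi];
    if (!is_bad(e)) {  // fixed as a side effect of an earlier swap
      bad[bi] = bad.back(); bad.pop_back();
      continue;
    }
    int f = runif_int(m);
    if (f == e) continue;
    // random orientations
    int a = eu[e], b = ev[e], c = eu[f], d = ev[f];
    if (unif_rand() < 0.5) std::swap(a, b);
    if (unif_rand() < 0.5) std::swap(c, d);
    // propose (a,b),(c,d) -> (a,d),(c,b)
    if (a == d || c == b) continue;
    ll k1 = ekey(a, d), k2 = ekey(c, b);
    int add1 = (mult.count(k1) ? mult[k1] : 0) + (k1 == k2 ? 1 : 0);
    int add2 = (mult.count(k2) ? mult[k2] : 0);
    if (add1 > 0 || add2 > 0) continue;  // would create new duplicates
    mult[ekey(a, b)] -= 1; mult[ekey(c, d)] -= 1;
    mult[k1] += 1; mult[k2] += 1;
    eu[e] = a; ev[e] = d;
    eu[f] = c; ev[f] = b;
    if (is_bad(f)) bad.push_back(f);
    if (!is_bad(e)) { bad[bi] = bad.back(); bad.pop_back(); }
  }
  IntegerMatrix out(m, 2);
  for (int e2 = 0; e2 < m; ++e2) { out(e2, 0) = eu[e2]; out(e2, 1) = ev[e2]; }
  return out;
}
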