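// Jukes-Cantor per-window phylogenetic engine.
//
// States: 0=A, 1=C, 2=G, 3=T, 4=missing (gap or N).  Trees are unrooted
// binary trees over leaves 0..ntax-1 with internal nodes ntax..2*ntax-3
// (ntax>=3; ntax==2 is a single edge).  All likelihoods use uniform base
// frequencies and the closed-form JC transition probabilities
//   P_same(t) = 1/4 + 3/4 exp(-4t/3),  P_diff(t) = 1/4 - 1/4 exp(-4t/3).
// Columns in which no taxon has an observed base are skipped (contribute 0).

#include <Rcpp.h>
#include <Rmath.h>
#include <cstdint>
#include <algorithm>
#include <array>
#include <map>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static const int ST_MISS = 4;
static const int MAX_TAXA = 20;  // 3-bit packing of a column into 64 bits

// ---------------------------------------------------------------- patterns

struct PatData {
  int ntax = 0;
  int npat = 0;
  std::vector<int> pat;     // npat * ntax, pattern-major
  std::vector<double> w;    // pattern weights (site counts)
  double nsites = 0;        // sites with >=1 observed base
};

// Compress columns [start, end) of enc (ntax x L, 0-based half-open) into
// site patterns, dropping all-missing columns.  rows: which taxa to keep.
static PatData compress_patterns(const IntegerMatrix& enc,
                                 const std::vector<int>& rows,
                                 int start, int end) {
  PatData pd;
  pd.ntax = (int)rows.size();
  std::unordered_map<uint64_t, int> seen;
  seen.reserve(1024);
  for (int s = start; s < end; ++s) {
    uint64_t key = 0;
    bool any = false;
    for (int i = 0; i < pd.ntax; ++i) {
      int st = enc(rows[i], s);
      if (st != ST_MISS) any = true;
      key = (key << 3) | (uint64_t)st;
    }
    if (!any) continue;
    auto it = seen.find(key);
    if (it == seen.end()) {
      seen.emplace(key, pd.npat);
      for (int i = 0; i < pd.ntax; ++i)
        pd.pat.push_back(enc(rows[i], s));
      pd.w.push_back(1.0);
      ++pd.npat;
    } else {
      pd.w[it->second] += 1.0;
    }
    pd.nsites += 1.0;
  }
  return pd;
}

// ---------------------------------------------------------------- tree

struct Tree {
  int ntax = 0;
  std::vector<int> eu, ev;       // edge endpoints
  std::vector<double> elen;      // branch lengths (subs/site)
  // adjacency: node -> list of (neighbour, edge index)
  std::vector<std::vector<std::pair<int, int>>> adj;

  int nedge() const { return (int)eu.size(); }
  int nnode() const { return ntax <= 2 ? ntax : 2 * ntax - 2; }

  void build_adj() {
    adj.assign(nnode(), {});
    for (int e = 0; e < nedge(); ++e) {
      adj[eu[e]].push_back({ev[e], e});
      adj[ev[e]].push_back({eu[e], e});
    }
  }
};

static inline void jc_probs(double t, double& ps, double& pd) {
  double e = std::exp(-4.0 * t / 3.0);
  ps = 0.25 + 0.75 * e;
  pd = 0.25 - 0.25 * e;
}

// Conditional likelihoods flowing INTO `node` from the subtree on the far
// side of `from_edge` (i.e. the product over node's other neighbours of the
// JC-propagated messages).  Leaf base case: indicator (or ones if missing).
// Output: out[p*4 + x].
static void flux_at(const Tree& tr, const PatData& pd, int node, int from_edge,
                    std::vector<double>& out) {
  const int npat = pd.npat;
  out.assign((size_t)npat * 4, 1.0);
  if (node < tr.ntax) {  // leaf
    for (int p = 0; p < npat; ++p) {
      int st = pd.pat[(size_t)p * pd.ntax + node];
      double* o = &out[(size_t)p * 4];
      if (st != ST_MISS) {
        o[0] = o[1] = o[2] = o[3] = 0.0;
        o[st] = 1.0;
      }
    }
    return;
  }
  std::vector<double> child;
  for (auto& nb : tr.adj[node]) {
    if (nb.second == from_edge) continue;
    flux_at(tr, pd, nb.first, nb.second, child);
    double ps, pdf;
    jc_probs(tr.elen[nb.second], ps, pdf);
    for (int p = 0; p < npat; ++p) {
      const double* c = &child[(size_t)p * 4];
      double sum = c[0] + c[1] + c[2] + c[3];
      double* o = &out[(size_t)p * 4];
      for (int x = 0; x < 4; ++x)
        o[x] *= pdf * sum + (ps - pdf) * c[x];
    }
  }
}

// Per-pattern cached terms for 1-D optimization of one edge:
// L_p(t) = 1/4 * ( pd(t) * C1_p + (ps(t) - pd(t)) * C2_p )
// with C1 = (sum_x A)(sum_y B), C2 = dot(A, B).
struct EdgeCache {
  std::vector<double> c1, c2, w;
  double eval(double t) const {
    double ps, pdv;
    jc_probs(t, ps, pdv);
    double lnl = 0.0;
    for (size_t p = 0; p < c1.size(); ++p) {
      double L = 0.25 * (pdv * c1[p] + (ps - pdv) * c2[p]);
      lnl += w[p] * std::log(std::max(L, 1e-300));
    }
    return lnl;
  }
};

static EdgeCache edge_cache(const Tree& tr, const PatData& pd, int e) {
  std::vector<double> A, B;
  flux_at(tr, pd, tr.eu[e], e, A);
  flux_at(tr, pd, tr.ev[e], e, B);
  EdgeCache ec;
  ec.c1.resize(pd.npat);
  ec.c2.resize(pd.npat);
  ec.w = pd.w;
  for (int p = 0; p < pd.npat; ++p) {
    const double* a = &A[(size_t)p * 4];
    const double* b = &B[(size_t)p * 4];
    double sa = a[0] + a[1] + a[2] + a[3];
    double sb = b[0] + b[1] + b[2] + b[3];
    ec.c1[p] = sa * sb;
    ec.c2[p] = a[0] * b[0] + a[1] * b[1] + a[2] * b[2] + a[3] * b[3];
  }
  return ec;
}

static double tree_lnl(const Tree& tr, const PatData& pd) {
  if (tr.nedge() == 0) return 0.0;
  EdgeCache ec = edge_cache(tr, pd, 0);
  return ec.eval(tr.elen[0]);
}

// Brent minimization of -f on [lo, hi]; returns argmax of f.
static double brent_max(const EdgeCache& ec, double lo, double hi,
                        double xtol, double& fbest) {
  const double gold = 0.3819660112501051;
  double a = lo, b = hi;
  double x = a + gold * (b - a), wx = x, v = x;
  double fx = -ec.eval(x), fw = fx, fv = fx;
  double d = 0.0, ee = 0.0;
  for (int iter = 0; iter < 100; ++iter) {
    double xm = 0.5 * (a + b);
    double tol1 = xtol * std::fabs(x) + 1e-12, tol2 = 2 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool golden = true;
    if (std::fabs(ee) > tol1) {
      double r = (x - wx) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - wx) * r;
      q = 2 * (q - r);
      if (q > 0) p = -p;
      q = std::fabs(q);
      double etemp = ee;
      ee = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etemp) && p > q * (a - x) &&
          p < q * (b - x)) {
        golden = false;
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x) ? tol1 : -tol1;
      }
    }
    if (golden) {
      ee = (x >= xm) ? a - x : b - x;
      d = gold * ee;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d >= 0) ? tol1 : -tol1);
    double fu = -ec.eval(u);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = wx; fv = fw; wx = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || wx == x) { v = wx; fv = fw; wx = u; fw = fu; }
      else if (fu <= fv || v == x || v == wx) { v = u; fv = fu; }
    }
  }
  // include endpoints: the MLE frequently clamps at blmin
  double flo = -ec.eval(lo), fhi = -ec.eval(hi);
  if (flo <= fx) { x = lo; fx = flo; }
  if (fhi < fx) { x = hi; fx = fhi; }
  fbest = -fx;
  return x;
}

// Coordinate ascent over branches until lnL gain < tol.
static double optimize_bl(Tree& tr, const PatData& pd, double blmin,
                          double blmax, double tol, int max_sweeps,
                          const std::vector<int>* only_edges = nullptr) {
  double cur = tree_lnl(tr, pd);
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double prev = cur;
    int ne = only_edges ? (int)only_edges->size() : tr.nedge();
    for (int k = 0; k < ne; ++k) {
      int e = only_edges ? (*only_edges)[k] : k;
      EdgeCache ec = edge_cache(tr, pd, e);
      double fbest;
      double t = brent_max(ec, blmin, blmax, 1e-8, fbest);
      if (fbest >= cur - 1e-12) {  // never move downhill
        tr.elen[e] = t;
        cur = fbest;
      }
    }
    if (cur - prev < tol) break;
  }
  return cur;
}

// ---------------------------------------------------------------- canonical

// Canonical unrooted-topology ID: root at the lexicographically smallest
// label, children sorted recursively; branch lengths ignored.
static std::string canon_sub(const Tree& tr, const std::vector<std::string>& lab,
                             int node, int from_edge) {
  if (node < tr.ntax) return lab[node];
  std::vector<std::string> parts;
  for (auto& nb : tr.adj[node])
    if (nb.second != from_edge)
      parts.push_back(canon_sub(tr, lab, nb.first, nb.second));
  if (parts.size() == 1) return parts[0];  // suppress degree-2 (rooting) nodes
  std::sort(parts.begin(), parts.end());
  std::string out = "(";
  for (size_t i = 0; i < parts.size(); ++i) {
    if (i) out += ",";
    out += parts[i];
  }
  out += ")";
  return out;
}

static std::string canonical_id(const Tree& tr,
                                const std::vector<std::string>& lab) {
  if (tr.ntax == 1) return lab[0] + ";";
  int root = 0;
  for (int i = 1; i < tr.ntax; ++i)
    if (lab[i] < lab[root]) root = i;
  if (tr.ntax == 2) {
    std::string a = lab[0], b = lab[1];
    if (b < a) std::swap(a, b);
    return "(" + a + "," + b + ");";
  }
  auto& nb = tr.adj[root][0];
  return "(" + lab[root] + "," + canon_sub(tr, lab, nb.first, nb.second) + ");";
}

// Newick with branch lengths, trifurcation at the internal node adjacent to
// leaf 0 (leaf order as given).
static std::string nwk_sub(const Tree& tr, const std::vector<std::string>& lab,
                           int node, int from_edge) {
  std::string s;
  if (node < tr.ntax) {
    s = lab[node];
  } else {
    s = "(";
    bool first = true;
    for (auto& nb : tr.adj[node]) {
      if (nb.second == from_edge) continue;
      if (!first) s += ",";
      first = false;
      s += nwk_sub(tr, lab, nb.first, nb.second);
    }
    s += ")";
  }
  char buf[40];
  snprintf(buf, sizeof(buf), ":%.10g", tr.elen[from_edge]);
  return s + buf;
}

static std::string to_newick(const Tree& tr,
                             const std::vector<std::string>& lab) {
  if (tr.ntax == 2) {
    char buf[40];
    snprintf(buf, sizeof(buf), ":%.10g", tr.elen[0]);
    return "(" + lab[0] + buf + "," + lab[1] + ":0);";
  }
  int root = tr.adj[0][0].first;  // internal neighbour of leaf 0
  std::string s = "(";
  bool first = true;
  for (auto& nb : tr.adj[root]) {
    if (!first) s += ",";
    first = false;
    s += nwk_sub(tr, lab, nb.first, nb.second);
  }
  return s + ");";
}

// ---------------------------------------------------------------- topology

// All unrooted binary topologies by stepwise addition (ntax <= 7 in
// practice; count is (2n-5)!!).
static void enumerate_topologies(int ntax, std::vector<Tree>& out) {
  Tree base;
  base.ntax = ntax;
  // star over leaves 0,1,2 with internal node ntax
  base.eu = {ntax, ntax, ntax};
  base.ev = {0, 1, 2};
  base.elen = {0.1, 0.1, 0.1};
  std::vector<Tree> cur = {base};
  for (int leaf = 3; leaf < ntax; ++leaf) {
    int newint = ntax + leaf - 2;  // next internal node id
    std::vector<Tree> nxt;
    for (const Tree& t : cur) {
      for (int e = 0; e < t.nedge(); ++e) {
        Tree t2 = t;
        int v = t2.ev[e];
        t2.ev[e] = newint;                   // split edge e
        t2.eu.push_back(newint); t2.ev.push_back(v);
        t2.elen.push_back(0.1);
        t2.eu.push_back(newint); t2.ev.push_back(leaf);
        t2.elen.push_back(0.1);
        nxt.push_back(std::move(t2));
      }
    }
    cur.swap(nxt);
  }
  for (Tree& t : cur) t.build_adj();
  out.swap(cur);
}

// JC distance matrix from patterns (pairwise deletion).
static void jc_distances(const PatData& pd, double blmax,
                         std::vector<std::vector<double>>& D) {
  int n = pd.ntax;
  D.assign(n, std::vector<double>(n, 0.0));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double shared = 0, diff = 0;
      for (int p = 0; p < pd.npat; ++p) {
        int a = pd.pat[(size_t)p * n + i], b = pd.pat[(size_t)p * n + j];
        if (a == ST_MISS || b == ST_MISS) continue;
        shared += pd.w[p];
        if (a != b) diff += pd.w[p];
      }
      double d;
      if (shared <= 0) {
        d = 1.0;  // no overlap: neutral moderate distance
      } else {
        double pr = diff / shared;
        double arg = 1.0 - 4.0 * pr / 3.0;
        d = (arg <= 1e-9) ? blmax : -0.75 * std::log(arg);
        if (d > blmax) d = blmax;
      }
      D[i][j] = D[j][i] = d;
    }
}

// Neighbour joining; deterministic ties (first minimum).
static Tree nj_tree(const PatData& pd, double blmin, double blmax) {
  int n = pd.ntax;
  Tree tr;
  tr.ntax = n;
  if (n == 2) {
    std::vector<std::vector<double>> D;
    jc_distances(pd, blmax, D);
    tr.eu = {0}; tr.ev = {1};
    tr.elen = {std::min(std::max(D[0][1], blmin), blmax)};
    tr.build_adj();
    return tr;
  }
  std::vector<std::vector<double>> D;
  jc_distances(pd, blmax, D);
  std::vector<int> act;           // active cluster -> node id
  for (int i = 0; i < n; ++i) act.push_back(i);
  std::vector<std::vector<double>> d = D;
  int next_int = n;               // internal ids n .. 2n-3
  auto clamp = [&](double x) { return std::min(std::max(x, blmin), blmax); };
  while ((int)act.size() > 3) {
    int m = (int)act.size();
    std::vector<double> r(m, 0.0);
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < m; ++j) r[i] += d[i][j];
    double best = 1e300; int bi = 0, bj = 1;
    for (int i = 0; i < m; ++i)
      for (int j = i + 1; j < m; ++j) {
        double q = (m - 2) * d[i][j] - r[i] - r[j];
        if (q < best - 1e-12) { best = q; bi = i; bj = j; }
      }
    double vi = 0.5 * d[bi][bj] + (r[bi] - r[bj]) / (2.0 * (m - 2));
    double vj = d[bi][bj] - vi;
    int u = next_int++;
    tr.eu.push_back(u); tr.ev.push_back(act[bi]); tr.elen.push_back(clamp(vi));
    tr.eu.push_back(u); tr.ev.push_back(act[bj]); tr.elen.push_back(clamp(vj));
    std::vector<double> dn;
    for (int k2 = 0; k2 < m; ++k2) {
      if (k2 == bi || k2 == bj) continue;
      dn.push_back(0.5 * (d[bi][k2] + d[bj][k2] - d[bi][bj]));
    }
    std::vector<int> act2;
    std::vector<std::vector<double>> d2;
    std::vector<int> keep;
    for (int k2 = 0; k2 < m; ++k2)
      if (k2 != bi && k2 != bj) keep.push_back(k2);
    int m2 = (int)keep.size() + 1;
    d2.assign(m2, std::vector<double>(m2, 0.0));
    for (size_t a = 0; a < keep.size(); ++a) {
      act2.push_back(act[keep[a]]);
      for (size_t b = 0; b < keep.size(); ++b) d2[a][b] = d[keep[a]][keep[b]];
      d2[a][m2 - 1] = d2[m2 - 1][a] = dn[a];
    }
    act2.push_back(u);
    act.swap(act2);
    d.swap(d2);
  }
  // join final three around one internal node
  int u = next_int++;
  double d01 = d[0][1], d02 = d[0][2], d12 = d[1][2];
  double v0 = 0.5 * (d01 + d02 - d12);
  double v1 = 0.5 * (d01 + d12 - d02);
  double v2 = 0.5 * (d02 + d12 - d01);
  tr.eu.push_back(u); tr.ev.push_back(act[0]); tr.elen.push_back(clamp(v0));
  tr.eu.push_back(u); tr.ev.push_back(act[1]); tr.elen.push_back(clamp(v1));
  tr.eu.push_back(u); tr.ev.push_back(act[2]); tr.elen.push_back(clamp(v2));
  tr.build_adj();
  return tr;
}

// The two NNI rearrangements around internal edge e of tr.
static void nni_neighbours(const Tree& tr, int e, std::vector<Tree>& out) {
  int u = tr.eu[e], v = tr.ev[e];
  if (u < tr.ntax || v < tr.ntax) return;
  // edges from u (not e) and from v (not e)
  std::vector<int> ue, ve;
  for (auto& nb : tr.adj[u]) if (nb.second != e) ue.push_back(nb.second);
  for (auto& nb : tr.adj[v]) if (nb.second != e) ve.push_back(nb.second);
  for (int which = 0; which < 2; ++which) {
    Tree t2 = tr;
    int ea = ue[1];           // subtree hanging off u
    int eb = ve[which];       // subtree hanging off v
    // reconnect: ea's far endpoint moves to v, eb's to u
    if (t2.eu[ea] == u) t2.eu[ea] = v; else t2.ev[ea] = v;
    if (t2.eu[eb] == v) t2.eu[eb] = u; else t2.ev[eb] = u;
    t2.build_adj();
    out.push_back(std::move(t2));
  }
}

struct FitResult {
  Tree tree;
  double lnl = 0;
  std::string canon;
};

// Full topology search.  strategy: 1 = exhaustive, 2 = NJ + NNI.
static FitResult search_topology_core(const PatData& pd,
                                      const std::vector<std::string>& lab,
                                      int strategy, double blmin, double blmax,
                                      double tol) {
  FitResult fr;
  int n = pd.ntax;
  if (n == 2) {
    fr.tree = nj_tree(pd, blmin, blmax);
    fr.lnl = optimize_bl(fr.tree, pd, blmin, blmax, tol, 10);
    fr.canon = canonical_id(fr.tree, lab);
    return fr;
  }
  if (strategy == 1 || n <= 3) {
    std::vector<Tree> topos;
    enumerate_topologies(n, topos);
    bool have = false;
    for (Tree& t : topos) {
      for (double& L : t.elen) L = std::max(0.05, blmin);
      double lnl = optimize_bl(t, pd, blmin, blmax, tol, 20);
      std::string cid = canonical_id(t, lab);
      if (!have || lnl > fr.lnl + 1e-9 ||
          (std::fabs(lnl - fr.lnl) <= 1e-9 && cid < fr.canon)) {
        have = true;
        fr.tree = t;
        fr.lnl = lnl;
        fr.canon = cid;
      }
    }
    return fr;
  }
  // NJ start + best-improvement NNI hill climbing
  Tree cur = nj_tree(pd, blmin, blmax);
  for (double& L : cur.elen) L = std::min(std::max(L, blmin), blmax);
  double curlnl = optimize_bl(cur, pd, blmin, blmax, tol, 20);
  const double accept_tol = std::max(tol, 1e-6);
  for (int round = 0; round < 50; ++round) {
    Tree bestT;
    double bestLnl = curlnl;
    bool improved = false;
    for (int e = 0; e < cur.nedge(); ++e) {
      if (cur.eu[e] < cur.ntax || cur.ev[e] < cur.ntax) continue;
      std::vector<Tree> nbs;
      nni_neighbours(cur, e, nbs);
      for (Tree& t2 : nbs) {
        // local re-optimization: the 5 edges around the swapped edge
        std::vector<int> local = {e};
        for (auto& nb : t2.adj[t2.eu[e]])
          if (nb.second != e) local.push_back(nb.second);
        for (auto& nb : t2.adj[t2.ev[e]])
          if (nb.second != e) local.push_back(nb.second);
        double lnl = optimize_bl(t2, pd, blmin, blmax, tol, 3, &local);
        if (lnl > bestLnl + accept_tol) {
          bestLnl = lnl;
          bestT = t2;
          improved = true;
        }
      }
    }
    if (!improved) break;
    cur = bestT;
    curlnl = optimize_bl(cur, pd, blmin, blmax, tol, 20);
  }
  fr.tree = cur;
  fr.lnl = curlnl;
  fr.canon = canonical_id(cur, lab);
  return fr;
}

// ---------------------------------------------------------------- splits

// Bipartition masks for internal edges (bit i = leaf i; normalized so bit 0
// is never set).
static void internal_splits(const Tree& tr, std::vector<uint32_t>& out) {
  out.clear();
  for (int e = 0; e < tr.nedge(); ++e) {
    if (tr.eu[e] < tr.ntax || tr.ev[e] < tr.ntax) continue;
    // leaves on ev side
    uint32_t mask = 0;
    std::vector<std::pair<int,int>> st = {{tr.ev[e], e}};
    while (!st.empty()) {
      auto [node, fe] = st.back();
      st.pop_back();
      if (node < tr.ntax) { mask |= (1u << node); continue; }
      for (auto& nb : tr.adj[node])
        if (nb.second != fe) st.push_back({nb.first, nb.second});
    }
    uint32_t all = (tr.ntax >= 32) ? 0xffffffffu
                                   : ((1u << tr.ntax) - 1u);
    if (mask & 1u) mask = (~mask) & all;
    out.push_back(mask);
  }
  std::sort(out.begin(), out.end());
}

// ---------------------------------------------------------------- interface

static std::vector<std::string> as_labels(const CharacterVector& lab) {
  std::vector<std::string> out;
  for (int i = 0; i < lab.size(); ++i) out.push_back(as<std::string>(lab[i]));
  return out;
}

// Build a Tree from an edge matrix (1-based, ape-style node numbering:
// leaves 1..ntax, internals ntax+1..) with branch lengths.
static Tree tree_from_edges(const IntegerMatrix& edge, const NumericVector& len,
                            int ntax) {
  Tree tr;
  tr.ntax = ntax;
  for (int i = 0; i < edge.nrow(); ++i) {
    tr.eu.push_back(edge(i, 0) - 1);
    tr.ev.push_back(edge(i, 1) - 1);
    tr.elen.push_back(len[i]);
  }
  // node ids may exceed 2n-3 if caller passes a rooted tree; keep max
  int mx = 0;
  for (int i = 0; i < (int)tr.eu.size(); ++i)
    mx = std::max(mx, std::max(tr.eu[i], tr.ev[i]));
  tr.adj.assign(mx + 1, {});
  for (int e = 0; e < tr.nedge(); ++e) {
    tr.adj[tr.eu[e]].push_back({tr.ev[e], e});
    tr.adj[tr.ev[e]].push_back({tr.eu[e], e});
  }
  return tr;
}

static PatData pat_from_window(const IntegerMatrix& enc, int start, int end) {
  std::vector<int> rows;
  for (int i = 0; i < enc.nrow(); ++i) rows.push_back(i);
  return compress_patterns(enc, rows, start, end);
}

// [[Rcpp::export(name = ".cpp_jc_lnl")]]
double cpp_jc_lnl(IntegerMatrix enc, IntegerMatrix edge, NumericVector len,
                  int ntax) {
  PatData pd = pat_from_window(enc, 0, enc.ncol());
  Tree tr = tree_from_edges(edge, len, ntax);
  if (tr.nedge() == 0) return 0.0;
  // works for rooted or unrooted input: likelihood is rooting-invariant,
  // computed from the flux across edge 0
  EdgeCache ec = edge_cache(tr, pd, 0);
  return ec.eval(tr.elen[0]);
}

// [[Rcpp::export(name = ".cpp_optimize_bl")]]
List cpp_optimize_bl(IntegerMatrix enc, IntegerMatrix edge, NumericVector len,
                     int ntax, double blmin, double blmax, double tol,
                     int max_sweeps) {
  PatData pd = pat_from_window(enc, 0, enc.ncol());
  Tree tr = tree_from_edges(edge, len, ntax);
  for (double& L : tr.elen) L = std::min(std::max(L, blmin), blmax);
  double lnl = optimize_bl(tr, pd, blmin, blmax, tol, max_sweeps);
  return List::create(_["lnl"] = lnl,
                      _["lengths"] = NumericVector(tr.elen.begin(),
                                                   tr.elen.end()));
}

// [[Rcpp::export(name = ".cpp_canonical_id")]]
String cpp_canonical_id(IntegerMatrix edge, int ntax, CharacterVector labels) {
  NumericVector len(edge.nrow(), 0.1);
  Tree tr = tree_from_edges(edge, len, ntax);
  return canonical_id(tr, as_labels(labels));
}

// Count of distinct full row strings over [start, end).
static int n_unique_rows(const IntegerMatrix& enc, int start, int end) {
  std::vector<std::string> rows;
  for (int i = 0; i < enc.nrow(); ++i) {
    std::string r;
    r.reserve(end - start);
    for (int s = start; s < end; ++s) r.push_back((char)('0' + enc(i, s)));
    rows.push_back(std::move(r));
  }
  std::sort(rows.begin(), rows.end());
  return (int)(std::unique(rows.begin(), rows.end()) - rows.begin());
}

// [[Rcpp::export(name = ".cpp_count_informative")]]
int cpp_count_informative(IntegerMatrix enc, int start, int end) {
  int count = 0;
  for (int s = start; s < end; ++s) {
    int tab[4] = {0, 0, 0, 0};
    for (int i = 0; i < enc.nrow(); ++i) {
      int st = enc(i, s);
      if (st != ST_MISS) tab[st]++;
    }
    int k = 0;
    for (int x = 0; x < 4; ++x)
      if (tab[x] >= 2) ++k;
    if (k >= 2) ++count;
  }
  return count;
}

static double bootstrap_mean_support(const PatData& pd,
                                     const std::vector<std::string>& lab,
                                     const Tree& mltree, int strategy,
                                     double blmin, double blmax, double tol,
                                     int reps) {
  std::vector<uint32_t> mlsplits;
  internal_splits(mltree, mlsplits);
  if (mlsplits.empty() || reps <= 0) return NA_REAL;
  std::vector<double> hits(mlsplits.size(), 0.0);
  int nsites = (int)std::lround(pd.nsites);
  std::vector<double> prob(pd.npat);
  for (int p = 0; p < pd.npat; ++p) prob[p] = pd.w[p] / pd.nsites;
  std::vector<int> draw(pd.npat);
  for (int r = 0; r < reps; ++r) {
    rmultinom(nsites, prob.data(), pd.npat, draw.data());
    PatData bd;
    bd.ntax = pd.ntax;
    for (int p = 0; p < pd.npat; ++p) {
      if (draw[p] == 0) continue;
      for (int i = 0; i < pd.ntax; ++i)
        bd.pat.push_back(pd.pat[(size_t)p * pd.ntax + i]);
      bd.w.push_back((double)draw[p]);
      ++bd.npat;
    }
    bd.nsites = nsites;
    FitResult fr = search_topology_core(bd, lab, strategy, blmin, blmax, tol);
    std::vector<uint32_t> sp;
    internal_splits(fr.tree, sp);
    for (size_t i = 0; i < mlsplits.size(); ++i)
      if (std::binary_search(sp.begin(), sp.end(), mlsplits[i]))
        hits[i] += 1.0;
  }
  double mean = 0.0;
  for (double h : hits) mean += 100.0 * h / reps;
  return mean / (double)hits.size();
}

// Fit one window (rows already subset to taxa with data).
// [[Rcpp::export(name = ".cpp_search_topology")]]
List cpp_search_topology(IntegerMatrix enc, CharacterVector labels,
                         int strategy, double blmin, double blmax, double tol,
                         int boot_reps, int boot_min_unique) {
  PatData pd = pat_from_window(enc, 0, enc.ncol());
  std::vector<std::string> lab = as_labels(labels);
  int n = enc.nrow();
  int strat = strategy == 0 ? (n <= 5 ? 1 : 2) : strategy;
  FitResult fr = search_topology_core(pd, lab, strat, blmin, blmax, tol);
  int nuniq = n_unique_rows(enc, 0, enc.ncol());
  double support = NA_REAL;
  if (boot_reps > 0 && nuniq >= boot_min_unique)
    support = bootstrap_mean_support(pd, lab, fr.tree, strat, blmin, blmax,
                                     tol, boot_reps);
  return List::create(
      _["lnl"] = fr.lnl, _["k"] = 2 * n - 3,
      _["canonical"] = fr.canon, _["newick"] = to_newick(fr.tree, lab),
      _["n_unique"] = nuniq, _["mean_support"] = support,
      _["n_patterns"] = pd.npat);
}

// Batch fit over many windows of one alignment.  enc: ntax x L; windows as
// 0-based half-open [starts, ends); fit only where analyzable.  In lenient
// mode taxa that are all-missing within a window are dropped from its fit.
// [[Rcpp::export(name = ".cpp_fit_windows")]]
List cpp_fit_windows(IntegerMatrix enc, CharacterVector labels,
                     IntegerVector starts, IntegerVector ends,
                     LogicalVector analyzable, int strategy, double blmin,
                     double blmax, double tol, int boot_reps,
                     int boot_min_unique, bool drop_missing_taxa) {
  int nw = starts.size();
  int ntax_all = enc.nrow();
  std::vector<std::string> lab_all = as_labels(labels);
  NumericVector lnl(nw, NA_REAL), support(nw, NA_REAL);
  IntegerVector kpar(nw, NA_INTEGER), ntx(nw, NA_INTEGER),
      nuq(nw, NA_INTEGER), npat(nw, NA_INTEGER);
  CharacterVector canon(nw, NA_STRING), nwk(nw, NA_STRING);
  for (int wi = 0; wi < nw; ++wi) {
    if (!analyzable[wi]) continue;
    int s = starts[wi], e = ends[wi];
    std::vector<int> rows;
    if (drop_missing_taxa) {
      for (int i = 0; i < ntax_all; ++i) {
        bool any = false;
        for (int c = s; c < e && !any; ++c)
          if (enc(i, c) != ST_MISS) any = true;
        if (any) rows.push_back(i);
      }
    } else {
      for (int i = 0; i < ntax_all; ++i) rows.push_back(i);
    }
    int n = (int)rows.size();
    if (n < 2) continue;
    PatData pd = compress_patterns(enc, rows, s, e);
    std::vector<std::string> lab;
    for (int i : rows) lab.push_back(lab_all[i]);
    int strat = strategy == 0 ? (n <= 5 ? 1 : 2) : strategy;
    FitResult fr = search_topology_core(pd, lab, strat, blmin, blmax, tol);
    // unique rows within the subset
    IntegerMatrix sub(n, e - s);
    for (int i = 0; i < n; ++i)
      for (int c = s; c < e; ++c) sub(i, c - s) = enc(rows[i], c);
    int nu = n_unique_rows(sub, 0, e - s);
    lnl[wi] = fr.lnl;
    kpar[wi] = (n == 2) ? 1 : 2 * n - 3;
    ntx[wi] = n;
    nuq[wi] = nu;
    npat[wi] = pd.npat;
    canon[wi] = fr.canon;
    nwk[wi] = to_newick(fr.tree, lab);
    if (boot_reps > 0 && nu >= boot_min_unique)
      support[wi] = bootstrap_mean_support(pd, lab, fr.tree, strat, blmin,
                                           blmax, tol, boot_reps);
    if (wi % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["lnl"] = lnl, _["k"] = kpar, _["n_taxa"] = ntx,
                      _["n_unique"] = nuq, _["n_patterns"] = npat,
                      _["canonical"] = canon, _["newick"] = nwk,
                      _["mean_support"] = support);
}

// ---------------------------------------------------------------- simulate

// Minimal Newick parser for the simulator's own gene-tree output: labels
// restricted to the given taxa, branch lengths after ':'.  Returns node
// count; fills parent/plen (leaf ids = taxa indices, internals from ntax).
struct SimTree {
  std::vector<int> parent;
  std::vector<double> plen;
  std::vector<std::vector<int>> children;
  int root = -1;
  int nnodes = 0;
};

static int parse_nwk_node(const std::string& s, size_t& pos, SimTree& tr,
                          const std::unordered_map<std::string, int>& taxmap,
                          int ntax) {
  auto ensure = [&](int id) {
    if (id >= (int)tr.parent.size()) {
      tr.parent.resize(id + 1, -1);
      tr.plen.resize(id + 1, 0.0);
      tr.children.resize(id + 1);
    }
    if (id + 1 > tr.nnodes) tr.nnodes = id + 1;
  };
  if (s[pos] == '(') {
    ++pos;
    int me = std::max((int)tr.parent.size(), ntax);
    ensure(me);
    while (true) {
      int child = parse_nwk_node(s, pos, tr, taxmap, ntax);
      double len = 0.0;
      if (pos < s.size() && s[pos] == ':') {
        ++pos;
        size_t next = pos;
        while (next < s.size() && s[next] != ',' && s[next] != ')' &&
               s[next] != ';')
          ++next;
        len = std::atof(s.substr(pos, next - pos).c_str());
        pos = next;
      }
      tr.parent[child] = me;
      tr.plen[child] = len;
      tr.children[me].push_back(child);
      if (pos < s.size() && s[pos] == ',') { ++pos; continue; }
      break;
    }
    if (pos >= s.size() || s[pos] != ')')
      stop("malformed Newick (missing ')')");
    ++pos;
    return me;
  }
  size_t next = pos;
  while (next < s.size() && s[next] != ':' && s[next] != ',' &&
         s[next] != ')' && s[next] != ';')
    ++next;
  std::string lab = s.substr(pos, next - pos);
  pos = next;
  auto it = taxmap.find(lab);
  if (it == taxmap.end()) stop("Newick leaf '" + lab + "' is not a taxon");
  ensure(it->second);
  return it->second;
}

// Simulate a concatenated JC alignment over a set of loci.  newicks[i] is
// the gene tree of locus i (branch lengths in subs/site), lens[i] its span
// in sites.  Taxa order fixes the output rows.  Uses R's RNG.
// [[Rcpp::export(name = ".cpp_simulate_alignment")]]
IntegerMatrix cpp_simulate_alignment(CharacterVector newicks,
                                     IntegerVector lens,
                                     CharacterVector taxa) {
  int ntax = taxa.size();
  std::unordered_map<std::string, int> taxmap;
  for (int i = 0; i < ntax; ++i) taxmap[as<std::string>(taxa[i])] = i;
  long total = 0;
  for (int i = 0; i < lens.size(); ++i) total += lens[i];
  IntegerMatrix out(ntax, (int)total);
  long offset = 0;
  std::vector<std::vector<int>> seq;
  for (int li = 0; li < newicks.size(); ++li) {
    std::string s = as<std::string>(newicks[li]);
    SimTree tr;
    tr.parent.resize(ntax, -1);
    tr.plen.resize(ntax, 0.0);
    tr.children.resize(ntax);
    tr.nnodes = ntax;
    size_t pos = 0;
    tr.root = parse_nwk_node(s, pos, tr, taxmap, ntax);
    int nsites = lens[li];
    seq.assign(tr.nnodes, {});
    seq[tr.root].resize(nsites);
    for (int c = 0; c < nsites; ++c)
      seq[tr.root][c] = (int)(unif_rand() * 4.0) & 3;
    // preorder DFS
    std::vector<int> stack = {tr.root};
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      for (int child : tr.children[u]) {
        double ps, pdv;
        jc_probs(tr.plen[child], ps, pdv);
        std::vector<int>& cs = seq[child];
        cs.resize(nsites);
        const std::vector<int>& psq = seq[u];
        for (int c = 0; c < nsites; ++c) {
          double u1 = unif_rand();
          if (u1 < ps) {
            cs[c] = psq[c];
          } else {
            int k = (int)((u1 - ps) / pdv);
            if (k > 2) k = 2;
            cs[c] = k >= psq[c] ? k + 1 : k;
          }
        }
        stack.push_back(child);
      }
    }
    for (int i = 0; i < ntax; ++i)
      for (int c = 0; c < nsites; ++c) out(i, offset + c) = seq[i][c];
    offset += nsites;
    if (li % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Evolve one locus under JC along a rooted tree given by an ape-style edge
// matrix (preorder; root = ntax+1).  Branch lengths in subs/site.  Uses R's
// RNG.  Returns ntax x nsites states 0..3.
// [[Rcpp::export(name = ".cpp_evolve_jc")]]
IntegerMatrix cpp_evolve_jc(IntegerMatrix edge, NumericVector len, int ntax,
                            int nnode_total, int nsites) {
  IntegerMatrix out(ntax, nsites);
  std::vector<std::vector<int>> seq(nnode_total);
  int root = ntax;  // 0-based id of ape node ntax+1
  seq[root].resize(nsites);
  for (int s = 0; s < nsites; ++s)
    seq[root][s] = (int)(unif_rand() * 4.0) & 3;
  for (int i = 0; i < edge.nrow(); ++i) {
    int par = edge(i, 0) - 1, child = edge(i, 1) - 1;
    double ps, pdv;
    jc_probs(len[i], ps, pdv);
    const std::vector<int>& p = seq[par];
    std::vector<int>& c = seq[child];
    c.resize(nsites);
    for (int s = 0; s < nsites; ++s) {
      double u = unif_rand();
      if (u < ps) {
        c[s] = p[s];
      } else {
        int k = (int)((u - ps) / pdv);
        if (k > 2) k = 2;
        // k-th state other than p[s]
        int st = k >= p[s] ? k + 1 : k;
        c[s] = st;
      }
    }
    if (child < ntax)
      for (int s = 0; s < nsites; ++s) out(child, s) = c[s];
  }
  return out;
}
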