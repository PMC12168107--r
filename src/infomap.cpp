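// Greedy two-level map-equation optimisation (Louvain-style local moves with
// module aggregation) for undirected, unweighted networks, with independent
// seeded restarts. Only the partition-dependent part of the description
// length is tracked during the search; the constant node-rate entropy term is
// added back at the end.

#include <Rcpp.h>
#include <cmath>
#include <map>
#include <random>
#include <vector>
using namespace Rcpp;

static inline double plogp(double x) {
  return x > 1e-300 ? x * std::log2(x) : 0.0;
}

struct Graph {
  int n;
  std::vector<std::vector<std::pair<int, double>>> adj; // neighbour, weight
  std::vector<double> deg;       // weighted degree incl. 2*selfloop
  std::vector<double> selfloop;  // self-loop weight
};

// Deterministic Fisher-Yates shuffle (own loop; avoids stdlib variation).
static void shuffle_order(std::vector<int>& v, std::mt19937& rng) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)(rng() % (unsigned)(i + 1));
    std::swap(v[i], v[j]);
  }
}

// One level of local moves on `g`; membership modified in place.
// Returns true if any move was made. twoE is the total degree of the
// ORIGINAL graph (constant across levels).
static bool local_moves(const Graph& g, std::vector<int>& member,
                        double twoE, std::mt19937& rng) {
  int n = g.n;
  std::vector<double> modDeg(n, 0.0), modInside(n, 0.0);
  for (int v = 0; v < n; ++v) {
    modDeg[member[v]] += g.deg[v];
    modInside[member[v]] += g.selfloop[v];
  }
  for (int v = 0; v < n; ++v)
    for (auto& e : g.adj[v])
      if (e.first > v && member[e.first] == member[v])
        modInside[member[v]] += e.second;

  double sum_q = 0.0, sum_plogp_q = 0.0, sum_plogp_qw = 0.0;
  for (int m = 0; m < n; ++m) {
    if (modDeg[m] <= 0) continue;
    double q = (modDeg[m] - 2.0 * modInside[m]) / twoE;
    sum_q += q;
    sum_plogp_q += plogp(q);
    sum_plogp_qw += plogp(q + modDeg[m] / twoE);
  }

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<double> kto(n, 0.0); // edge weight from v to each module
  std::vector<int> touched;
  bool any_move = false;
  const double eps = 1e-12;

  bool improved = true;
  while (improved) {
    improved = false;
    shuffle_order(order, rng);
    for (int oi = 0; oi < n; ++oi) {
      int v = order[oi];
      int A = member[v];
      touched.clear();
      for (auto& e : g.adj[v]) {
        int m = member[e.first];
        if (kto[m] == 0.0) touched.push_back(m);
        kto[m] += e.second;
      }
      double kA = kto[A]; // weight to own module (excluding selfloop)
      // current contribution of module A and its state without v
      double qA = (modDeg[A] - 2.0 * modInside[A]) / twoE;
      double degA2 = modDeg[A] - g.deg[v];
      double inA2 = modInside[A] - kA - g.selfloop[v];
      double qA2 = degA2 > 0 ? (degA2 - 2.0 * inA2) / twoE : 0.0;
      double baseA_q = sum_q - qA + qA2;
      double baseA_pq = sum_plogp_q - plogp(qA) + plogp(qA2);
      double baseA_pqw = sum_plogp_qw - plogp(qA + modDeg[A] / twoE) +
        (degA2 > 0 ? plogp(qA2 + degA2 / twoE) : 0.0);
      double curL = plogp(sum_q) - 2.0 * sum_plogp_q + sum_plogp_qw;

      int best = A;
      double bestL = curL;
      for (int ti = 0; ti < (int)touched.size(); ++ti) {
        int B = touched[ti];
        if (B == A) continue;
        double qB = (modDeg[B] - 2.0 * modInside[B]) / twoE;
        double degB2 = modDeg[B] + g.deg[v];
        double inB2 = modInside[B] + kto[B] + g.selfloop[v];
        double qB2 = (degB2 - 2.0 * inB2) / twoE;
        double nq = baseA_q - qB + qB2;
        double npq = baseA_pq - plogp(qB) + plogp(qB2);
        double npqw = baseA_pqw - plogp(qB + modDeg[B] / twoE) +
          plogp(qB2 + degB2 / twoE);
        double L = plogp(nq) - 2.0 * npq + npqw;
        if (L < bestL - eps) { bestL = L; best = B; }
      }
      if (best != A) {
        // apply move
        double qB = (modDeg[best] - 2.0 * modInside[best]) / twoE;
        sum_q = sum_q - qA - qB;
        sum_plogp_q = sum_plogp_q - plogp(qA) - plogp(qB);
        sum_plogp_qw = sum_plogp_qw - plogp(qA + modDeg[A] / twoE) -
          plogp(qB + modDeg[best] / twoE);
        modDeg[A] -= g.deg[v];
        modInside[A] -= kA + g.selfloop[v];
        modDeg[best] += g.deg[v];
        modInside[best] += kto[best] + g.selfloop[v];
        member[v] = best;
        double qA2b = modDeg[A] > 0 ?
          (modDeg[A] - 2.0 * modInside[A]) / twoE : 0.0;
        double qB2b = (modDeg[best] - 2.0 * modInside[best]) / twoE;
        sum_q += qA2b + qB2b;
        sum_plogp_q += plogp(qA2b) + plogp(qB2b);
        sum_plogp_qw += (modDeg[A] > 0 ?
                           plogp(qA2b + modDeg[A] / twoE) : 0.0) +
          plogp(qB2b + modDeg[best] / twoE);
        improved = true;
        any_move = true;
      }
      for (int m : touched) kto[m] = 0.0;
    }
  }
  return any_move;
}

// Aggregate graph by modules; returns new graph and writes the module id of
// each old node's supernode into `remap`.
static Graph aggregate(const Graph& g, const std::vector<int>& member,
                       std::vector<int>& remap) {
  int n = g.n;
  remap.assign(n, -1);
  int k = 0;
  for (int v = 0; v < n; ++v)
    if (remap[member[v]] == -1) remap[member[v]] = k++;
  Graph h;
  h.n = k;
  h.adj.assign(k, {});
  h.deg.assign(k, 0.0);
  h.selfloop.assign(k, 0.0);
  // accumulate edge weights between supernodes
  std::vector<std::map<int, double>> acc(k);
  for (int v = 0; v < n; ++v) {
    int a = remap[member[v]];
    h.selfloop[a] += g.selfloop[v];
    for (auto& e : g.adj[v]) {
      if (e.first < v) continue; // each undirected edge once
      int b = remap[member[e.first]];
      if (a == b) h.selfloop[a] += (e.first == v) ? 0.0 : e.second;
      else {
        int lo = std::min(a, b), hi = std::max(a, b);
        acc[lo][hi] += e.second;
      }
    }
  }
  for (int a = 0; a < k; ++a)
    for (auto& kv : acc[a]) {
      h.adj[a].push_back({kv.first, kv.second});
      h.adj[kv.first].push_back({a, kv.second});
    }
  for (int a = 0; a < k; ++a) {
    double d = 2.0 * h.selfloop[a];
    for (auto& e : h.adj[a]) d += e.second;
    h.deg[a] = d;
  }
  return h;
}

// Compact membership ids in place; returns number of distinct modules.
static int compact_ids(std::vector<int>& m) {
  std::vector<int> remap(m.size(), -1);
  int k = 0;
  for (size_t v = 0; v < m.size(); ++v) {
    if (remap[m[v]] == -1) remap[m[v]] = k++;
    m[v] = remap[m[v]];
  }
  return k;
}

// Coarse-tuning: split each module into submodules (local moves on the
// induced subgraph), aggregate the full graph by submodules, and run local
// moves on that graph initialised from the parent partition so that whole
// submodules can change module. Updates `flat`; returns true on improvement.
static bool coarse_tune(const Graph& g0, std::vector<int>& flat, double twoE,
                        std::mt19937& rng) {
  int n = g0.n;
  int n_mod = compact_ids(flat);
  // nodes per module
  std::vector<std::vector<int>> members(n_mod);
  for (int v = 0; v < n; ++v) members[flat[v]].push_back(v);
  std::vector<int> submod(n, -1), local(n, -1);
  int next_id = 0;
  for (int m = 0; m < n_mod; ++m) {
    const std::vector<int>& nodes = members[m];
    if ((int)nodes.size() == 1) { submod[nodes[0]] = next_id++; continue; }
    Graph sub;
    sub.n = (int)nodes.size();
    sub.adj.assign(sub.n, {});
    sub.deg.assign(sub.n, 0.0);
    sub.selfloop.assign(sub.n, 0.0);
    for (int i = 0; i < sub.n; ++i) local[nodes[i]] = i;
    for (int i = 0; i < sub.n; ++i) {
      int v = nodes[i];
      sub.selfloop[i] = g0.selfloop[v];
      for (auto& e : g0.adj[v])
        if (flat[e.first] == m)
          sub.adj[i].push_back({local[e.first], e.second});
    }
    for (int i = 0; i < sub.n; ++i) {
      double d = 2.0 * sub.selfloop[i];
      for (auto& e : sub.adj[i]) d += e.second;
      sub.deg[i] = d;
    }
    std::vector<int> sm(sub.n);
    for (int i = 0; i < sub.n; ++i) sm[i] = i;
    local_moves(sub, sm, twoE, rng);
    compact_ids(sm);
    for (int i = 0; i < sub.n; ++i) submod[nodes[i]] = next_id + sm[i];
    int mx = 0;
    for (int i = 0; i < sub.n; ++i) mx = std::max(mx, sm[i]);
    next_id += mx + 1;
  }
  // aggregate by submodules; initial membership = parent module
  std::vector<int> remap;
  Graph h = aggregate(g0, submod, remap);
  std::vector<int> super_parent(h.n, -1);
  for (int v = 0; v < n; ++v) super_parent[remap[submod[v]]] = flat[v];
  bool moved = local_moves(h, super_parent, twoE, rng);
  if (moved)
    for (int v = 0; v < n; ++v) flat[v] = super_parent[remap[submod[v]]];
  return moved;
}

// [[Rcpp::export]]
List infomap_greedy_cpp(IntegerVector from, IntegerVector to, int n_nodes,
                        int n_runs, int seed) {
  int m = from.size();
  Graph g0;
  g0.n = n_nodes;
  g0.adj.assign(n_nodes, {});
  g0.deg.assign(n_nodes, 0.0);
  g0.selfloop.assign(n_nodes, 0.0);
  for (int e = 0; e < m; ++e) {
    int a = from[e], b = to[e];
    if (a == b) { g0.selfloop[a] += 1.0; continue; }
    g0.adj[a].push_back({b, 1.0});
    g0.adj[b].push_back({a, 1.0});
  }
  double twoE = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    double d = 2.0 * g0.selfloop[v];
    for (auto& e : g0.adj[v]) d += e.second;
    g0.deg[v] = d;
    twoE += d;
  }
  // constant term: entropy of original node visit rates
  double const_term = 0.0;
  for (int v = 0; v < n_nodes; ++v) const_term -= plogp(g0.deg[v] / twoE);

  std::vector<int> best_member;
  double best_L = R_PosInf;
  int best_run = -1;

  for (int run = 0; run < n_runs; ++run) {
    std::mt19937 rng((unsigned)(seed) * 1000003u + (unsigned)run);
    // flat membership over original nodes
    std::vector<int> flat(n_nodes);
    for (int v = 0; v < n_nodes; ++v) flat[v] = v;
    // Outer loop alternates an aggregation phase (Louvain-style supernode
    // merges) with a fine-tuning phase (single-node moves on the original
    // graph starting from the current partition), until neither improves.
    bool keep_going = true;
    while (keep_going) {
      keep_going = false;
      // aggregation phase on the module graph implied by `flat`
      std::vector<int> remap0;
      Graph g = aggregate(g0, flat, remap0);
      for (int v = 0; v < n_nodes; ++v) flat[v] = remap0[flat[v]];
      std::vector<int> member(g.n);
      for (int v = 0; v < g.n; ++v) member[v] = v;
      while (true) {
        bool moved = local_moves(g, member, twoE, rng);
        if (moved) keep_going = true;
        std::vector<int> remap;
        Graph h = aggregate(g, member, remap);
        for (int v = 0; v < n_nodes; ++v) flat[v] = remap[member[flat[v]]];
        if (!moved || h.n == g.n) break;
        g = h;
        member.resize(g.n);
        for (int v = 0; v < g.n; ++v) member[v] = v;
      }
      // fine-tuning phase: node-level moves from the current partition
      if (local_moves(g0, flat, twoE, rng)) keep_going = true;
      // coarse-tuning phase: detect submodules inside each module by local
      // moves on the module's induced subgraph, then let whole submodules
      // move between modules on the submodule-aggregated graph
      if (coarse_tune(g0, flat, twoE, rng)) keep_going = true;
    }
    // evaluate final codelength of the flat partition on the original graph
    std::vector<int> remapf;
    Graph g = aggregate(g0, flat, remapf);
    for (int v = 0; v < n_nodes; ++v) flat[v] = remapf[flat[v]];
    double sq = 0.0, spq = 0.0, spqw = 0.0;
    for (int a = 0; a < g.n; ++a) {
      double q = (g.deg[a] - 2.0 * g.selfloop[a]) / twoE;
      sq += q;
      spq += plogp(q);
      spqw += plogp(q + g.deg[a] / twoE);
    }
    double L = plogp(sq) - 2.0 * spq + spqw + const_term;
    if (L < best_L - 1e-12) {
      best_L = L;
      best_member = flat;
      best_run = run + 1;
    }
  }

  return List::create(_["membership"] = IntegerVector(best_member.begin(),
                                                      best_member.end()),
                      _["codelength"] = best_L,
                      _["best_run"] = best_run);
}
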