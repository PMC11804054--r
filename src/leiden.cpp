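// Multiplex Leiden community detection over an arbitrary number of edge
// layers sharing one node set. Per-layer quality is the unnormalized
// RB-configuration modularity
//   Q_l = sum_ij (A_ij - gamma_l k_i k_j / (2m_l)) delta(c_i, c_j)
// over ordered pairs (k_i = row sum of A including a self-loop once,
// 2m_l = sum of all entries); the optimized objective is
//   Q_total = sum_l w_l Q_l.
// The optimizer follows the Leiden scheme: queue-based local moving,
// refinement restricted to communities (merges accepted only on strictly
// positive gain), and simultaneous aggregation of every layer with
// self-loops kept, iterated until a pass yields no quality increase.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

namespace {

struct Layer {
  int n = 0;
  std::vector<std::vector<std::pair<int, double>>> adj;  // no self pairs
  std::vector<double> self;  // A_ii
  std::vector<double> deg;   // k_i
  double twom = 0.0;         // sum_i k_i
  void finalize() {
    deg.assign(n, 0.0);
    twom = 0.0;
    for (int v = 0; v < n; ++v) {
      double d = self[v];
      for (auto &e : adj[v]) d += e.second;
      deg[v] = d;
      twom += d;
    }
  }
};

// deterministic RNG (splitmix64), independent of R's RNG state
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed + 0x9E3779B97f4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97f4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  int below(int bound) { return (int)(next() % (uint64_t)bound); }
  void shuffle(std::vector<int> &v) {  // Fisher-Yates
    for (int i = (int)v.size() - 1; i > 0; --i) std::swap(v[i], v[below(i + 1)]);
  }
};

double quality(const std::vector<Layer> &layers,
               const std::vector<double> &lw,
               const std::vector<double> &lres,
               const std::vector<int> &comm, int ncomm) {
  double q = 0.0;
  for (size_t l = 0; l < layers.size(); ++l) {
    if (lw[l] == 0.0) continue;
    const Layer &L = layers[l];
    double in = 0.0;
    std::vector<double> tot(ncomm, 0.0);
    for (int v = 0; v < L.n; ++v) {
      in += L.self[v];
      tot[comm[v]] += L.deg[v];
      for (auto &e : L.adj[v])
        if (comm[e.first] == comm[v]) in += e.second;
    }
    double nul = 0.0;
    if (L.twom > 0) {
      for (int c = 0; c < ncomm; ++c) nul += tot[c] * tot[c];
      nul *= lres[l] / L.twom;
    }
    q += lw[l] * (in - nul);
  }
  return q;
}

// One queue-based local moving phase; comm is modified in place.
// Returns the number of accepted moves.
int local_move(const std::vector<Layer> &layers,
               const std::vector<double> &lw,
               const std::vector<double> &lres,
               std::vector<int> &comm, Rng &rng) {
  const int n = layers[0].n;
  const int nl = (int)layers.size();
  const double tol = 1e-12;

  // community stats per layer
  std::vector<std::vector<double>> tot(nl, std::vector<double>(n, 0.0));
  std::vector<int> csize(n, 0);
  for (int v = 0; v < n; ++v) {
    csize[comm[v]]++;
    for (int l = 0; l < nl; ++l) tot[l][comm[v]] += layers[l].deg[v];
  }
  std::vector<int> free_ids;
  for (int c = 0; c < n; ++c) if (csize[c] == 0) free_ids.push_back(c);

  std::vector<int> order(n);
  for (int v = 0; v < n; ++v) order[v] = v;
  rng.shuffle(order);
  std::vector<int> queue(order);
  std::vector<char> in_queue(n, 1);
  size_t head = 0;

  // scratch: edge weight from v to each community, per layer
  std::vector<std::vector<double>> kvc(nl, std::vector<double>(n, 0.0));
  std::vector<int> touched;

  int moved = 0;
  while (head < queue.size()) {
    int v = queue[head++];
    in_queue[v] = 0;
    int a = comm[v];

    touched.clear();
    for (int l = 0; l < nl; ++l) {
      if (lw[l] == 0.0) continue;
      for (auto &e : layers[l].adj[v]) {
        int c = comm[e.first];
        bool seen = false;
        if (kvc[l][c] != 0.0) seen = true;
        else for (int ll = 0; ll < nl; ++ll) if (kvc[ll][c] != 0.0) { seen = true; break; }
        if (!seen) touched.push_back(c);
        kvc[l][c] += e.second;
      }
    }
    // candidate communities: neighbor communities plus one empty
    // community; on small problems all non-empty communities are
    // considered, which makes the search exhaustive per move
    int empty_c = -1;
    if (csize[a] > 1 && !free_ids.empty()) empty_c = free_ids.back();
    if (n <= 64) {
      for (int c = 0; c < n; ++c) {
        if (c == a || csize[c] == 0) continue;
        bool seen = false;
        for (int ll = 0; ll < nl; ++ll) if (kvc[ll][c] != 0.0) { seen = true; break; }
        if (!seen) touched.push_back(c);
      }
    }

    double best = tol;  // must strictly improve to move
    int best_c = a;
    auto eval = [&](int c) {
      if (c == a) return;
      double d = 0.0;
      for (int l = 0; l < nl; ++l) {
        if (lw[l] == 0.0) continue;
        const Layer &L = layers[l];
        double kc = kvc[l][c], ka = kvc[l][a];
        double dl = 2.0 * (kc - ka);
        if (L.twom > 0) {
          double K = L.deg[v];
          dl += 2.0 * lres[l] * K * ((tot[l][a] - K) - tot[l][c]) / L.twom;
        }
        d += lw[l] * dl;
      }
      if (d > best + tol || (d > best - tol && best_c != a && c < best_c)) {
        best = d; best_c = c;
      }
    };
    std::sort(touched.begin(), touched.end());
    for (int c : touched) eval(c);
    if (empty_c >= 0) eval(empty_c);

    if (best_c != a) {
      // apply move
      if (best_c == empty_c) free_ids.pop_back();
      csize[a]--; csize[best_c]++;
      if (csize[a] == 0) free_ids.push_back(a);
      for (int l = 0; l < nl; ++l) {
        tot[l][a] -= layers[l].deg[v];
        tot[l][best_c] += layers[l].deg[v];
      }
      comm[v] = best_c;
      moved++;
      for (int l = 0; l < nl; ++l) {
        if (lw[l] == 0.0) continue;
        for (auto &e : layers[l].adj[v]) {
          int u = e.first;
          if (comm[u] != best_c && !in_queue[u]) {
            in_queue[u] = 1;
            queue.push_back(u);
          }
        }
      }
    }
    for (int l = 0; l < nl; ++l)
      for (int c : touched) kvc[l][c] = 0.0;
  }
  return moved;
}

// Refinement: within each community, grow refined clusters from
// singletons; a node alone in its refined cluster may merge into an
// adjacent refined cluster of the same community when the quality gain
// is strictly positive.
std::vector<int> refine(const std::vector<Layer> &layers,
                        const std::vector<double> &lw,
                        const std::vector<double> &lres,
                        const std::vector<int> &comm, Rng &rng) {
  const int n = layers[0].n;
  const int nl = (int)layers.size();
  const double tol = 1e-12;

  std::vector<int> ref(n);
  for (int v = 0; v < n; ++v) ref[v] = v;
  std::vector<int> rsize(n, 1);
  std::vector<std::vector<double>> rtot(nl, std::vector<double>(n, 0.0));
  for (int l = 0; l < nl; ++l)
    for (int v = 0; v < n; ++v) rtot[l][v] = layers[l].deg[v];

  std::vector<int> order(n);
  for (int v = 0; v < n; ++v) order[v] = v;
  rng.shuffle(order);

  std::vector<std::vector<double>> kvr(nl, std::vector<double>(n, 0.0));
  std::vector<int> touched;

  for (int v : order) {
    if (rsize[ref[v]] != 1) continue;  // only isolated nodes merge
    int a = ref[v];
    touched.clear();
    for (int l = 0; l < nl; ++l) {
      if (lw[l] == 0.0) continue;
      for (auto &e : layers[l].adj[v]) {
        if (comm[e.first] != comm[v]) continue;
        int r = e.first >= 0 ? ref[e.first] : -1;
        bool seen = false;
        for (int ll = 0; ll < nl; ++ll) if (kvr[ll][r] != 0.0) { seen = true; break; }
        if (!seen && r != a) touched.push_back(r);
        if (r != a) kvr[l][r] += e.second;
      }
    }
    double best = tol;
    int best_r = a;
    std::sort(touched.begin(), touched.end());
    for (int r : touched) {
      double d = 0.0;
      for (int l = 0; l < nl; ++l) {
        if (lw[l] == 0.0) continue;
        const Layer &L = layers[l];
        double dl = 2.0 * kvr[l][r];  // v is singleton: k_va = 0
        if (L.twom > 0) {
          double K = L.deg[v];
          dl += 2.0 * lres[l] * K * ((rtot[l][a] - K) - rtot[l][r]) / L.twom;
        }
        d += lw[l] * dl;
      }
      if (d > best + tol || (d > best - tol && best_r != a && r < best_r)) {
        best = d; best_r = r;
      }
    }
    if (best_r != a) {
      rsize[a]--; rsize[best_r]++;
      for (int l = 0; l < nl; ++l) {
        rtot[l][a] -= layers[l].deg[v];
        rtot[l][best_r] += layers[l].deg[v];
      }
      ref[v] = best_r;
    }
    for (int l = 0; l < nl; ++l)
      for (int r : touched) kvr[l][r] = 0.0;
  }
  return ref;
}

std::vector<Layer> aggregate(const std::vector<Layer> &layers,
                             const std::vector<int> &rmap, int nr) {
  std::vector<Layer> out(layers.size());
  for (size_t l = 0; l < layers.size(); ++l) {
    const Layer &L = layers[l];
    Layer &A = out[l];
    A.n = nr;
    A.adj.assign(nr, {});
    A.self.assign(nr, 0.0);
    std::vector<std::unordered_map<int, double>> acc(nr);
    for (int v = 0; v < L.n; ++v) {
      int rv = rmap[v];
      A.self[rv] += L.self[v];
      for (auto &e : L.adj[v]) {
        int ru = rmap[e.first];
        if (ru == rv) A.self[rv] += e.second;  // both directions accumulate
        else acc[rv][ru] += e.second;
      }
    }
    for (int r = 0; r < nr; ++r) {
      A.adj[r].reserve(acc[r].size());
      for (auto &kv : acc[r]) A.adj[r].emplace_back(kv.first, kv.second);
      std::sort(A.adj[r].begin(), A.adj[r].end());
    }
    A.finalize();
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
List leiden_multiplex_cpp(List layer_list, int n, NumericVector layer_weights,
                          NumericVector resolutions, int seed,
                          int max_passes = 100) {
  const int nl = layer_list.size();
  if (nl < 1) stop("at least one layer required");
  std::vector<Layer> layers(nl);
  for (int l = 0; l < nl; ++l) {
    List ll = layer_list[l];
    IntegerVector from = ll["from"], to = ll["to"];
    NumericVector w = ll["weight"];
    Layer &L = layers[l];
    L.n = n;
    L.adj.assign(n, {});
    L.self.assign(n, 0.0);
    for (int e = 0; e < from.size(); ++e) {
      int u = from[e], v = to[e];
      if (u < 0 || v < 0 || u >= n || v >= n) stop("edge endpoint out of range");
      if (u == v) L.self[u] += w[e];
      else {
        L.adj[u].emplace_back(v, w[e]);
        L.adj[v].emplace_back(u, w[e]);
      }
    }
    for (int v = 0; v < n; ++v) std::sort(L.adj[v].begin(), L.adj[v].end());
    L.finalize();
  }
  std::vector<double> lw(layer_weights.begin(), layer_weights.end());
  std::vector<double> lres(resolutions.begin(), resolutions.end());
  if ((int)lw.size() != nl || (int)lres.size() != nl)
    stop("layer_weights/resolutions length mismatch");

  Rng rng((uint64_t)(uint32_t)seed);

  std::vector<int> orig2node(n);
  for (int v = 0; v < n; ++v) orig2node[v] = v;
  std::vector<Layer> cur = layers;
  std::vector<int> comm(n);
  for (int v = 0; v < n; ++v) comm[v] = v;

  std::vector<double> trace;
  double q_prev = quality(cur, lw, lres, comm, cur[0].n);
  bool monotone = true;
  bool hit_max = true;
  int passes = 0;

  for (int pass = 0; pass < max_passes; ++pass) {
    passes = pass + 1;
    int moved = local_move(cur, lw, lres, comm, rng);
    double q = quality(cur, lw, lres, comm, cur[0].n);
    trace.push_back(q);
    if (q < q_prev - 1e-9 * (1.0 + std::abs(q_prev))) monotone = false;
    if (moved == 0 || q <= q_prev + 1e-12 * (1.0 + std::abs(q_prev))) {
      if (pass > 0 || moved == 0) { hit_max = false; break; }
    }
    q_prev = q;

    std::vector<int> ref = refine(cur, lw, lres, comm, rng);
    // renumber refined clusters contiguously
    std::vector<int> rmap(cur[0].n, -1);
    int nr = 0;
    for (int v = 0; v < cur[0].n; ++v)
      if (rmap[ref[v]] == -1) rmap[ref[v]] = nr++;
    std::vector<int> rlab(cur[0].n);
    for (int v = 0; v < cur[0].n; ++v) rlab[v] = rmap[ref[v]];
    if (nr == cur[0].n) { hit_max = false; break; }  // nothing to aggregate

    // seed aggregate nodes with their pre-refinement communities
    std::vector<int> agg_comm(nr, -1);
    for (int v = 0; v < cur[0].n; ++v) agg_comm[rlab[v]] = comm[v];
    // community ids must stay contiguous below the new node count
    {
      std::unordered_map<int, int> cmap;
      int kc = 0;
      for (int r = 0; r < nr; ++r) {
        auto it = cmap.find(agg_comm[r]);
        if (it == cmap.end()) { cmap[agg_comm[r]] = kc; agg_comm[r] = kc++; }
        else agg_comm[r] = it->second;
      }
    }
    cur = aggregate(cur, rlab, nr);
    comm = agg_comm;
    for (int v = 0; v < n; ++v) orig2node[v] = rlab[orig2node[v]];
  }
  if (hit_max)
    Rcpp::warning("max_passes = %d reached before convergence", max_passes);

  // flatten and renumber 0..k-1 by first appearance
  IntegerVector membership(n);
  std::unordered_map<int, int> seen;
  int k = 0;
  for (int v = 0; v < n; ++v) {
    int c = comm[orig2node[v]];
    auto it = seen.find(c);
    if (it == seen.end()) { seen[c] = k; membership[v] = k; ++k; }
    else membership[v] = it->second;
  }
  std::vector<int> flat(n);
  for (int v = 0; v < n; ++v) flat[v] = membership[v];
  double q_final = quality(layers, lw, lres, flat, k);

  return List::create(_["membership"] = membership,
                      _["n_clusters"] = k,
                      _["quality"] = q_final,
                      _["quality_trace"] = NumericVector(trace.begin(), trace.end()),
                      _["passes"] = passes,
                      _["monotone"] = monotone);
}
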