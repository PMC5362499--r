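// Prize-collecting Steiner subgraph search.
//
// Two independent code paths:
//  * pcst_enumerate_cpp  — exhaustive oracle: enumerates every non-empty
//    connected node subset (bitmask, <= 20 nodes) and minimizes
//    sum(edge costs of the subset MST) - sum(node prizes).
//  * pcst_local_search_cpp — scalable heuristic: strong-pruned-MST and
//    whole-component starts refined by steepest-descent local search with
//    remove / cheapest-path-add moves.
//
// Both report the minimizing node set; ties broken by fewer nodes, then
// lexicographically smallest sorted index sequence.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
#include <cmath>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
static const double TOL = 1e-11;

// lexicographic order of the sorted index sequences of two equally sized
// sets: at the lowest index where membership differs, the set holding it
// comes first.
static bool lex_less(const std::vector<bool> &a, const std::vector<bool> &b) {
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i] != b[i]) return a[i];
  }
  return false;
}

static int popcount_vec(const std::vector<bool> &a) {
  int c = 0;
  for (bool x : a) c += x;
  return c;
}

// Prim MST cost over the nodes flagged in `in`, using dense costs; INF if
// the induced subgraph is disconnected.
static double induced_mst_cost(const std::vector<bool> &in,
                               const std::vector<std::vector<double>> &cost) {
  int n = in.size();
  std::vector<int> nodes;
  for (int i = 0; i < n; ++i) if (in[i]) nodes.push_back(i);
  int k = nodes.size();
  if (k == 0) return INF;
  if (k == 1) return 0.0;
  std::vector<double> key(k, INF);
  std::vector<bool> used(k, false);
  key[0] = 0.0;
  double total = 0.0;
  for (int it = 0; it < k; ++it) {
    int best = -1;
    double bk = INF;
    for (int i = 0; i < k; ++i)
      if (!used[i] && key[i] < bk) { bk = key[i]; best = i; }
    if (best < 0) return INF;
    used[best] = true;
    total += key[best];
    for (int i = 0; i < k; ++i) {
      if (used[i]) continue;
      double c = cost[nodes[best]][nodes[i]];
      if (c < key[i]) key[i] = c;
    }
  }
  return total;
}

static double objective_of(const std::vector<bool> &in,
                           const std::vector<std::vector<double>> &cost,
                           const NumericVector &prizes) {
  double mst = induced_mst_cost(in, cost);
  if (!std::isfinite(mst)) return INF;
  double p = 0.0;
  for (size_t i = 0; i < in.size(); ++i) if (in[i]) p += prizes[i];
  return mst - p;
}

static std::vector<std::vector<double>> dense_costs(int n,
                                                    const IntegerMatrix &edges,
                                                    const NumericVector &costs) {
  std::vector<std::vector<double>> cost(n, std::vector<double>(n, INF));
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    double c = costs[e];
    if (c < cost[a][b]) { cost[a][b] = c; cost[b][a] = c; }
  }
  return cost;
}

// ---------------------------------------------------------------- oracle

// [[Rcpp::export]]
List pcst_enumerate_cpp(int n, IntegerMatrix edges, NumericVector costs,
                        NumericVector prizes) {
  if (n > 20) stop("exact enumeration limited to 20 nodes");
  std::vector<std::vector<double>> cost = dense_costs(n, edges, costs);
  std::vector<unsigned int> adj(n, 0u);
  for (int e = 0; e < edges.nrow(); ++e) {
    adj[edges(e, 0)] |= 1u << edges(e, 1);
    adj[edges(e, 1)] |= 1u << edges(e, 0);
  }

  double best_obj = INF;
  std::vector<bool> best_set;
  unsigned int full = (n >= 32) ? 0u : ((1u << n) - 1u);
  for (unsigned int mask = 1; mask <= full; ++mask) {
    // connectivity by bitmask expansion from the lowest member
    unsigned int reach = mask & (~mask + 1u);
    for (;;) {
      unsigned int nxt = reach, m = reach;
      while (m) {
        int v = __builtin_ctz(m);
        m &= m - 1u;
        nxt |= adj[v] & mask;
      }
      if (nxt == reach) break;
      reach = nxt;
    }
    if (reach != mask) continue;

    std::vector<bool> in(n, false);
    for (int i = 0; i < n; ++i) if (mask & (1u << i)) in[i] = true;
    double obj = objective_of(in, cost, prizes);
    if (!std::isfinite(obj)) continue;
    bool take = false;
    if (obj < best_obj - TOL) {
      take = true;
    } else if (obj <= best_obj + TOL && !best_set.empty()) {
      int sz = popcount_vec(in), bsz = popcount_vec(best_set);
      if (sz < bsz || (sz == bsz && lex_less(in, best_set))) take = true;
    }
    if (take) { best_obj = obj; best_set = in; }
  }

  IntegerVector nodes;
  for (int i = 0; i < n; ++i)
    if (!best_set.empty() && best_set[i]) nodes.push_back(i + 1);
  return List::create(_["nodes"] = nodes, _["objective"] = best_obj);
}

// ------------------------------------------------------------- heuristic

struct Tree {
  std::vector<std::vector<int>> kids;
  std::vector<int> parent;
};

// deterministic Prim MST over one component, returning the rooted tree
static Tree component_mst(const std::vector<int> &comp,
                          const std::vector<std::vector<double>> &cost,
                          int n) {
  Tree t;
  t.kids.assign(n, {});
  t.parent.assign(n, -1);
  int k = comp.size();
  std::vector<double> key(k, INF);
  std::vector<int> from(k, -1);
  std::vector<bool> used(k, false);
  key[0] = 0.0;
  for (int it = 0; it < k; ++it) {
    int best = -1;
    double bk = INF;
    for (int i = 0; i < k; ++i)
      if (!used[i] && key[i] < bk) { bk = key[i]; best = i; }
    if (best < 0) break;
    used[best] = true;
    if (from[best] >= 0) {
      t.parent[comp[best]] = comp[from[best]];
      t.kids[comp[from[best]]].push_back(comp[best]);
    }
    for (int i = 0; i < k; ++i) {
      if (used[i]) continue;
      double c = cost[comp[best]][comp[i]];
      if (c < key[i]) { key[i] = c; from[i] = best; }
    }
  }
  return t;
}

// strong pruning rooted at r: net value of each subtree, keep positive ones
static double strong_prune(int r, const Tree &t,
                           const std::vector<std::vector<double>> &cost,
                           const NumericVector &prizes,
                           std::vector<double> &net) {
  double v = prizes[r];
  for (int c : t.kids[r]) {
    double nc = strong_prune(c, t, cost, prizes, net);
    double gain = nc - cost[r][c];
    if (gain > 0) v += gain;
  }
  net[r] = v;
  return v;
}

static void prune_collect(int r, const Tree &t,
                          const std::vector<std::vector<double>> &cost,
                          const std::vector<double> &net,
                          std::vector<bool> &keep) {
  keep[r] = true;
  for (int c : t.kids[r]) {
    if (net[c] - cost[r][c] > 0) prune_collect(c, t, cost, net, keep);
  }
}

static bool still_connected(const std::vector<bool> &in, int drop,
                            const std::vector<std::vector<int>> &adjlist) {
  int n = in.size();
  int start = -1, want = 0;
  for (int i = 0; i < n; ++i)
    if (in[i] && i != drop) { if (start < 0) start = i; ++want; }
  if (want == 0) return false;
  std::vector<bool> seen(n, false);
  std::queue<int> q;
  q.push(start);
  seen[start] = true;
  int got = 1;
  while (!q.empty()) {
    int v = q.front(); q.pop();
    for (int u : adjlist[v]) {
      if (u == drop || !in[u] || seen[u]) continue;
      seen[u] = true; ++got;
      q.push(u);
    }
  }
  return got == want;
}

// steepest-descent local search from a start set within one component
static void local_search(std::vector<bool> &in,
                         const std::vector<int> &comp,
                         const std::vector<std::vector<double>> &cost,
                         const std::vector<std::vector<int>> &adjlist,
                         const NumericVector &prizes) {
  int n = in.size();
  std::vector<bool> incomp(n, false);
  for (int v : comp) incomp[v] = true;
  double f = objective_of(in, cost, prizes);

  for (int guard = 0; guard < 10000; ++guard) {
    double best_f = f;
    std::vector<bool> best_set;

    // removals
    for (int v : comp) {
      if (!in[v]) continue;
      if (popcount_vec(in) == 1) continue;
      if (!still_connected(in, v, adjlist)) continue;
      std::vector<bool> cand = in;
      cand[v] = false;
      double fc = objective_of(cand, cost, prizes);
      if (fc < best_f - TOL) { best_f = fc; best_set = cand; }
    }

    // cheapest-path additions: multi-source Dijkstra from the current set
    std::vector<double> dist(n, INF);
    std::vector<int> pred(n, -1);
    typedef std::pair<double, int> DI;
    std::priority_queue<DI, std::vector<DI>, std::greater<DI>> pq;
    for (int v : comp) if (in[v]) { dist[v] = 0.0; pq.push({0.0, v}); }
    while (!pq.empty()) {
      DI top = pq.top(); pq.pop();
      if (top.first > dist[top.second] + TOL) continue;
      int v = top.second;
      for (int u : adjlist[v]) {
        double c = cost[v][u];
        if (c < 0) c = 0;
        if (dist[v] + c < dist[u] - TOL) {
          dist[u] = dist[v] + c;
          pred[u] = v;
          pq.push({dist[u], u});
        }
      }
    }
    for (int v : comp) {
      if (in[v] || !std::isfinite(dist[v])) continue;
      std::vector<bool> cand = in;
      for (int u = v; u >= 0 && !cand[u]; u = pred[u]) cand[u] = true;
      double fc = objective_of(cand, cost, prizes);
      if (fc < best_f - TOL) { best_f = fc; best_set = cand; }
    }

    if (best_set.empty()) break;
    in = best_set;
    f = best_f;
  }

  // equal-objective shrink: prefer fewer nodes at the same objective
  bool changed = true;
  while (changed) {
    changed = false;
    for (int v : comp) {
      if (!in[v] || popcount_vec(in) == 1) continue;
      if (!still_connected(in, v, adjlist)) continue;
      std::vector<bool> cand = in;
      cand[v] = false;
      double fc = objective_of(cand, cost, prizes);
      if (fc <= f + TOL) { in = cand; f = fc; changed = true; }
    }
  }
}

// [[Rcpp::export]]
List pcst_local_search_cpp(int n, IntegerMatrix edges, NumericVector costs,
                           NumericVector prizes) {
  std::vector<std::vector<double>> cost = dense_costs(n, edges, costs);
  std::vector<std::vector<int>> adjlist(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    adjlist[edges(e, 0)].push_back(edges(e, 1));
    adjlist[edges(e, 1)].push_back(edges(e, 0));
  }
  // components
  std::vector<int> comp_id(n, -1);
  int ncomp = 0;
  for (int s = 0; s < n; ++s) {
    if (comp_id[s] >= 0) continue;
    std::queue<int> q;
    q.push(s);
    comp_id[s] = ncomp;
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (int u : adjlist[v])
        if (comp_id[u] < 0) { comp_id[u] = ncomp; q.push(u); }
    }
    ++ncomp;
  }

  double best_obj = INF;
  std::vector<bool> best_set;
  for (int c = 0; c < ncomp; ++c) {
    std::vector<int> comp;
    for (int i = 0; i < n; ++i) if (comp_id[i] == c) comp.push_back(i);

    std::vector<std::vector<bool>> starts;
    // whole component
    std::vector<bool> full(n, false);
    for (int v : comp) full[v] = true;
    starts.push_back(full);
    // strong-pruned MST, best root
    if (comp.size() > 1) {
      Tree t = component_mst(comp, cost, n);
      int root = comp[0];
      for (int v : comp) if (t.parent[v] < 0) root = v;
      // reroot at every node is costly on big graphs; prune from the MST
      // root and from the max-prize node by rebuilding the tree rooted there
      std::vector<int> roots = {root};
      int pmax = comp[0];
      for (int v : comp) if (prizes[v] > prizes[pmax]) pmax = v;
      if (pmax != root) roots.push_back(pmax);
      for (int r : roots) {
        // orient tree at r
        Tree tr;
        tr.kids.assign(n, {});
        tr.parent.assign(n, -1);
        std::vector<bool> seen(n, false);
        std::queue<int> q;
        q.push(r);
        seen[r] = true;
        std::vector<std::vector<int>> und(n);
        for (int v : comp) {
          if (t.parent[v] >= 0) {
            und[v].push_back(t.parent[v]);
            und[t.parent[v]].push_back(v);
          }
        }
        while (!q.empty()) {
          int v = q.front(); q.pop();
          for (int u : und[v]) {
            if (seen[u]) continue;
            seen[u] = true;
            tr.parent[u] = v;
            tr.kids[v].push_back(u);
            q.push(u);
          }
        }
        std::vector<double> net(n, 0.0);
        strong_prune(r, tr, cost, prizes, net);
        std::vector<bool> keep(n, false);
        prune_collect(r, tr, cost, net, keep);
        starts.push_back(keep);
      }
    }
    // best single node
    int pmax = comp[0];
    for (int v : comp) if (prizes[v] > prizes[pmax]) pmax = v;
    std::vector<bool> single(n, false);
    single[pmax] = true;
    starts.push_back(single);

    for (std::vector<bool> &s : starts) {
      local_search(s, comp, cost, adjlist, prizes);
      double obj = objective_of(s, cost, prizes);
      bool take = false;
      if (obj < best_obj - TOL) {
        take = true;
      } else if (obj <= best_obj + TOL && !best_set.empty()) {
        int sz = popcount_vec(s), bsz = popcount_vec(best_set);
        if (sz < bsz || (sz == bsz && lex_less(s, best_set))) take = true;
      }
      if (take) { best_obj = obj; best_set = s; }
    }
  }

  IntegerVector nodes;
  for (int i = 0; i < n; ++i)
    if (!best_set.empty() && best_set[i]) nodes.push_back(i + 1);
  return List::create(_["nodes"] = nodes, _["objective"] = best_obj);
}
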