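#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// (6,6) body-bar pebble game.
//
// Each body starts with 6 pebbles. A bar of multiplicity m is inserted as m
// edge copies; a copy is independent iff 7 pebbles can be gathered on its
// endpoints (6 reserved for the trivial rigid-body motions of the pair), in
// which case one pebble is consumed and the copy is oriented away from the
// paying endpoint. Pebble searches are DFS with path reversal.
//
// Rigid clusters: co-rigidity of two bodies is equivalent to the failure of a
// 7-pebble gather on the pair, and in 3D body-bar frameworks co-rigidity is an
// equivalence relation whose classes are connected through bars. The
// decomposition therefore tests bar-adjacent pairs with union-find; on a
// failed gather the whole reach set of the search (which provably carries
// 6|D|-6 independent arcs, hence is rigid) is united in one step.

struct Game {
  int n;
  std::vector<int> peb;
  std::vector<std::vector<std::pair<int, int> > > out; // (to, count)
  std::vector<int> visited, parent, order, stack_;
  int stamp;

  Game(int n_) : n(n_), peb(n_, 6), out(n_), visited(n_, 0), parent(n_, -1),
                 stamp(0) {}

  int &countRef(int u, int v) {
    for (size_t i = 0; i < out[u].size(); ++i)
      if (out[u][i].first == v) return out[u][i].second;
    out[u].push_back(std::make_pair(v, 0));
    return out[u].back().second;
  }

  // DFS from root, never taking pebbles from root or `avoid`, and not
  // traversing `avoid`. On success moves one free pebble to root.
  bool findPebble(int root, int avoid) {
    ++stamp;
    visited[root] = stamp;
    if (avoid >= 0) visited[avoid] = stamp;
    parent[root] = -1;
    stack_.clear();
    stack_.push_back(root);
    while (!stack_.empty()) {
      int u = stack_.back();
      stack_.pop_back();
      for (size_t i = 0; i < out[u].size(); ++i) {
        if (out[u][i].second <= 0) continue;
        int v = out[u][i].first;
        if (visited[v] == stamp) continue;
        visited[v] = stamp;
        parent[v] = u;
        if (peb[v] > 0) {
          // reverse the path root -> ... -> v
          int x = v;
          while (parent[x] != -1) {
            int p = parent[x];
            countRef(p, x)--;
            countRef(x, p)++;
            x = p;
          }
          peb[v]--;
          peb[root]++;
          return true;
        }
        stack_.push_back(v);
      }
    }
    return false;
  }

  // try to gather 7 pebbles on {a, b}; pebble moves persist either way
  bool canGatherSeven(int a, int b) {
    while (peb[a] + peb[b] < 7) {
      bool got = findPebble(a, b);
      if (!got) got = findPebble(b, a);
      if (!got) return false;
    }
    return true;
  }

  // vertices reachable from a or b along directed arcs (inclusive)
  void reach(int a, int b, std::vector<int> &res) {
    ++stamp;
    res.clear();
    stack_.clear();
    visited[a] = stamp; res.push_back(a); stack_.push_back(a);
    if (visited[b] != stamp) { visited[b] = stamp; res.push_back(b); stack_.push_back(b); }
    while (!stack_.empty()) {
      int u = stack_.back();
      stack_.pop_back();
      for (size_t i = 0; i < out[u].size(); ++i) {
        if (out[u][i].second <= 0) continue;
        int v = out[u][i].first;
        if (visited[v] == stamp) continue;
        visited[v] = stamp;
        res.push_back(v);
        stack_.push_back(v);
      }
    }
  }
};

struct UF {
  std::vector<int> p;
  UF(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[b] = a; }
};

// [[Rcpp::export(name = ".pebbleGameCpp")]]
List pebbleGameCpp(int n, IntegerVector a, IntegerVector b,
                   IntegerVector mult) {
  int m = a.size();
  Game g(n);
  UF conn(n);   // connectivity over all bars
  int rank = 0;

  for (int e = 0; e < m; ++e) {
    int u = a[e] - 1, v = b[e] - 1;
    if (u == v) stop("self-loop bar");
    conn.unite(u, v);
    for (int c = 0; c < mult[e]; ++c) {
      if (g.canGatherSeven(u, v)) {
        if (g.peb[u] > 0) { g.peb[u]--; g.countRef(u, v)++; }
        else              { g.peb[v]--; g.countRef(v, u)++; }
        ++rank;
      }
      // redundant copies are dropped (they add no constraint)
    }
  }

  // rigid clusters over bar-adjacent pairs
  UF clus(n);
  std::vector<int> D;
  for (int e = 0; e < m; ++e) {
    int u = a[e] - 1, v = b[e] - 1;
    if (clus.find(u) == clus.find(v)) continue;
    if (!g.canGatherSeven(u, v)) {
      g.reach(u, v, D);
      for (size_t i = 1; i < D.size(); ++i) clus.unite(D[0], D[i]);
    }
  }

  // canonical contiguous cluster ids, ordered by lowest member index
  IntegerVector clusterOf(n);
  std::vector<int> label(n, 0);
  int nclus = 0;
  for (int i = 0; i < n; ++i) {
    int r = clus.find(i);
    if (label[r] == 0) label[r] = ++nclus;
    clusterOf[i] = label[r];
  }

  int ncomp = 0;
  for (int i = 0; i < n; ++i) if (conn.find(i) == i) ++ncomp;
  int floppy = 6 * n - 6 * ncomp - rank;

  return List::create(_["clusterOf"] = clusterOf,
                      _["nClusters"] = nclus,
                      _["floppyModes"] = floppy,
                      _["rank"] = rank,
                      _["nComponents"] = ncomp);
}
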