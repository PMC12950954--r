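// Exact maximum-clique search over the modular product of two molecular
// graphs. Two modes:
//  * connected (default): a c-clique branch-and-bound in the spirit of
//    Koch's algorithm for connected common subgraphs; candidates are split
//    into P (joined to the growing clique through at least one strong,
//    i.e. bonded-bonded, edge) and D (compatible but not yet connected),
//    and D-vertices migrate into P as strong neighbours are added.
//  * unconstrained: Bron-Kerbosch with pivoting.
// Both prune on |C| + |candidates| against the best size found so far and
// collect all co-optimal cliques (up to a cap) in lexicographic order.

#include <Rcpp.h>
#include <cstdint>
#include <set>
#include <vector>

namespace {

typedef std::vector<uint64_t> Bits;

inline bool bget(const Bits& b, int i) { return (b[i >> 6] >> (i & 63)) & 1ULL; }
inline void bset(Bits& b, int i) { b[i >> 6] |= 1ULL << (i & 63); }
inline void bclear(Bits& b, int i) { b[i >> 6] &= ~(1ULL << (i & 63)); }
inline int bcount(const Bits& b) {
  int c = 0;
  for (uint64_t w : b) c += __builtin_popcountll(w);
  return c;
}
inline bool bempty(const Bits& b) {
  for (uint64_t w : b)
    if (w) return false;
  return true;
}

struct Search {
  int n, nw;
  std::vector<Bits> adj;   // all compatibility edges
  std::vector<Bits> conn;  // strong (bonded-bonded) edges
  int best = 0;
  size_t cap;
  unsigned long long nodes = 0, node_limit;
  bool truncated = false, limit_hit = false;
  std::set<std::vector<int> > sols;

  void record(const std::vector<int>& C) {
    int sz = (int)C.size();
    if (sz < best) return;
    if (sz > best) {
      best = sz;
      sols.clear();
      truncated = false;
    }
    std::vector<int> s(C);
    std::sort(s.begin(), s.end());
    if (sols.size() < cap)
      sols.insert(s);
    else if (!sols.count(s))
      truncated = true;
  }

  // ---- connected mode -------------------------------------------------
  void koch(std::vector<int>& C, const Bits& P, const Bits& D, const Bits& X) {
    if (limit_hit || ++nodes > node_limit) {
      limit_hit = true;
      return;
    }
    int pc = bcount(P), dc = bcount(D);
    if ((int)C.size() + pc + dc < best) return;
    if (pc == 0) {
      if (bempty(X)) record(C);
      return;
    }
    Bits P2(nw), D2(nw), X2(nw), Pw(P), Xw(X);
    for (int v = 0; v < n; ++v) {
      if (!bget(Pw, v)) continue;
      bclear(Pw, v);
      for (int w = 0; w < nw; ++w) {
        uint64_t av = adj[v][w], cv = conn[v][w];
        P2[w] = (Pw[w] & av) | (D[w] & av & cv);
        D2[w] = D[w] & av & ~cv;
        X2[w] = (Xw[w] & av) | /* S not tracked: X holds both kinds */ 0ULL;
      }
      C.push_back(v);
      koch(C, P2, D2, X2);
      C.pop_back();
      if (limit_hit) return;
      bset(Xw, v);
    }
  }

  // ---- unconstrained Bron-Kerbosch with pivot -------------------------
  void bk(std::vector<int>& C, const Bits& P, const Bits& X) {
    if (limit_hit || ++nodes > node_limit) {
      limit_hit = true;
      return;
    }
    int pc = bcount(P);
    if ((int)C.size() + pc < best) return;
    if (pc == 0) {
      if (bempty(X)) record(C);
      return;
    }
    int pivot = -1, bestdeg = -1;
    for (int u = 0; u < n; ++u) {
      if (!bget(P, u) && !bget(X, u)) continue;
      int d = 0;
      for (int w = 0; w < nw; ++w) d += __builtin_popcountll(P[w] & adj[u][w]);
      if (d > bestdeg) {
        bestdeg = d;
        pivot = u;
      }
    }
    Bits Pw(P), Xw(X), P2(nw), X2(nw);
    for (int v = 0; v < n; ++v) {
      if (!bget(Pw, v) || bget(adj[pivot], v)) continue;
      for (int w = 0; w < nw; ++w) {
        P2[w] = Pw[w] & adj[v][w];
        X2[w] = Xw[w] & adj[v][w];
      }
      C.push_back(v);
      bclear(Pw, v);
      bk(C, P2, X2);
      C.pop_back();
      if (limit_hit) return;
      bset(Xw, v);
    }
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List clique_search_cpp(Rcpp::LogicalMatrix adjacency,
                             Rcpp::LogicalMatrix strong, bool connected,
                             int cap, double node_limit) {
  Search s;
  s.n = adjacency.nrow();
  s.nw = (s.n + 63) / 64;
  s.cap = cap > 0 ? (size_t)cap : 1;
  s.node_limit = (unsigned long long)node_limit;
  s.adj.assign(s.n, Bits(s.nw, 0));
  s.conn.assign(s.n, Bits(s.nw, 0));
  for (int i = 0; i < s.n; ++i)
    for (int j = 0; j < s.n; ++j) {
      if (adjacency(i, j)) bset(s.adj[i], j);
      if (strong(i, j)) bset(s.conn[i], j);
    }

  std::vector<int> C;
  if (connected) {
    Bits T(s.nw, 0);
    for (int u = 0; u < s.n && !s.limit_hit; ++u) {
      Bits P(s.nw), D(s.nw), X(s.nw);
      for (int w = 0; w < s.nw; ++w) {
        P[w] = s.conn[u][w] & ~T[w];
        D[w] = s.adj[u][w] & ~s.conn[u][w] & ~T[w];
        X[w] = s.conn[u][w] & T[w];
      }
      C.assign(1, u);
      s.koch(C, P, D, X);
      bset(T, u);
    }
  } else {
    Bits P(s.nw, 0), X(s.nw, 0);
    for (int u = 0; u < s.n; ++u) bset(P, u);
    C.clear();
    s.bk(C, P, X);
  }

  Rcpp::List cliques(s.sols.size());
  int k = 0;
  for (std::set<std::vector<int> >::const_iterator it = s.sols.begin();
       it != s.sols.end(); ++it) {
    Rcpp::IntegerVector v(it->size());
    for (size_t q = 0; q < it->size(); ++q) v[q] = (*it)[q] + 1;  // 1-based
    cliques[k++] = v;
  }
  return Rcpp::List::create(Rcpp::Named("size") = s.best,
                            Rcpp::Named("cliques") = cliques,
                            Rcpp::Named("truncated") = s.truncated,
                            Rcpp::Named("limit_hit") = s.limit_hit);
}
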