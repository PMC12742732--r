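#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Vietoris-Rips persistent homology over Z/2 by boundary-matrix reduction
// with the clearing (twist) optimisation.  Simplices enter the filtration at
// their diameter (max pairwise distance); the complex is capped at
// max_radius.  H0 is computed by union-find over the sorted edge list (its
// finite deaths are exactly the MST edge lengths); H1/H2 come from reducing
// the dim-2 and dim-3 boundary matrices.

namespace {

struct UnionFind {
  std::vector<int> parent;
  UnionFind(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    parent[b] = a;
    return true;
  }
};

typedef std::vector<int> Column;

// XOR two sorted columns (symmetric difference).
Column col_xor(const Column &a, const Column &b) {
  Column out;
  out.reserve(a.size() + b.size());
  std::set_symmetric_difference(a.begin(), a.end(), b.begin(), b.end(),
                                std::back_inserter(out));
  return out;
}

// Reduce boundary columns (sorted by filtration).  Returns for each column
// its pivot row (-1 if reduced to zero).  pivot_of[row] = column index.
void reduce_columns(std::vector<Column> &cols, std::vector<int> &pivot_row,
                    std::vector<int> &pivot_of, int n_rows) {
  pivot_of.assign(n_rows, -1);
  pivot_row.assign(cols.size(), -1);
  for (size_t j = 0; j < cols.size(); ++j) {
    Column &c = cols[j];
    while (!c.empty()) {
      int piv = c.back();
      int other = pivot_of[piv];
      if (other < 0) break;
      c = col_xor(c, cols[other]);
    }
    if (!c.empty()) {
      pivot_row[j] = c.back();
      pivot_of[c.back()] = (int)j;
    }
  }
}

struct Simplex {
  double diam;
  int v[4];  // vertex ids, ascending; unused slots -1
};

bool simplex_less(const Simplex &a, const Simplex &b) {
  if (a.diam != b.diam) return a.diam < b.diam;
  if (a.v[0] != b.v[0]) return a.v[0] < b.v[0];
  if (a.v[1] != b.v[1]) return a.v[1] < b.v[1];
  if (a.v[2] != b.v[2]) return a.v[2] < b.v[2];
  return a.v[3] < b.v[3];
}

// adjacency bitset intersection helpers
typedef std::vector<uint64_t> Bits;
inline bool bit_get(const Bits &b, int i) { return (b[i >> 6] >> (i & 63)) & 1ULL; }
inline void bit_set(Bits &b, int i) { b[i >> 6] |= (1ULL << (i & 63)); }

}  // namespace

// Enumerate simplices of the Rips complex up to dimension max_simplex_dim
// (0=vertices,...,3=tetrahedra) with diameter <= radius.
static void enumerate_simplices(const NumericMatrix &d, double radius,
                                int max_simplex_dim,
                                std::vector<Simplex> &edges,
                                std::vector<Simplex> &tris,
                                std::vector<Simplex> &tets) {
  const int n = d.nrow();
  const int words = (n + 63) / 64;
  std::vector<Bits> adj(n, Bits(words, 0));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (d(i, j) <= radius) {
        bit_set(adj[i], j);
        bit_set(adj[j], i);
        Simplex s; s.diam = d(i, j); s.v[0] = i; s.v[1] = j; s.v[2] = -1; s.v[3] = -1;
        edges.push_back(s);
      }
  if (max_simplex_dim < 2) return;
  Bits common(words), common2(words);
  for (size_t e = 0; e < edges.size(); ++e) {
    int i = edges[e].v[0], j = edges[e].v[1];
    for (int w = 0; w < words; ++w) common[w] = adj[i][w] & adj[j][w];
    for (int k = j + 1; k < n; ++k) {
      if (!bit_get(common, k)) continue;
      double diam3 = std::max(edges[e].diam, std::max(d(i, k), d(j, k)));
      Simplex t; t.diam = diam3; t.v[0] = i; t.v[1] = j; t.v[2] = k; t.v[3] = -1;
      tris.push_back(t);
      if (max_simplex_dim < 3) continue;
      for (int w = 0; w < words; ++w) common2[w] = common[w] & adj[k][w];
      for (int l = k + 1; l < n; ++l) {
        if (!bit_get(common2, l)) continue;
        double diam4 = std::max(diam3, std::max(d(i, l), std::max(d(j, l), d(k, l))));
        Simplex q; q.diam = diam4; q.v[0] = i; q.v[1] = j; q.v[2] = k; q.v[3] = l;
        tets.push_back(q);
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_rips_persistence(NumericMatrix dist, int max_dim, double max_radius) {
  const int n = dist.nrow();
  if (n < 1) stop("empty point cloud");
  if (max_dim < 0 || max_dim > 2) stop("max_dim must be 0, 1 or 2");
  std::vector<Simplex> edges, tris, tets;
  enumerate_simplices(dist, max_radius, max_dim + 1, edges, tris, tets);
  std::stable_sort(edges.begin(), edges.end(), simplex_less);
  std::stable_sort(tris.begin(), tris.end(), simplex_less);
  std::stable_sort(tets.begin(), tets.end(), simplex_less);

  // --- H0 via union-find; positive edges create 1-cycles ---
  std::vector<double> h0_death;
  std::vector<char> edge_positive(edges.size(), 0);
  {
    UnionFind uf(n);
    for (size_t e = 0; e < edges.size(); ++e) {
      if (uf.unite(edges[e].v[0], edges[e].v[1])) h0_death.push_back(edges[e].diam);
      else edge_positive[e] = 1;
    }
  }
  int n_components = n - (int)h0_death.size();

  std::vector<double> h1_birth, h1_death, h2_birth, h2_death;

  if (max_dim >= 1 && !tris.empty()) {
    // ranks: edge key -> sorted index
    std::vector<std::pair<uint64_t, int> > ekey(edges.size());
    for (size_t e = 0; e < edges.size(); ++e)
      ekey[e] = std::make_pair((uint64_t)edges[e].v[0] * n + edges[e].v[1], (int)e);
    std::sort(ekey.begin(), ekey.end());
    std::vector<uint64_t> ek(edges.size());
    std::vector<int> ev(edges.size());
    for (size_t e = 0; e < edges.size(); ++e) { ek[e] = ekey[e].first; ev[e] = ekey[e].second; }
    auto edge_rank = [&](int a, int b) {
      uint64_t key = (uint64_t)a * n + b;
      size_t lo = std::lower_bound(ek.begin(), ek.end(), key) - ek.begin();
      return ev[lo];
    };

    // clearing: reduce dim-3 boundary first (only needed for H2)
    std::vector<char> tri_cleared(tris.size(), 0);
    std::vector<double> tri_pair_death(tris.size(), -1.0);
    if (max_dim >= 2 && !tets.empty()) {
      std::vector<std::pair<uint64_t, int> > tkey(tris.size());
      const uint64_t N = (uint64_t)n;
      for (size_t t = 0; t < tris.size(); ++t)
        tkey[t] = std::make_pair(((uint64_t)tris[t].v[0] * N + tris[t].v[1]) * N + tris[t].v[2], (int)t);
      std::sort(tkey.begin(), tkey.end());
      std::vector<uint64_t> tk(tris.size());
      std::vector<int> tv(tris.size());
      for (size_t t = 0; t < tris.size(); ++t) { tk[t] = tkey[t].first; tv[t] = tkey[t].second; }
      auto tri_rank = [&](int a, int b, int c) {
        uint64_t key = ((uint64_t)a * N + b) * N + c;
        size_t lo = std::lower_bound(tk.begin(), tk.end(), key) - tk.begin();
        return tv[lo];
      };
      std::vector<Column> cols(tets.size());
      for (size_t q = 0; q < tets.size(); ++q) {
        int a = tets[q].v[0], b = tets[q].v[1], c = tets[q].v[2], e = tets[q].v[3];
        Column col;
        col.push_back(tri_rank(b, c, e));
        col.push_back(tri_rank(a, c, e));
        col.push_back(tri_rank(a, b, e));
        col.push_back(tri_rank(a, b, c));
        std::sort(col.begin(), col.end());
        cols[q] = col;
      }
      std::vector<int> pivot_row, pivot_of;
      reduce_columns(cols, pivot_row, pivot_of, (int)tris.size());
      for (size_t q = 0; q < tets.size(); ++q) {
        if (pivot_row[q] >= 0) {
          int t = pivot_row[q];
          tri_cleared[t] = 1;                 // pivot triangle is positive & paired
          tri_pair_death[t] = tets[q].diam;
        }
      }
    }

    // reduce dim-2 boundary (H1 pairs; positive triangles for essential H2)
    std::vector<Column> cols;
    std::vector<int> col_tri;
    cols.reserve(tris.size());
    for (size_t t = 0; t < tris.size(); ++t) {
      if (tri_cleared[t]) continue;
      int a = tris[t].v[0], b = tris[t].v[1], c = tris[t].v[2];
      Column col;
      col.push_back(edge_rank(b, c));
      col.push_back(edge_rank(a, c));
      col.push_back(edge_rank(a, b));
      std::sort(col.begin(), col.end());
      cols.push_back(col);
      col_tri.push_back((int)t);
    }
    std::vector<int> pivot_row, pivot_of;
    reduce_columns(cols, pivot_row, pivot_of, (int)edges.size());
    std::vector<char> edge_paired(edges.size(), 0);
    for (size_t j = 0; j < cols.size(); ++j) {
      int t = col_tri[j];
      if (pivot_row[j] >= 0) {
        int e = pivot_row[j];
        edge_paired[e] = 1;
        if (tris[t].diam > edges[e].diam) {
          h1_birth.push_back(edges[e].diam);
          h1_death.push_back(tris[t].diam);
        }
      } else if (max_dim >= 2) {
        // positive triangle, unpaired by any tetrahedron -> essential H2
        h2_birth.push_back(tris[t].diam);
        h2_death.push_back(R_PosInf);
      }
    }
    // cleared triangles carry the H2 finite pairs
    if (max_dim >= 2) {
      for (size_t t = 0; t < tris.size(); ++t)
        if (tri_cleared[t] && tri_pair_death[t] > tris[t].diam) {
          h2_birth.push_back(tris[t].diam);
          h2_death.push_back(tri_pair_death[t]);
        }
    }
    // essential H1: positive edges never a dim-2 pivot
    for (size_t e = 0; e < edges.size(); ++e)
      if (edge_positive[e] && !edge_paired[e]) {
        h1_birth.push_back(edges[e].diam);
        h1_death.push_back(R_PosInf);
      }
  } else if (max_dim >= 1) {
    // no triangles: every positive edge is an essential 1-cycle
    for (size_t e = 0; e < edges.size(); ++e)
      if (edge_positive[e]) {
        h1_birth.push_back(edges[e].diam);
        h1_death.push_back(R_PosInf);
      }
  }

  int n0 = (int)h0_death.size() + n_components;
  NumericMatrix d0(n0, 2);
  for (size_t i = 0; i < h0_death.size(); ++i) { d0(i, 0) = 0.0; d0(i, 1) = h0_death[i]; }
  for (int i = 0; i < n_components; ++i) {
    d0(h0_death.size() + i, 0) = 0.0;
    d0(h0_death.size() + i, 1) = R_PosInf;
  }
  NumericMatrix d1(h1_birth.size(), 2), d2(h2_birth.size(), 2);
  for (size_t i = 0; i < h1_birth.size(); ++i) { d1(i, 0) = h1_birth[i]; d1(i, 1) = h1_death[i]; }
  for (size_t i = 0; i < h2_birth.size(); ++i) { d2(i, 0) = h2_birth[i]; d2(i, 1) = h2_death[i]; }
  return List::create(Named("dim0") = d0, Named("dim1") = d1, Named("dim2") = d2,
                      Named("n_edges") = (int)edges.size(),
                      Named("n_triangles") = (int)tris.size(),
                      Named("n_tetrahedra") = (int)tets.size());
}

// Simplex lists of the Rips complex at one radius (1-based vertex ids),
// used to assemble boundary matrices / Hodge Laplacians in R.
// [[Rcpp::export]]
List cpp_rips_simplices(NumericMatrix dist, double radius, int max_simplex_dim) {
  const int n = dist.nrow();
  std::vector<Simplex> edges, tris, tets;
  enumerate_simplices(dist, radius, max_simplex_dim, edges, tris, tets);
  IntegerMatrix E(edges.size(), 2), T(tris.size(), 3), Q(tets.size(), 4);
  for (size_t e = 0; e < edges.size(); ++e) {
    E(e, 0) = edges[e].v[0] + 1; E(e, 1) = edges[e].v[1] + 1;
  }
  for (size_t t = 0; t < tris.size(); ++t)
    for (int k = 0; k < 3; ++k) T(t, k) = tris[t].v[k] + 1;
  for (size_t q = 0; q < tets.size(); ++q)
    for (int k = 0; k < 4; ++k) Q(q, k) = tets[q].v[k] + 1;
  return List::create(Named("edges") = E, Named("triangles") = T,
                      Named("tetrahedra") = Q);
}

// Template-pair counts for sample entropy (Richman-Moorman convention):
// templates start at 1..N-m for both lengths m and m+1; pairs i<j; Chebyshev
// distance <= r counts as a match; self-matches excluded by construction.
// [[Rcpp::export]]
NumericVector cpp_sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  if (n <= m + 1) stop("series too short for pattern length m");
  const int nt = n - m;  // number of templates
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dm = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::abs(x[i + k] - x[j + k]);
        if (d > dm) dm = d;
      }
      if (dm <= r) {
        B += 1.0;
        double d = std::abs(x[i + m] - x[j + m]);
        if (std::max(dm, d) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(B, A);  // (matches of length m, of length m+1)
}
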