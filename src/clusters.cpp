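// Spatio-temporal cluster enumeration for cluster-mass permutation tests.
//
// A cluster is a pair (C, [a,b]): C a connected set of electrodes under the
// montage adjacency, [a,b] a run of samples, such that every member of C is
// supra-threshold with a common sign at every sample of the run, and the
// pair is maximal (the run cannot be extended in time for C, and no
// adjacent electrode is supra-threshold throughout the run).  Electrode
// sets are manipulated as 32-bit masks (montages here have <= 32 channels),
// which keeps the permutation null distribution cheap to compute.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Cluster {
  uint32_t members;
  int a, b;      // 0-based inclusive run
  int sign;      // +1 / -1
  double mass;
};

// connected components of the bitmask m under adjacency (bitmask rows)
inline void components(uint32_t m, const std::vector<uint32_t>& adj,
                       std::vector<uint32_t>& out) {
  out.clear();
  uint32_t left = m;
  while (left) {
    int seed = __builtin_ctz(left);
    uint32_t comp = 1u << seed, frontier = comp;
    while (frontier) {
      uint32_t next = 0;
      uint32_t f = frontier;
      while (f) {
        int e = __builtin_ctz(f);
        f &= f - 1;
        next |= adj[e] & m & ~comp;
      }
      comp |= next;
      frontier = next;
    }
    out.push_back(comp);
    left &= ~comp;
  }
}

// enumerate maximal clusters of one sign; colmask[t] marks supra electrodes
void enumerate_sign(const std::vector<uint32_t>& colmask, int T, int sign,
                    const std::vector<uint32_t>& adj,
                    const std::vector<double>& cumabs, int E,
                    std::vector<Cluster>& out) {
  std::vector<uint32_t> comps;
  int t = 0;
  while (t < T) {
    if (!colmask[t]) { ++t; continue; }
    int isl_end = t;
    while (isl_end + 1 < T && colmask[isl_end + 1]) ++isl_end;
    for (int a = t; a <= isl_end; ++a) {
      uint32_t m = 0xffffffffu;
      uint32_t left = (a > 0) ? colmask[a - 1] : 0u;
      for (int b = a; b <= isl_end; ++b) {
        m &= colmask[b];
        if (!m) break;
        uint32_t right = (b + 1 < T) ? colmask[b + 1] : 0u;
        // every subset of m extendable in time -> nothing maximal here
        if ((m & ~left) == 0 || (m & ~right) == 0) continue;
        components(m, adj, comps);
        for (uint32_t C : comps) {
          if ((C & ~left) == 0) continue;   // run extends earlier
          if ((C & ~right) == 0) continue;  // run extends later
          double mass = 0.0;
          uint32_t c = C;
          while (c) {
            int e = __builtin_ctz(c);
            c &= c - 1;
            mass += cumabs[(size_t)e * (T + 1) + (b + 1)] -
                    cumabs[(size_t)e * (T + 1) + a];
          }
          out.push_back({C, a, b, sign, mass});
        }
      }
    }
    t = isl_end + 1;
  }
}

// all maximal clusters of a t-map (E x T), both signs
void find_all(const double* tmap, int E, int T, double thresh,
              const std::vector<uint32_t>& adj, std::vector<Cluster>& out) {
  std::vector<uint32_t> pos(T, 0), neg(T, 0);
  for (int t = 0; t < T; ++t) {
    for (int e = 0; e < E; ++e) {
      double v = tmap[e + (size_t)E * t];
      if (v > thresh) pos[t] |= 1u << e;
      else if (v < -thresh) neg[t] |= 1u << e;
    }
  }
  std::vector<double> cumabs((size_t)E * (T + 1), 0.0);
  for (int e = 0; e < E; ++e) {
    for (int t = 0; t < T; ++t) {
      cumabs[(size_t)e * (T + 1) + t + 1] =
        cumabs[(size_t)e * (T + 1) + t] + std::fabs(tmap[e + (size_t)E * t]);
    }
  }
  enumerate_sign(pos, T, +1, adj, cumabs, E, out);
  enumerate_sign(neg, T, -1, adj, cumabs, E, out);
}

std::vector<uint32_t> adj_masks(const LogicalMatrix& adj) {
  int E = adj.nrow();
  if (E > 32) stop("at most 32 electrodes supported");
  std::vector<uint32_t> out(E, 0);
  for (int i = 0; i < E; ++i) {
    for (int j = 0; j < E; ++j) {
      if (i != j && adj(i, j)) out[i] |= 1u << j;
    }
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
List cpp_find_clusters(NumericMatrix tmap, LogicalMatrix adj, double thresh) {
  int E = tmap.nrow(), T = tmap.ncol();
  if (adj.nrow() != E) stop("adjacency does not match t-map");
  std::vector<uint32_t> am = adj_masks(adj);
  std::vector<Cluster> cl;
  find_all(REAL(tmap), E, T, thresh, am, cl);
  int n = cl.size();
  List members(n);
  IntegerVector a(n), b(n), sgn(n);
  NumericVector mass(n);
  for (int i = 0; i < n; ++i) {
    std::vector<int> mem;
    uint32_t c = cl[i].members;
    while (c) {
      mem.push_back(__builtin_ctz(c) + 1);
      c &= c - 1;
    }
    members[i] = wrap(mem);
    a[i] = cl[i].a + 1;
    b[i] = cl[i].b + 1;
    sgn[i] = cl[i].sign;
    mass[i] = cl[i].mass;
  }
  return List::create(_["members"] = members, _["start"] = a, _["end"] = b,
                      _["sign"] = sgn, _["mass"] = mass);
}

// Null distribution of the maximum cluster mass under whole-signal sign
// flips.  betas: (E*T) x n matrix of per-participant coefficient maps
// (cell-major, electrode fastest); signs: n x n_perm matrix of +/-1.
// Squares are flip-invariant, so each permutation only needs the flipped
// mean; the variance follows from the precomputed sum of squares.
// [[Rcpp::export]]
NumericVector cpp_cluster_null(NumericMatrix betas, IntegerMatrix signs,
                               LogicalMatrix adj, double thresh,
                               int n_electrodes) {
  int cells = betas.nrow(), n = betas.ncol();
  int E = n_electrodes, T = cells / E;
  if (E * T != cells) stop("cell count is not a multiple of electrode count");
  if (signs.nrow() != n) stop("sign matrix does not match participant count");
  int n_perm = signs.ncol();
  std::vector<uint32_t> am = adj_masks(adj);

  std::vector<double> sumsq(cells, 0.0);
  const double* B = REAL(betas);
  for (int p = 0; p < n; ++p) {
    const double* col = B + (size_t)p * cells;
    for (int c = 0; c < cells; ++c) sumsq[c] += col[c] * col[c];
  }
  std::vector<double> tmap(cells);
  std::vector<Cluster> cl;
  NumericVector out(n_perm);
  for (int q = 0; q < n_perm; ++q) {
    for (int c = 0; c < cells; ++c) tmap[c] = 0.0;
    for (int p = 0; p < n; ++p) {
      double s = signs(p, q);
      const double* col = B + (size_t)p * cells;
      for (int c = 0; c < cells; ++c) tmap[c] += s * col[c];
    }
    for (int c = 0; c < cells; ++c) {
      double m = tmap[c] / n;
      double var = (sumsq[c] - n * m * m) / (n - 1);
      tmap[c] = (var > 0) ? m / std::sqrt(var / n) : 0.0;
    }
    cl.clear();
    find_all(tmap.data(), E, T, thresh, am, cl);
    double mx = 0.0;
    for (const Cluster& k : cl) mx = std::max(mx, k.mass);
    out[q] = mx;
  }
  return out;
}
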