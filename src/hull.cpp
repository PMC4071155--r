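// Incremental convex hull with running volume, dimensions 2-4, on an
// integer lattice with exact arithmetic.
//
// Callers snap points to a grid and pass coordinates that are integer
// multiples of the lattice spacing (the R wrappers do the scaling).
// Every geometric predicate — facet normals by cofactor expansion,
// visibility signs, simplex volumes — is evaluated exactly in 64/128-bit
// integers, so the beneath-beyond update can never be corrupted by
// floating-point slivers: the facet complex stays a consistent
// triangulated sphere and the accumulated volume is exact for the
// inserted point set.  Lattice coordinates must lie within +/- 65536,
// which keeps every intermediate inside the 128-bit range for d <= 4.
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

typedef int64_t i64;
typedef __int128 i128;

const i64 COORD_MAX = 65536;

struct Facet {
  std::vector<i64> v;        // d vertex ids
  std::vector<i64> n;        // outward normal (integer cofactors)
  i128 off;                  // n . x = off on the facet plane
  std::vector<uint64_t> rk;  // packed keys of the d ridges
  bool alive;
};

struct Hull {
  int d;
  double scale;              // lattice spacing: world coord = scale * int
  std::vector<std::vector<i64>> pts;
  std::vector<i64> interior_sum;   // sum of the d+1 starting vertices
  std::vector<Facet> facets;
  std::unordered_map<uint64_t, std::pair<int, int>> adj;
  double volume_lattice;     // exact volume in lattice units
};

// exact determinant of an n x n matrix (n <= 4) with i64 entries, by
// cofactor expansion; intermediates fit in i128 for |entries| <= 2^17
i128 det_i(const i64* a, int n) {
  if (n == 1) return (i128)a[0];
  if (n == 2) return (i128)a[0] * a[3] - (i128)a[1] * a[2];
  if (n == 3) {
    return (i128)a[0] * ((i128)a[4] * a[8] - (i128)a[5] * a[7])
         - (i128)a[1] * ((i128)a[3] * a[8] - (i128)a[5] * a[6])
         + (i128)a[2] * ((i128)a[3] * a[7] - (i128)a[4] * a[6]);
  }
  // n == 4: expand along the first row with 3x3 minors
  i128 det = 0;
  i64 sub[9];
  int sgn = 1;
  for (int c = 0; c < 4; ++c) {
    int cc = 0;
    for (int j = 0; j < 4; ++j) {
      if (j == c) continue;
      for (int r = 1; r < 4; ++r) sub[(r - 1) * 3 + cc] = a[r * 4 + j];
      ++cc;
    }
    det += (i128)sgn * a[c] * det_i(sub, 3);
    sgn = -sgn;
  }
  return det;
}

uint64_t ridge_key(const std::vector<i64>& f, int drop, int d) {
  i64 ids[4];
  int c = 0;
  for (int t = 0; t < d; ++t) if (t != drop) ids[c++] = f[t];
  std::sort(ids, ids + c);
  uint64_t k = 0;
  for (int i = 0; i < c; ++i) k = (k << 21) | (uint64_t)ids[i];
  return k;
}

void fill_ridge_keys(Facet& F, int d) {
  F.rk.resize(d);
  for (int j = 0; j < d; ++j) F.rk[j] = ridge_key(F.v, j, d);
}

void adj_add(Hull& H, int fi) {
  const Facet& F = H.facets[fi];
  for (size_t j = 0; j < F.rk.size(); ++j) {
    std::unordered_map<uint64_t, std::pair<int, int> >::iterator it =
      H.adj.find(F.rk[j]);
    if (it == H.adj.end()) H.adj[F.rk[j]] = std::make_pair(fi, -1);
    else if (it->second.first < 0) it->second.first = fi;
    else it->second.second = fi;
  }
}

void adj_remove(Hull& H, int fi) {
  const Facet& F = H.facets[fi];
  for (size_t j = 0; j < F.rk.size(); ++j) {
    std::unordered_map<uint64_t, std::pair<int, int> >::iterator it =
      H.adj.find(F.rk[j]);
    if (it == H.adj.end()) continue;
    if (it->second.first == fi) it->second.first = -1;
    else if (it->second.second == fi) it->second.second = -1;
    if (it->second.first < 0 && it->second.second < 0) H.adj.erase(it);
  }
}

// exact facet plane through the d lattice points vid, oriented away from
// the interior reference; false when the points are affinely dependent
// or the plane passes through the reference point
bool facet_geom(const Hull& H, const std::vector<i64>& vid, Facet& out) {
  int d = H.d;
  i64 E[12];                           // (d-1) x d edge matrix
  const std::vector<i64>& v0 = H.pts[(size_t)vid[0]];
  for (int r = 0; r < d - 1; ++r)
    for (int c = 0; c < d; ++c)
      E[r * d + c] = H.pts[(size_t)vid[r + 1]][c] - v0[c];
  std::vector<i64> n(d);
  i64 sub[9];
  int sgn = 1;
  bool nonzero = false;
  for (int i = 0; i < d; ++i) {
    int cc = 0;
    for (int c = 0; c < d; ++c) {
      if (c == i) continue;
      for (int r = 0; r < d - 1; ++r) sub[r * (d - 1) + cc] = E[r * d + c];
      ++cc;
    }
    i128 m = det_i(sub, d - 1);        // fits comfortably in i64 range
    n[i] = (i64)(sgn > 0 ? m : -m);
    sgn = -sgn;
    if (n[i] != 0) nonzero = true;
  }
  if (!nonzero) return false;
  i128 off = 0, dint = 0;
  for (int i = 0; i < d; ++i) {
    off += (i128)n[i] * v0[i];
    dint += (i128)n[i] * H.interior_sum[i];
  }
  // orientation against the (unnormalised) centroid of the start simplex
  i128 rhs = off * (i128)(d + 1);
  if (dint == rhs) return false;
  if (dint > rhs) {
    for (int i = 0; i < d; ++i) n[i] = -n[i];
    off = -off;
  }
  out.v = vid;
  out.n = n;
  out.off = off;
  out.alive = true;
  return true;
}

double simplex_vol_lattice(const Hull& H, const std::vector<i64>& vid,
                           const std::vector<i64>& apex) {
  int d = H.d;
  i64 M[16];
  for (int r = 0; r < d; ++r)
    for (int c = 0; c < d; ++c)
      M[r * d + c] = H.pts[(size_t)vid[r]][c] - apex[c];
  i128 det = det_i(M, d);
  if (det < 0) det = -det;
  double f = 1;
  for (int i = 2; i <= d; ++i) f *= i;
  return static_cast<double>(det) / f;
}

void insert_point(Hull& H, const std::vector<i64>& p) {
  int d = H.d;
  int nf = (int)H.facets.size();
  // exact side of p for every alive facet: sign(n.p - off)
  std::vector<signed char> side(nf, -2);
  bool any_strict = false;
  for (int fi = 0; fi < nf; ++fi) {
    Facet& F = H.facets[fi];
    if (!F.alive) continue;
    i128 s = -F.off;
    for (int i = 0; i < d; ++i) s += (i128)F.n[i] * p[i];
    side[fi] = s > 0 ? 1 : (s == 0 ? 0 : -1);
    if (side[fi] > 0) any_strict = true;
  }
  if (!any_strict) return;             // on or inside the hull
  // visible set: strictly visible facets plus coplanar facets connected
  // to them through ridges (zero extra volume, but consuming them keeps
  // the complex simplicial and consistent)
  std::vector<char> visible(nf, 0);
  std::vector<int> stack;
  for (int fi = 0; fi < nf; ++fi) {
    if (side[fi] == 1) {
      visible[fi] = 1;
      stack.push_back(fi);
    }
  }
  while (!stack.empty()) {
    int a = stack.back();
    stack.pop_back();
    const Facet& F = H.facets[a];
    for (int j = 0; j < d; ++j) {
      std::unordered_map<uint64_t, std::pair<int, int> >::iterator it =
        H.adj.find(F.rk[j]);
      if (it == H.adj.end()) continue;
      int b = (it->second.first == a) ? it->second.second : it->second.first;
      if (b >= 0 && !visible[b] && side[b] == 0) {
        visible[b] = 1;
        stack.push_back(b);
      }
    }
  }
  // horizon ridges: between a visible facet and a strictly-below facet
  std::vector<uint64_t> horizon;
  for (int a = 0; a < nf; ++a) {
    if (!visible[a]) continue;
    const Facet& F = H.facets[a];
    for (int j = 0; j < d; ++j) {
      std::unordered_map<uint64_t, std::pair<int, int> >::iterator it =
        H.adj.find(F.rk[j]);
      if (it == H.adj.end()) continue;
      int b = (it->second.first == a) ? it->second.second : it->second.first;
      if (b < 0 || !visible[b]) horizon.push_back(F.rk[j]);
    }
  }
  if (horizon.empty()) return;
  int pid = (int)H.pts.size();
  H.pts.push_back(p);
  std::vector<Facet> newf(horizon.size());
  for (size_t hi = 0; hi < horizon.size(); ++hi) {
    std::vector<i64> vid(d - 1);
    uint64_t k = horizon[hi];
    for (int i = d - 2; i >= 0; --i) {
      vid[i] = (i64)(k & ((1u << 21) - 1));
      k >>= 21;
    }
    vid.push_back(pid);
    if (!facet_geom(H, vid, newf[hi])) {
      // cannot happen for a horizon ridge under exact signs (the facet
      // beyond the ridge is strictly below p); guard regardless
      H.pts.pop_back();
      return;
    }
    fill_ridge_keys(newf[hi], d);
  }
  double dv = 0;
  for (int fi = 0; fi < nf; ++fi) {
    if (!visible[fi]) continue;
    dv += simplex_vol_lattice(H, H.facets[fi].v, p);
    H.facets[fi].alive = false;
    adj_remove(H, fi);
  }
  for (size_t i = 0; i < newf.size(); ++i) {
    H.facets.push_back(newf[i]);
    adj_add(H, (int)H.facets.size() - 1);
  }
  H.volume_lattice += dv;
  // compact dead facets once they dominate
  if (H.facets.size() > 256) {
    size_t dead = 0;
    for (size_t i = 0; i < H.facets.size(); ++i)
      if (!H.facets[i].alive) ++dead;
    if (dead > H.facets.size() / 2) {
      std::vector<Facet> keep;
      keep.reserve(H.facets.size() - dead);
      for (size_t i = 0; i < H.facets.size(); ++i)
        if (H.facets[i].alive) keep.push_back(H.facets[i]);
      H.facets.swap(keep);
      H.adj.clear();
      for (size_t fi = 0; fi < H.facets.size(); ++fi) adj_add(H, (int)fi);
    }
  }
}

std::vector<i64> to_lattice(const NumericMatrix& pts, int row, double scale) {
  std::vector<i64> p(pts.ncol());
  for (int c = 0; c < pts.ncol(); ++c) {
    double v = pts(row, c) / scale;
    i64 iv = (i64)std::llround(v);
    if (iv < -COORD_MAX || iv > COORD_MAX)
      stop("point coordinate out of lattice range; use a coarser snap");
    p[c] = iv;
  }
  return p;
}

} // namespace

// [[Rcpp::export(name = ".hull_new")]]
SEXP hull_new_cpp(NumericMatrix simplex, double scale) {
  int d = simplex.ncol();
  if (d < 2 || d > 4) stop("hull dimension must be between 2 and 4");
  if (simplex.nrow() != d + 1) stop("need exactly d+1 starting points");
  if (scale <= 0) stop("'scale' must be positive");
  Hull* H = new Hull();
  H->d = d;
  H->scale = scale;
  H->volume_lattice = 0.0;
  H->interior_sum.assign(d, 0);
  for (int r = 0; r < d + 1; ++r) {
    std::vector<i64> p = to_lattice(simplex, r, scale);
    for (int c = 0; c < d; ++c) H->interior_sum[c] += p[c];
    H->pts.push_back(p);
  }
  for (int i = 0; i < d + 1; ++i) {
    std::vector<i64> vid;
    for (int t = 0; t < d + 1; ++t) if (t != i) vid.push_back(t);
    Facet F;
    if (!facet_geom(*H, vid, F)) {
      delete H;
      stop("degenerate starting simplex");
    }
    fill_ridge_keys(F, d);
    H->facets.push_back(F);
    adj_add(*H, (int)H->facets.size() - 1);
  }
  std::vector<i64> base;
  for (int t = 1; t < d + 1; ++t) base.push_back(t);
  H->volume_lattice = simplex_vol_lattice(*H, base, H->pts[0]);
  XPtr<Hull> ptr(H, true);
  return ptr;
}

// [[Rcpp::export(name = ".hull_add")]]
double hull_add_cpp(SEXP hptr, NumericMatrix pts) {
  XPtr<Hull> H(hptr);
  int d = H->d;
  if (pts.ncol() != d) stop("dimension mismatch");
  for (int r = 0; r < pts.nrow(); ++r) {
    insert_point(*H, to_lattice(pts, r, H->scale));
  }
  return H->volume_lattice * std::pow(H->scale, d);
}

// [[Rcpp::export(name = ".hull_volume")]]
double hull_volume_cpp(SEXP hptr) {
  XPtr<Hull> H(hptr);
  return H->volume_lattice * std::pow(H->scale, H->d);
}

// [[Rcpp::export(name = ".hull_volume_recompute")]]
double hull_volume_recompute_cpp(SEXP hptr) {
  // independent cross-check: sum pyramids from vertex 0 over all facets
  // that do not contain it
  XPtr<Hull> H(hptr);
  double v = 0;
  const std::vector<i64>& apex = H->pts[0];
  for (size_t i = 0; i < H->facets.size(); ++i) {
    const Facet& F = H->facets[i];
    if (!F.alive) continue;
    bool has_apex = false;
    for (int j = 0; j < H->d; ++j) if (F.v[j] == 0) has_apex = true;
    if (has_apex) continue;
    v += simplex_vol_lattice(*H, F.v, apex);
  }
  return v * std::pow(H->scale, H->d);
}

// [[Rcpp::export(name = ".hull_n_facets")]]
int hull_n_facets_cpp(SEXP hptr) {
  XPtr<Hull> H(hptr);
  int n = 0;
  for (size_t i = 0; i < H->facets.size(); ++i)
    if (H->facets[i].alive) ++n;
  return n;
}

// [[Rcpp::export(name = ".hull_n_points")]]
int hull_n_points_cpp(SEXP hptr) {
  XPtr<Hull> H(hptr);
  return (int)H->pts.size();
}
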