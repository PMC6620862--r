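#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher
// lower-envelope algorithm) in 3D, with feature transform: for every grid
// node the linear index of the nearest "site" node is returned, so callers
// can apply sub-grid corrections based on the field value at the site.
// Distances are in grid-index units (multiply by the spacing afterwards).

namespace {

const double INF = std::numeric_limits<double>::infinity();

// 1D transform of sampled function f along a line; feat in/out carries the
// site label attached to each parabola vertex.
void dt1d(const std::vector<double> &f, const std::vector<int> &feat_in,
          std::vector<double> &d, std::vector<int> &feat_out, int n,
          std::vector<int> &v, std::vector<double> &z) {
  int q = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int i = 1; i < n; ++i) {
    if (f[i] == INF) continue;
    if (f[v[0]] == INF && q == 0) { v[0] = i; continue; }
    double s;
    while (true) {
      int vk = v[q];
      s = ((f[i] + i * (double)i) - (f[vk] + vk * (double)vk)) /
          (2.0 * i - 2.0 * vk);
      if (s <= z[q]) { --q; } else break;
    }
    ++q;
    v[q] = i;
    z[q] = s;
    z[q + 1] = INF;
  }
  int k = 0;
  for (int i = 0; i < n; ++i) {
    if (f[v[0]] == INF) { d[i] = INF; feat_out[i] = -1; continue; }
    while (z[k + 1] < i) ++k;
    double di = (double)(i - v[k]);
    d[i] = di * di + f[v[k]];
    feat_out[i] = feat_in[v[k]];
  }
}

} // namespace

// mask: logical array, TRUE marks "site" voxels (distance zero there).
// Returns list(dist2 = squared distance in index units, feature = 1-based
// linear index of nearest site, or NA where no site exists).
// [[Rcpp::export(name = ".cpp_edt3d")]]
List cpp_edt3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> D(n);
  std::vector<int> F(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    D[i] = mask[i] ? 0.0 : INF;
    F[i] = mask[i] ? (int)i : -1;
  }
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> fin(nmax), fout(nmax), v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) { f[i] = D[base + i]; fin[i] = F[base + i]; }
      dt1d(f, fin, d, fout, nx, v, z);
      for (int i = 0; i < nx; ++i) { D[base + i] = d[i]; F[base + i] = fout[i]; }
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) {
        f[j] = D[base + (R_xlen_t)nx * j];
        fin[j] = F[base + (R_xlen_t)nx * j];
      }
      dt1d(f, fin, d, fout, ny, v, z);
      for (int j = 0; j < ny; ++j) {
        D[base + (R_xlen_t)nx * j] = d[j];
        F[base + (R_xlen_t)nx * j] = fout[j];
      }
    }
  // pass along z
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) {
        f[k] = D[base + nxy * k];
        fin[k] = F[base + nxy * k];
      }
      dt1d(f, fin, d, fout, nz, v, z);
      for (int k = 0; k < nz; ++k) {
        D[base + nxy * k] = d[k];
        F[base + nxy * k] = fout[k];
      }
    }

  NumericVector dist2(n);
  IntegerVector feature(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    dist2[i] = D[i];
    feature[i] = F[i] < 0 ? NA_INTEGER : F[i] + 1;
  }
  dist2.attr("dim") = dims;
  feature.attr("dim") = dims;
  return List::create(_["dist2"] = dist2, _["feature"] = feature);
}
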