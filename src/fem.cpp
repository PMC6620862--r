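#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel finite elements: every material voxel is one eight-node trilinear
// brick with the isotropic linear-elastic constitutive matrix. The global
// system is never assembled; a matrix-free Jacobi-preconditioned conjugate
// gradient iterates on the free degrees of freedom, with prescribed
// displacements carried to the right-hand side.
//
// Local node order: node c (0..7) sits at offsets (c&1, (c>>1)&1, (c>>2)&1)
// of the voxel; DOFs are (ux, uy, uz) per node, interleaved.

namespace {

// 24x24 element stiffness by 2x2x2 Gauss quadrature (exact for the trilinear
// brick: the integrand is quadratic per direction).
void hex_ke(double E, double nu, double h, std::vector<double> &KE) {
  KE.assign(24 * 24, 0.0);
  const double lam = E * nu / ((1 + nu) * (1 - 2 * nu));
  const double mu = E / (2 * (1 + nu));
  double C[6][6] = {{0}};
  C[0][0] = C[1][1] = C[2][2] = lam + 2 * mu;
  C[0][1] = C[0][2] = C[1][0] = C[1][2] = C[2][0] = C[2][1] = lam;
  C[3][3] = C[4][4] = C[5][5] = mu;
  const double g = 1.0 / std::sqrt(3.0);
  const double gp[2] = {-g, g};
  for (int ix = 0; ix < 2; ++ix)
    for (int iy = 0; iy < 2; ++iy)
      for (int iz = 0; iz < 2; ++iz) {
        double xi = gp[ix], eta = gp[iy], zeta = gp[iz];
        // shape-function derivatives wrt physical coords (element [0,h]^3)
        double dN[8][3];
        for (int c = 0; c < 8; ++c) {
          double sx = (c & 1) ? 1.0 : -1.0;
          double sy = ((c >> 1) & 1) ? 1.0 : -1.0;
          double sz = ((c >> 2) & 1) ? 1.0 : -1.0;
          dN[c][0] = sx * (1 + sy * eta) * (1 + sz * zeta) / 8.0 * (2.0 / h);
          dN[c][1] = (1 + sx * xi) * sy * (1 + sz * zeta) / 8.0 * (2.0 / h);
          dN[c][2] = (1 + sx * xi) * (1 + sy * eta) * sz / 8.0 * (2.0 / h);
        }
        // B matrix (6 x 24), Voigt order xx, yy, zz, yz, xz, xy
        double B[6][24] = {{0}};
        for (int c = 0; c < 8; ++c) {
          B[0][3 * c + 0] = dN[c][0];
          B[1][3 * c + 1] = dN[c][1];
          B[2][3 * c + 2] = dN[c][2];
          B[3][3 * c + 1] = dN[c][2]; B[3][3 * c + 2] = dN[c][1];
          B[4][3 * c + 0] = dN[c][2]; B[4][3 * c + 2] = dN[c][0];
          B[5][3 * c + 0] = dN[c][1]; B[5][3 * c + 1] = dN[c][0];
        }
        const double w = (h / 2) * (h / 2) * (h / 2); // gauss weight * |J|
        double CB[6][24];
        for (int r = 0; r < 6; ++r)
          for (int q = 0; q < 24; ++q) {
            double s = 0;
            for (int m = 0; m < 6; ++m) s += C[r][m] * B[m][q];
            CB[r][q] = s;
          }
        for (int p = 0; p < 24; ++p)
          for (int q = 0; q < 24; ++q) {
            double s = 0;
            for (int m = 0; m < 6; ++m) s += B[m][p] * CB[m][q];
            KE[p * 24 + q] += w * s;
          }
      }
}

struct Grid {
  int M;             // voxels per edge
  int Mn;            // nodes per edge = M + 1
  std::vector<int> elems;          // linear element ids of material voxels
  std::vector<int> enodes;         // 8 node ids per element
  void build(const LogicalVector &occ) {
    Mn = M + 1;
    elems.clear();
    enodes.clear();
    for (int k = 0; k < M; ++k)
      for (int j = 0; j < M; ++j)
        for (int i = 0; i < M; ++i) {
          R_xlen_t e = i + (R_xlen_t)M * (j + (R_xlen_t)M * k);
          if (!occ[e]) continue;
          elems.push_back((int)e);
          for (int c = 0; c < 8; ++c) {
            int ii = i + (c & 1), jj = j + ((c >> 1) & 1), kk = k + ((c >> 2) & 1);
            enodes.push_back(ii + Mn * (jj + Mn * kk));
          }
        }
  }
};

void apply_K(const Grid &g, const std::vector<double> &KE,
             const std::vector<double> &u, std::vector<double> &out) {
  std::fill(out.begin(), out.end(), 0.0);
  const size_t ne = g.elems.size();
  double ue[24], fe[24];
  for (size_t e = 0; e < ne; ++e) {
    const int *nd = &g.enodes[8 * e];
    for (int c = 0; c < 8; ++c)
      for (int d = 0; d < 3; ++d) ue[3 * c + d] = u[3 * nd[c] + d];
    for (int p = 0; p < 24; ++p) {
      double s = 0;
      const double *row = &KE[p * 24];
      for (int q = 0; q < 24; ++q) s += row[q] * ue[q];
      fe[p] = s;
    }
    for (int c = 0; c < 8; ++c)
      for (int d = 0; d < 3; ++d) out[3 * nd[c] + d] += fe[3 * c + d];
  }
}

} // namespace

// [[Rcpp::export(name = ".cpp_hex_ke")]]
NumericMatrix cpp_hex_ke(double E, double nu, double h) {
  std::vector<double> KE;
  hex_ke(E, nu, h, KE);
  NumericMatrix out(24, 24);
  for (int p = 0; p < 24; ++p)
    for (int q = 0; q < 24; ++q) out(p, q) = KE[p * 24 + q];
  return out;
}

// occ: logical M^3 voxel occupancy; fixed: logical 3*(M+1)^3 DOF mask;
// uval: prescribed displacement where fixed (0 elsewhere ignored).
// Returns u (full DOF vector), f = K u (nodal forces, reactions at
// constrained DOFs), iterations and final relative residual.
// [[Rcpp::export(name = ".cpp_fem_solve")]]
List cpp_fem_solve(LogicalVector occ, int M, double h, double E, double nu,
                   LogicalVector fixed, NumericVector uval,
                   double tol = 1e-8, int maxit = 50000) {
  Grid g;
  g.M = M;
  g.build(occ);
  std::vector<double> KE;
  hex_ke(E, nu, h, KE);
  const R_xlen_t ndof = 3 * (R_xlen_t)g.Mn * g.Mn * g.Mn;
  if ((R_xlen_t)fixed.size() != ndof)
    stop("constraint mask has wrong length");

  // diag for Jacobi preconditioner; also marks active DOFs
  std::vector<double> diag(ndof, 0.0);
  for (size_t e = 0; e < g.elems.size(); ++e) {
    const int *nd = &g.enodes[8 * e];
    for (int c = 0; c < 8; ++c)
      for (int d = 0; d < 3; ++d)
        diag[3 * nd[c] + d] += KE[(3 * c + d) * 24 + (3 * c + d)];
  }

  std::vector<double> u(ndof, 0.0), r(ndof, 0.0), p(ndof, 0.0), Ap(ndof, 0.0);
  std::vector<int> freelist;
  freelist.reserve(ndof / 4);
  for (R_xlen_t i = 0; i < ndof; ++i) {
    if (fixed[i]) u[i] = uval[i];
    else if (diag[i] > 0) freelist.push_back((int)i);
  }
  const size_t nfree = freelist.size();

  // b = -K u_prescribed restricted to free DOFs
  apply_K(g, KE, u, r);
  double bnorm = 0;
  {
    std::vector<double> rf(ndof, 0.0);
    for (size_t q = 0; q < nfree; ++q) {
      int i = freelist[q];
      rf[i] = -r[i];
      bnorm += rf[i] * rf[i];
    }
    r.swap(rf);
  }
  bnorm = std::sqrt(bnorm);
  int it = 0;
  double relres = 0.0;
  if (bnorm > 0) {
    double rz = 0;
    for (size_t q = 0; q < nfree; ++q) {
      int i = freelist[q];
      p[i] = r[i] / diag[i];
      rz += r[i] * p[i];
    }
    for (it = 1; it <= maxit; ++it) {
      apply_K(g, KE, p, Ap);
      double pAp = 0;
      for (size_t q = 0; q < nfree; ++q) {
        int i = freelist[q];
        pAp += p[i] * Ap[i];
      }
      double alpha = rz / pAp;
      double rnorm = 0;
      for (size_t q = 0; q < nfree; ++q) {
        int i = freelist[q];
        u[i] += alpha * p[i];
        r[i] -= alpha * Ap[i];
        rnorm += r[i] * r[i];
      }
      relres = std::sqrt(rnorm) / bnorm;
      if (relres <= tol) break;
      double rznew = 0;
      for (size_t q = 0; q < nfree; ++q) {
        int i = freelist[q];
        rznew += r[i] * r[i] / diag[i];
      }
      double beta = rznew / rz;
      rz = rznew;
      for (size_t q = 0; q < nfree; ++q) {
        int i = freelist[q];
        p[i] = r[i] / diag[i] + beta * p[i];
      }
    }
  }

  apply_K(g, KE, u, Ap); // nodal forces f = K u
  NumericVector uo(ndof), fo(ndof);
  for (R_xlen_t i = 0; i < ndof; ++i) {
    uo[i] = u[i];
    fo[i] = Ap[i];
  }
  return List::create(_["u"] = uo, _["f"] = fo, _["iterations"] = it,
                      _["relres"] = relres, _["n_elements"] = (int)g.elems.size());
}

// Element-centroid stresses (Voigt xx, yy, zz, yz, xz, xy) and von Mises,
// for material voxels in the order they appear in the occupancy array.
// [[Rcpp::export(name = ".cpp_fem_stress")]]
List cpp_fem_stress(LogicalVector occ, int M, double h, double E, double nu,
                    NumericVector u) {
  Grid g;
  g.M = M;
  g.build(occ);
  const double lam = E * nu / ((1 + nu) * (1 - 2 * nu));
  const double mu = E / (2 * (1 + nu));
  const size_t ne = g.elems.size();
  NumericMatrix stress(ne, 6);
  NumericVector vm(ne);
  IntegerVector elem_id(ne);
  // shape-function gradients at the centroid (xi = eta = zeta = 0)
  double dN[8][3];
  for (int c = 0; c < 8; ++c) {
    double sx = (c & 1) ? 1.0 : -1.0;
    double sy = ((c >> 1) & 1) ? 1.0 : -1.0;
    double sz = ((c >> 2) & 1) ? 1.0 : -1.0;
    dN[c][0] = sx / 8.0 * (2.0 / h);
    dN[c][1] = sy / 8.0 * (2.0 / h);
    dN[c][2] = sz / 8.0 * (2.0 / h);
  }

  for (size_t e = 0; e < ne; ++e) {
    const int *nd = &g.enodes[8 * e];
    double eps[6] = {0, 0, 0, 0, 0, 0};
    for (int c = 0; c < 8; ++c) {
      double ux = u[3 * nd[c] + 0], uy = u[3 * nd[c] + 1], uz = u[3 * nd[c] + 2];
      eps[0] += dN[c][0] * ux;
      eps[1] += dN[c][1] * uy;
      eps[2] += dN[c][2] * uz;
      eps[3] += dN[c][2] * uy + dN[c][1] * uz;
      eps[4] += dN[c][2] * ux + dN[c][0] * uz;
      eps[5] += dN[c][1] * ux + dN[c][0] * uy;
    }
    double tr = eps[0] + eps[1] + eps[2];
    double sxx = lam * tr + 2 * mu * eps[0];
    double syy = lam * tr + 2 * mu * eps[1];
    double szz = lam * tr + 2 * mu * eps[2];
    double syz = mu * eps[3], sxz = mu * eps[4], sxy = mu * eps[5];
    stress(e, 0) = sxx; stress(e, 1) = syy; stress(e, 2) = szz;
    stress(e, 3) = syz; stress(e, 4) = sxz; stress(e, 5) = sxy;
    vm[e] = std::sqrt(0.5 * ((sxx - syy) * (sxx - syy) +
                             (syy - szz) * (syy - szz) +
                             (szz - sxx) * (szz - sxx)) +
                      3 * (syz * syz + sxz * sxz + sxy * sxy));
    elem_id[e] = g.elems[e] + 1;
  }
  return List::create(_["stress"] = stress, _["von_mises"] = vm,
                      _["element"] = elem_id);
}

// Connected components of material voxels under 6-face adjacency.
// Returns 1-based component label per voxel (0 for void).
// [[Rcpp::export(name = ".cpp_voxel_components")]]
IntegerVector cpp_voxel_components(LogicalVector occ, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector label(n);
  std::vector<R_xlen_t> stack;
  int comp = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!occ[s] || label[s] != 0) continue;
    ++comp;
    stack.push_back(s);
    label[s] = comp;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = cur % nx, j = (cur / nx) % ny, k = cur / ((R_xlen_t)nx * ny);
      const int di[6] = {1, -1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, 1, -1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, 1, -1};
      for (int q = 0; q < 6; ++q) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t nb = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (occ[nb] && label[nb] == 0) {
          label[nb] = comp;
          stack.push_back(nb);
        }
      }
    }
  }
  label.attr("dim") = dims;
  return label;
}
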