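// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
using namespace Rcpp;

// Paraboloid-method curvature estimation. Every mesh vertex is approximated
// in its local tangent frame (z along the vertex normal) by the quadric
//   h(u, v) = a u^2 + b u v + c v^2 + d u + e v
// fitted by least squares over the two-ring neighbourhood (widened to three
// rings when fewer than 6 neighbours are available). Principal curvatures are
// the eigenvalues of the shape operator built from the first and second
// fundamental forms of the fitted quadric, evaluated at the vertex.
//
// Sign convention: positive curvature means the surface bends towards the
// supplied vertex normal. With normals oriented away from the material phase
// this makes pore-facing caps (cups seen from the pore) carry positive
// curvatures.

// [[Rcpp::export(name = ".cpp_paraboloid_curvatures")]]
List cpp_paraboloid_curvatures(NumericMatrix vertices, IntegerMatrix faces,
                               NumericMatrix normals, int min_neighbors = 6,
                               int rings = 2) {
  const int nv = vertices.nrow(), nf = faces.nrow();

  // vertex adjacency (CSR built from face edges, deduplicated)
  std::vector<std::vector<int>> adj(nv);
  auto add_edge = [&](int a, int b) {
    adj[a].push_back(b);
    adj[b].push_back(a);
  };
  for (int f = 0; f < nf; ++f) {
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    add_edge(a, b); add_edge(b, c); add_edge(a, c);
  }
  for (int v = 0; v < nv; ++v) {
    std::sort(adj[v].begin(), adj[v].end());
    adj[v].erase(std::unique(adj[v].begin(), adj[v].end()), adj[v].end());
  }

  NumericVector k1(nv), k2(nv), H(nv), G(nv), R(nv);
  LogicalVector fit_ok(nv);
  std::vector<int> mark(nv, -1);
  std::vector<int> ring;

  for (int v = 0; v < nv; ++v) {
    // collect k-ring neighbourhood by BFS, widened once if too few
    for (int depth = rings; depth <= rings + 1; ++depth) {
      ring.clear();
      mark[v] = v;
      std::vector<int> frontier = {v};
      for (int d = 0; d < depth; ++d) {
        std::vector<int> next;
        for (int u : frontier)
          for (int w : adj[u])
            if (mark[w] != v) {
              mark[w] = v;
              ring.push_back(w);
              next.push_back(w);
            }
        frontier.swap(next);
      }
      for (int u : ring) mark[u] = -1; // reset marks (v's own mark reused)
      mark[v] = -1;
      if ((int)ring.size() >= min_neighbors || depth == rings + 1) break;
    }
    if ((int)ring.size() < min_neighbors) {
      fit_ok[v] = false;
      k1[v] = k2[v] = H[v] = G[v] = R[v] = NA_REAL;
      continue;
    }

    arma::vec n = {normals(v, 0), normals(v, 1), normals(v, 2)};
    double nn = arma::norm(n);
    if (!(nn > 0)) {
      fit_ok[v] = false;
      k1[v] = k2[v] = H[v] = G[v] = R[v] = NA_REAL;
      continue;
    }
    n /= nn;
    arma::vec ref = std::abs(n[0]) < 0.9 ? arma::vec{1, 0, 0} : arma::vec{0, 1, 0};
    arma::vec t1 = arma::normalise(arma::cross(n, ref));
    arma::vec t2 = arma::cross(n, t1);

    const int m = (int)ring.size();
    arma::mat A(m, 5);
    arma::vec h(m);
    for (int q = 0; q < m; ++q) {
      arma::vec dvec = {vertices(ring[q], 0) - vertices(v, 0),
                        vertices(ring[q], 1) - vertices(v, 1),
                        vertices(ring[q], 2) - vertices(v, 2)};
      double u = arma::dot(dvec, t1), w = arma::dot(dvec, t2);
      A(q, 0) = u * u;
      A(q, 1) = u * w;
      A(q, 2) = w * w;
      A(q, 3) = u;
      A(q, 4) = w;
      h[q] = arma::dot(dvec, n);
    }
    arma::vec coef;
    bool ok = arma::solve(coef, A.t() * A, A.t() * h,
                          arma::solve_opts::no_approx);
    if (!ok) {
      fit_ok[v] = false;
      k1[v] = k2[v] = H[v] = G[v] = R[v] = NA_REAL;
      continue;
    }
    double a = coef[0], b = coef[1], c = coef[2], d = coef[3], e = coef[4];
    // fundamental forms of z = h(u, v) at the origin with slope (d, e)
    double E1 = 1 + d * d, F1 = d * e, G1 = 1 + e * e;
    double den = std::sqrt(1 + d * d + e * e);
    double L2 = 2 * a / den, M2 = b / den, N2 = 2 * c / den;
    // det(II - k I) = 0
    double p2 = E1 * G1 - F1 * F1;
    double p1 = -(E1 * N2 + G1 * L2 - 2 * F1 * M2);
    double p0 = L2 * N2 - M2 * M2;
    double disc = std::max(0.0, p1 * p1 - 4 * p2 * p0);
    double rt = std::sqrt(disc);
    double ka = (-p1 + rt) / (2 * p2), kb = (-p1 - rt) / (2 * p2);
    k1[v] = std::max(ka, kb);
    k2[v] = std::min(ka, kb);
    H[v] = 0.5 * (ka + kb);
    G[v] = ka * kb;
    R[v] = std::sqrt(ka * ka + kb * kb);
    fit_ok[v] = true;
  }

  return List::create(_["k1"] = k1, _["k2"] = k2, _["H"] = H, _["G"] = G,
                      _["R"] = R, _["fit_ok"] = fit_ok);
}
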