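#include <Rcpp.h>
#include <unordered_map>
#include <functional>
#include <cstdint>
using namespace Rcpp;

// Marching tetrahedra on the body-centred 24-tetrahedron decomposition of
// each grid cell: every cube is split into 24 tets spanned by the cell
// centre, a face centre and a face edge. Face and cell centres carry the
// trilinearly interpolated (average) field value. Unlike the 6-tet Kuhn
// split, this decomposition is invariant under the full cube symmetry
// group, so symmetric fields tessellate symmetrically; shared cube faces
// are triangulated identically from both sides (4 triangles about the face
// centre), so the surface is watertight up to the domain boundary.
// Vertices are interpolated on tetrahedron edges and deduplicated by the
// pair of global point ids of the edge, which gives exact vertex sharing.

namespace {

// corner c (0..7) has offsets (c&1, (c>>1)&1, (c>>2)&1);
// FACES[f] lists the corner cycle of cube face f (f = 2*axis + side)
const int FACES[6][4] = {
  {0, 2, 6, 4}, // x-
  {1, 3, 7, 5}, // x+
  {0, 1, 5, 4}, // y-
  {2, 3, 7, 6}, // y+
  {0, 1, 3, 2}, // z-
  {4, 5, 7, 6}  // z+
};

struct MeshAcc {
  std::unordered_map<uint64_t, int> edge2vid;
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;

  int edge_vertex(uint64_t ga, uint64_t gb, double va, double vb,
                  const double *pa, const double *pb) {
    uint64_t key = ga < gb ? (ga << 32) | gb : (gb << 32) | ga;
    auto it = edge2vid.find(key);
    if (it != edge2vid.end()) return it->second;
    double t = va / (va - vb);
    int id = (int)vx.size();
    vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    edge2vid.emplace(key, id);
    return id;
  }

  // orient so the triangle normal has positive dot product with dir
  void add_tri(int a, int b, int c, const double *dir) {
    double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
    double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
    double nx = uy * wz - uz * wy;
    double ny = uz * wx - ux * wz;
    double nz = ux * wy - uy * wx;
    double d = nx * dir[0] + ny * dir[1] + nz * dir[2];
    if (d >= 0) { fa.push_back(a); fb.push_back(b); fc.push_back(c); }
    else        { fa.push_back(a); fb.push_back(c); fc.push_back(b); }
  }
};

} // namespace

// field: N3 array values (x fastest), iso already subtracted upstream is NOT
// assumed: `iso` is subtracted here. Returns vertices (V x 3), faces (F x 3,
// 1-based). Triangle winding is such that geometric normals point away from
// the region {field > iso} (outward from the internal phase).
// [[Rcpp::export(name = ".cpp_march_tets")]]
List cpp_march_tets(NumericVector field, IntegerVector dims,
                    NumericVector origin, double spacing, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const uint64_t n_nodes = (uint64_t)nx * ny * nz;
  // id spaces: grid nodes | cell centres | face centres (3 orientations)
  const uint64_t cx = (uint64_t)(nx - 1), cy = (uint64_t)(ny - 1),
                 cz = (uint64_t)(nz - 1);
  const uint64_t n_cells = cx * cy * cz;
  const uint64_t base_cell = n_nodes;
  const uint64_t base_fx = base_cell + n_cells;          // faces normal to x
  const uint64_t n_fx = (uint64_t)nx * cy * cz;
  const uint64_t base_fy = base_fx + n_fx;               // faces normal to y
  const uint64_t n_fy = cx * (uint64_t)ny * cz;
  const uint64_t base_fz = base_fy + n_fy;               // faces normal to z
  auto gid = [&](int i, int j, int k) -> uint64_t {
    return (uint64_t)i + (uint64_t)nx * ((uint64_t)j + (uint64_t)ny * k);
  };
  MeshAcc acc;
  double cp[8][3]; // corner positions
  double cv[8];    // corner values (minus iso)
  uint64_t cg[8];  // corner global ids

  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool anyp = false, anyn = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + (c & 1), jj = j + ((c >> 1) & 1), kk = k + ((c >> 2) & 1);
          cg[c] = gid(ii, jj, kk);
          cv[c] = field[cg[c]] - iso;
          cp[c][0] = ox + spacing * ii;
          cp[c][1] = oy + spacing * jj;
          cp[c][2] = oz + spacing * kk;
          (cv[c] > 0 ? anyp : anyn) = true;
        }
        if (!anyp || !anyn) continue;
        // cell centre
        uint64_t ccid = base_cell + (uint64_t)i + cx * ((uint64_t)j + cy * k);
        double ccv = 0, ccp[3] = {0, 0, 0};
        for (int c = 0; c < 8; ++c) {
          ccv += cv[c] / 8.0;
          for (int d = 0; d < 3; ++d) ccp[d] += cp[c][d] / 8.0;
        }
        for (int fface = 0; fface < 6; ++fface) {
          const int *F = FACES[fface];
          int axis = fface / 2, side = fface % 2;
          // face-centre global id
          uint64_t fcid;
          if (axis == 0) {
            fcid = base_fx + (uint64_t)(i + side) +
                   (uint64_t)nx * ((uint64_t)j + cy * k);
          } else if (axis == 1) {
            fcid = base_fy + (uint64_t)i +
                   cx * ((uint64_t)(j + side) + (uint64_t)ny * k);
          } else {
            fcid = base_fz + (uint64_t)i +
                   cx * ((uint64_t)j + cy * (uint64_t)(k + side));
          }
          double fcv = 0, fcp[3] = {0, 0, 0};
          for (int m = 0; m < 4; ++m) {
            fcv += cv[F[m]] / 4.0;
            for (int d = 0; d < 3; ++d) fcp[d] += cp[F[m]][d] / 4.0;
          }
          for (int m = 0; m < 4; ++m) {
            int a = F[m], b = F[(m + 1) % 4];
            // tet: cell centre, face centre, corners a, b
            double tv[4] = {ccv, fcv, cv[a], cv[b]};
            const double *tp[4] = {ccp, fcp, cp[a], cp[b]};
            uint64_t tg[4] = {ccid, fcid, cg[a], cg[b]};
            int pos[4], neg[4], np = 0, nn = 0;
            for (int q = 0; q < 4; ++q)
              (tv[q] > 0 ? pos[np++] : neg[nn++]) = q;
            if (np == 0 || np == 4) continue;
            // direction from positive side to negative side (outward)
            double dir[3] = {0, 0, 0};
            for (int q = 0; q < np; ++q)
              for (int d = 0; d < 3; ++d) dir[d] -= tp[pos[q]][d] / np;
            for (int q = 0; q < nn; ++q)
              for (int d = 0; d < 3; ++d) dir[d] += tp[neg[q]][d] / nn;
            if (np == 1 || np == 3) {
              int lone = (np == 1) ? pos[0] : neg[0];
              int *oth = (np == 1) ? neg : pos;
              int qv[3];
              for (int q = 0; q < 3; ++q)
                qv[q] = acc.edge_vertex(tg[lone], tg[oth[q]], tv[lone],
                                        tv[oth[q]], tp[lone], tp[oth[q]]);
              acc.add_tri(qv[0], qv[1], qv[2], dir);
            } else { // np == 2: quad split into two triangles
              int q00 = acc.edge_vertex(tg[pos[0]], tg[neg[0]], tv[pos[0]],
                                        tv[neg[0]], tp[pos[0]], tp[neg[0]]);
              int q01 = acc.edge_vertex(tg[pos[0]], tg[neg[1]], tv[pos[0]],
                                        tv[neg[1]], tp[pos[0]], tp[neg[1]]);
              int q10 = acc.edge_vertex(tg[pos[1]], tg[neg[0]], tv[pos[1]],
                                        tv[neg[0]], tp[pos[1]], tp[neg[0]]);
              int q11 = acc.edge_vertex(tg[pos[1]], tg[neg[1]], tv[pos[1]],
                                        tv[neg[1]], tp[pos[1]], tp[neg[1]]);
              acc.add_tri(q00, q01, q11, dir);
              acc.add_tri(q00, q11, q10, dir);
            }
          }
        }
      }

  const int nv = (int)acc.vx.size(), nf = (int)acc.fa.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = acc.vx[v]; V(v, 1) = acc.vy[v]; V(v, 2) = acc.vz[v];
  }
  for (int f = 0; f < nf; ++f) {
    F(f, 0) = acc.fa[f] + 1; F(f, 1) = acc.fb[f] + 1; F(f, 2) = acc.fc[f] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Connected components of mesh vertices under edge adjacency (union-find).
// faces: F x 3, 1-based. Returns 1-based component label per vertex.
// [[Rcpp::export(name = ".cpp_mesh_components")]]
IntegerVector cpp_mesh_components(IntegerMatrix faces, int n_vertices) {
  std::vector<int> parent(n_vertices);
  for (int i = 0; i < n_vertices; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[a] = b;
  };
  for (int f = 0; f < faces.nrow(); ++f) {
    unite(faces(f, 0) - 1, faces(f, 1) - 1);
    unite(faces(f, 1) - 1, faces(f, 2) - 1);
    unite(faces(f, 0) - 1, faces(f, 2) - 1);
  }
  std::unordered_map<int, int> relabel;
  IntegerVector out(n_vertices);
  for (int i = 0; i < n_vertices; ++i) {
    int r = find(i);
    auto it = relabel.find(r);
    if (it == relabel.end()) {
      int id = (int)relabel.size() + 1;
      relabel.emplace(r, id);
      out[i] = id;
    } else out[i] = it->second;
  }
  return out;
}
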