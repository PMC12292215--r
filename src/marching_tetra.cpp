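#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Isosurface extraction by marching tetrahedra: each grid cube is split
// into six tetrahedra sharing the main diagonal, and the zero level set of
// the linearly interpolated field is triangulated per tetrahedron. Solid
// convention: field > 0 inside. Returns a triangle soup.

static const int CUBE[8][3] = {
  {0,0,0}, {1,0,0}, {1,1,0}, {0,1,0},
  {0,0,1}, {1,0,1}, {1,1,1}, {0,1,1}
};

// Six tetrahedra around the 0-6 diagonal; all share vertices 0 and 6.
static const int TETS[6][4] = {
  {0,5,1,6}, {0,1,2,6}, {0,2,3,6}, {0,3,7,6}, {0,7,4,6}, {0,4,5,6}
};

struct V3 { double x, y, z; };

static inline V3 lerp_zero(const V3& a, const V3& b, double fa, double fb) {
  double t = fa / (fa - fb);
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  V3 r;
  r.x = a.x + t * (b.x - a.x);
  r.y = a.y + t * (b.y - a.y);
  r.z = a.z + t * (b.z - a.z);
  return r;
}

static inline double tri_area2(const V3& a, const V3& b, const V3& c) {
  double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
  double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
  double cx = uy * vz - uz * vy;
  double cy = uz * vx - ux * vz;
  double cz = ux * vy - uy * vx;
  return cx * cx + cy * cy + cz * cz; // squared twice-area
}

// [[Rcpp::export(name = ".march_tetra")]]
List march_tetra(NumericVector field, IntegerVector dims,
                 NumericVector origin, double spacing,
                 double degenerate_tol = 1e-12) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> verts; // flat x,y,z triplets
  const double* F = REAL(field);
  const double tol2 = degenerate_tol * degenerate_tol;

  V3 p[8];
  double f[8];
  V3 tv[4];
  double tf[4];
  int ins[4], outs[4];

  for (int k = 0; k + 1 < nz; ++k)
  for (int j = 0; j + 1 < ny; ++j)
  for (int i = 0; i + 1 < nx; ++i) {
    bool any_pos = false, any_neg = false;
    for (int c = 0; c < 8; ++c) {
      int ii = i + CUBE[c][0], jj = j + CUBE[c][1], kk = k + CUBE[c][2];
      double v = F[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
      f[c] = v;
      p[c].x = origin[0] + ii * spacing;
      p[c].y = origin[1] + jj * spacing;
      p[c].z = origin[2] + kk * spacing;
      if (v > 0) any_pos = true; else any_neg = true;
    }
    if (!any_pos || !any_neg) continue;

    for (int t = 0; t < 6; ++t) {
      int nin = 0, nout = 0;
      for (int v = 0; v < 4; ++v) {
        int c = TETS[t][v];
        tv[v] = p[c];
        tf[v] = f[c];
        if (f[c] > 0) ins[nin++] = v; else outs[nout++] = v;
      }
      if (nin == 0 || nin == 4) continue;

      V3 q[4];
      int nq = 0;
      if (nin == 1) {
        for (int o = 0; o < 3; ++o)
          q[nq++] = lerp_zero(tv[ins[0]], tv[outs[o]], tf[ins[0]], tf[outs[o]]);
      } else if (nin == 3) {
        for (int s = 0; s < 3; ++s)
          q[nq++] = lerp_zero(tv[ins[s]], tv[outs[0]], tf[ins[s]], tf[outs[0]]);
      } else { // 2 in, 2 out -> quad split into two triangles
        q[nq++] = lerp_zero(tv[ins[0]], tv[outs[0]], tf[ins[0]], tf[outs[0]]);
        q[nq++] = lerp_zero(tv[ins[0]], tv[outs[1]], tf[ins[0]], tf[outs[1]]);
        q[nq++] = lerp_zero(tv[ins[1]], tv[outs[1]], tf[ins[1]], tf[outs[1]]);
        q[nq++] = lerp_zero(tv[ins[1]], tv[outs[0]], tf[ins[1]], tf[outs[0]]);
      }
      // emit triangle(s), dropping degenerates
      const int tris1[3] = {0, 1, 2};
      if (tri_area2(q[tris1[0]], q[tris1[1]], q[tris1[2]]) > tol2) {
        for (int v = 0; v < 3; ++v) {
          verts.push_back(q[tris1[v]].x);
          verts.push_back(q[tris1[v]].y);
          verts.push_back(q[tris1[v]].z);
        }
      }
      if (nq == 4) {
        const int tris2[3] = {0, 2, 3};
        if (tri_area2(q[tris2[0]], q[tris2[1]], q[tris2[2]]) > tol2) {
          for (int v = 0; v < 3; ++v) {
            verts.push_back(q[tris2[v]].x);
            verts.push_back(q[tris2[v]].y);
            verts.push_back(q[tris2[v]].z);
          }
        }
      }
    }
  }

  const R_xlen_t nv = (R_xlen_t)verts.size() / 3;
  NumericMatrix vm(nv, 3);
  for (R_xlen_t r = 0; r < nv; ++r) {
    vm(r, 0) = verts[3 * r];
    vm(r, 1) = verts[3 * r + 1];
    vm(r, 2) = verts[3 * r + 2];
  }
  const R_xlen_t nf = nv / 3;
  IntegerMatrix fm(nf, 3);
  for (R_xlen_t r = 0; r < nf; ++r) {
    fm(r, 0) = 3 * r + 1;
    fm(r, 1) = 3 * r + 2;
    fm(r, 2) = 3 * r + 3;
  }
  return List::create(Named("vertices") = vm, Named("faces") = fm);
}
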