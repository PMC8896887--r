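// Incremental Bowyer-Watson Delaunay triangulation in 2D and 3D.
// Containment uses orientation-corrected insphere/incircle determinant
// predicates; robustness for the modest point counts handled here comes
// from a deterministic sub-femto jitter rather than exact arithmetic.

#include "delaunay.h"
#include <cmath>
#include <cstdint>
#include <map>
#include <stdexcept>
#include <limits>
#include <algorithm>

namespace {

// deterministic per-index jitter in [-1,1) (splitmix64-style hash)
double hash_jitter(std::uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  x = x ^ (x >> 31);
  return (double)(x >> 11) / (double)(1ULL << 53) * 2.0 - 1.0;
}

inline long double det3(long double a, long double b, long double c,
                        long double d, long double e, long double f,
                        long double g, long double h, long double i) {
  return a * (e * i - f * h) - b * (d * i - f * g) + c * (d * h - e * g);
}

double orient3d(const double* pa, const double* pb, const double* pc, const double* pd) {
  return (double)det3(pb[0]-pa[0], pb[1]-pa[1], pb[2]-pa[2],
                      pc[0]-pa[0], pc[1]-pa[1], pc[2]-pa[2],
                      pd[0]-pa[0], pd[1]-pa[1], pd[2]-pa[2]);
}

// > 0 when pe lies inside the circumsphere of positively oriented (pa..pd)
double insphere(const double* pa, const double* pb, const double* pc,
                const double* pd, const double* pe) {
  long double ae[3], be[3], ce[3], de[3];
  for (int i = 0; i < 3; ++i) {
    ae[i] = (long double)pa[i]-pe[i]; be[i] = (long double)pb[i]-pe[i];
    ce[i] = (long double)pc[i]-pe[i]; de[i] = (long double)pd[i]-pe[i];
  }
  long double a2 = ae[0]*ae[0]+ae[1]*ae[1]+ae[2]*ae[2];
  long double b2 = be[0]*be[0]+be[1]*be[1]+be[2]*be[2];
  long double c2 = ce[0]*ce[0]+ce[1]*ce[1]+ce[2]*ce[2];
  long double d2 = de[0]*de[0]+de[1]*de[1]+de[2]*de[2];
  // 4x4 determinant expanded along the last column
  long double m1 = det3(be[0],be[1],be[2], ce[0],ce[1],ce[2], de[0],de[1],de[2]);
  long double m2 = det3(ae[0],ae[1],ae[2], ce[0],ce[1],ce[2], de[0],de[1],de[2]);
  long double m3 = det3(ae[0],ae[1],ae[2], be[0],be[1],be[2], de[0],de[1],de[2]);
  long double m4 = det3(ae[0],ae[1],ae[2], be[0],be[1],be[2], ce[0],ce[1],ce[2]);
  return (double)(a2 * m1 - b2 * m2 + c2 * m3 - d2 * m4);
}

struct Tet {
  int v[4];
  double orient;   // cached orientation sign
  bool alive;
};

struct Face {
  int a, b, c;
  Face(int x, int y, int z) {
    if (x > y) std::swap(x, y);
    if (y > z) std::swap(y, z);
    if (x > y) std::swap(x, y);
    a = x; b = y; c = z;
  }
  bool operator<(const Face& o) const {
    if (a != o.a) return a < o.a;
    if (b != o.b) return b < o.b;
    return c < o.c;
  }
};

} // namespace

std::vector<std::pair<int,int> > delaunay3_edges(const std::vector<double>& pts_in,
                                                 int n,
                                                 std::vector<int>* hull_vertices,
                                                 std::vector<std::pair<int,int> >* hull_edges) {
  if (n < 4) throw std::runtime_error("need at least 4 points for a 3D triangulation");
  double lo[3] = {1e300,1e300,1e300}, hi[3] = {-1e300,-1e300,-1e300};
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], pts_in[3*i+d]);
      hi[d] = std::max(hi[d], pts_in[3*i+d]);
    }
  double diag = 0.0;
  for (int d = 0; d < 3; ++d) diag = std::max(diag, hi[d]-lo[d]);
  if (diag <= 0) throw std::runtime_error("degenerate input: all points coincide");

  // near-coplanarity check via the covariance determinant
  {
    double mean[3] = {0,0,0};
    for (int i = 0; i < n; ++i) for (int d = 0; d < 3; ++d) mean[d] += pts_in[3*i+d];
    for (int d = 0; d < 3; ++d) mean[d] /= n;
    double C[6] = {0,0,0,0,0,0};
    for (int i = 0; i < n; ++i) {
      double x = pts_in[3*i]-mean[0], y = pts_in[3*i+1]-mean[1], z = pts_in[3*i+2]-mean[2];
      C[0]+=x*x; C[1]+=x*y; C[2]+=x*z; C[3]+=y*y; C[4]+=y*z; C[5]+=z*z;
    }
    double det = C[0]*(C[3]*C[5]-C[4]*C[4]) - C[1]*(C[1]*C[5]-C[4]*C[2])
               + C[2]*(C[1]*C[4]-C[3]*C[2]);
    double tr = C[0]+C[3]+C[5];
    if (det < 1e-20 * tr * tr * tr + 1e-300)
      throw std::runtime_error("degenerate (coplanar) point set");
  }

  std::vector<double> P(pts_in);
  double jit = 1e-8 * diag;
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d)
      P[3*i+d] += jit * hash_jitter((std::uint64_t)i * 3u + d);

  double cx = 0.5*(lo[0]+hi[0]), cy = 0.5*(lo[1]+hi[1]), cz = 0.5*(lo[2]+hi[2]);
  // Regular enclosing tetrahedron (inscribed ball radius R/3 covers the
  // data ball), rotated by a generic rotation so that no super edge is
  // parallel to a coordinate axis (symmetric placements create exactly
  // degenerate configurations with gridded inputs).
  double R = 1.0e4 * diag;
  double dir[4][3] = {{1,1,1}, {1,-1,-1}, {-1,1,-1}, {-1,-1,1}};
  double ca = std::cos(0.73), sa = std::sin(0.73);
  double cb = std::cos(0.41), sb = std::sin(0.41);
  P.resize(3 * (n + 4));
  for (int k = 0; k < 4; ++k) {
    double x = dir[k][0] / std::sqrt(3.0), y = dir[k][1] / std::sqrt(3.0),
           z = dir[k][2] / std::sqrt(3.0);
    double x1 = ca * x - sa * y, y1 = sa * x + ca * y;        // rotate about z
    double y2 = cb * y1 - sb * z, z2 = sb * y1 + cb * z;      // rotate about x
    P[3*(n+k)]   = cx + R * x1;
    P[3*(n+k)+1] = cy + R * y2;
    P[3*(n+k)+2] = cz + R * z2;
  }

  std::vector<Tet> tets;
  {
    Tet t; t.v[0]=n; t.v[1]=n+1; t.v[2]=n+2; t.v[3]=n+3; t.alive = true;
    t.orient = orient3d(&P[3*t.v[0]], &P[3*t.v[1]], &P[3*t.v[2]], &P[3*t.v[3]]);
    tets.push_back(t);
  }

  for (int ip = 0; ip < n; ++ip) {
    const double* p = &P[3*ip];
    std::map<Face, int> faceCount;
    bool found = false;
    for (size_t it = 0; it < tets.size(); ++it) {
      if (!tets[it].alive) continue;
      Tet& t = tets[it];
      double val = insphere(&P[3*t.v[0]], &P[3*t.v[1]], &P[3*t.v[2]], &P[3*t.v[3]], p);
      bool inside = (t.orient > 0) ? (val > 0) : (val < 0);
      if (std::fabs(t.orient) < 1e-300) inside = true;  // flat sliver: absorb
      if (!inside) continue;
      found = true;
      t.alive = false;
      faceCount[Face(t.v[0],t.v[1],t.v[2])]++;
      faceCount[Face(t.v[0],t.v[1],t.v[3])]++;
      faceCount[Face(t.v[0],t.v[2],t.v[3])]++;
      faceCount[Face(t.v[1],t.v[2],t.v[3])]++;
    }
    if (!found) throw std::runtime_error("Delaunay insertion failed (point outside all circumspheres)");
    for (std::map<Face,int>::iterator f = faceCount.begin(); f != faceCount.end(); ++f) {
      if (f->second != 1) continue;
      Tet nt;
      nt.v[0] = f->first.a; nt.v[1] = f->first.b; nt.v[2] = f->first.c; nt.v[3] = ip;
      nt.alive = true;
      nt.orient = orient3d(&P[3*nt.v[0]], &P[3*nt.v[1]], &P[3*nt.v[2]], &P[3*nt.v[3]]);
      tets.push_back(nt);
    }
    // compact occasionally to keep scans short
    if (tets.size() > 64u && ip % 16 == 15) {
      std::vector<Tet> keep;
      keep.reserve(tets.size());
      for (size_t it = 0; it < tets.size(); ++it)
        if (tets[it].alive) keep.push_back(tets[it]);
      tets.swap(keep);
    }
  }

  std::map<std::pair<int,int>, int> edgeSet;
  std::map<Face, int> faceCountFinal;
  for (size_t it = 0; it < tets.size(); ++it) {
    if (!tets[it].alive) continue;
    const int* v = tets[it].v;
    bool super = false;
    for (int k = 0; k < 4; ++k) if (v[k] >= n) { super = true; break; }
    if (super) continue;
    for (int a = 0; a < 4; ++a)
      for (int b = a+1; b < 4; ++b) {
        int i = v[a], j = v[b];
        if (i > j) std::swap(i, j);
        edgeSet[std::make_pair(i,j)] = 1;
      }
    faceCountFinal[Face(v[0],v[1],v[2])]++;
    faceCountFinal[Face(v[0],v[1],v[3])]++;
    faceCountFinal[Face(v[0],v[2],v[3])]++;
    faceCountFinal[Face(v[1],v[2],v[3])]++;
  }
  if (edgeSet.empty())
    throw std::runtime_error("triangulation produced no interior tetrahedra");
  if (hull_vertices || hull_edges) {
    std::vector<char> on(n, 0);
    std::map<std::pair<int,int>, int> he;
    for (std::map<Face,int>::iterator f = faceCountFinal.begin(); f != faceCountFinal.end(); ++f)
      if (f->second == 1) {
        on[f->first.a]=1; on[f->first.b]=1; on[f->first.c]=1;
        he[std::make_pair(f->first.a, f->first.b)] = 1;
        he[std::make_pair(f->first.a, f->first.c)] = 1;
        he[std::make_pair(f->first.b, f->first.c)] = 1;
      }
    if (hull_vertices) {
      hull_vertices->clear();
      for (int i = 0; i < n; ++i) if (on[i]) hull_vertices->push_back(i);
    }
    if (hull_edges) {
      hull_edges->clear();
      for (std::map<std::pair<int,int>,int>::iterator e = he.begin(); e != he.end(); ++e)
        hull_edges->push_back(e->first);
    }
  }
  std::vector<std::pair<int,int> > edges;
  edges.reserve(edgeSet.size());
  for (std::map<std::pair<int,int>,int>::iterator e = edgeSet.begin(); e != edgeSet.end(); ++e)
    edges.push_back(e->first);
  return edges;
}

// ------------------------------ 2D ------------------------------

namespace {

double orient2d(const double* pa, const double* pb, const double* pc) {
  return (double)(((long double)pb[0]-pa[0]) * ((long double)pc[1]-pa[1])
                - ((long double)pb[1]-pa[1]) * ((long double)pc[0]-pa[0]));
}

// > 0 when pd lies inside the circumcircle of counter-clockwise (pa,pb,pc)
double incircle(const double* pa, const double* pb, const double* pc, const double* pd) {
  long double ad[2] = {(long double)pa[0]-pd[0], (long double)pa[1]-pd[1]};
  long double bd[2] = {(long double)pb[0]-pd[0], (long double)pb[1]-pd[1]};
  long double cd[2] = {(long double)pc[0]-pd[0], (long double)pc[1]-pd[1]};
  long double a2 = ad[0]*ad[0]+ad[1]*ad[1];
  long double b2 = bd[0]*bd[0]+bd[1]*bd[1];
  long double c2 = cd[0]*cd[0]+cd[1]*cd[1];
  return (double)(a2 * (bd[0]*cd[1] - cd[0]*bd[1])
                - b2 * (ad[0]*cd[1] - cd[0]*ad[1])
                + c2 * (ad[0]*bd[1] - bd[0]*ad[1]));
}

struct Tri2 {
  int v[3];
  double orient;
  bool alive;
};

} // namespace

std::vector<int> delaunay2_tris(const std::vector<double>& pts_in, int n) {
  if (n < 3) throw std::runtime_error("need at least 3 points for a 2D triangulation");
  double lo[2] = {1e300,1e300}, hi[2] = {-1e300,-1e300};
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 2; ++d) {
      lo[d] = std::min(lo[d], pts_in[2*i+d]);
      hi[d] = std::max(hi[d], pts_in[2*i+d]);
    }
  double diag = std::max(hi[0]-lo[0], hi[1]-lo[1]);
  if (diag <= 0) throw std::runtime_error("degenerate input: all points coincide");
  std::vector<double> P(pts_in);
  double jit = 1e-9 * diag;
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 2; ++d)
      P[2*i+d] += jit * hash_jitter((std::uint64_t)i * 2u + d + 77u);
  double cx0 = 0.5*(lo[0]+hi[0]), cy0 = 0.5*(lo[1]+hi[1]);
  // equilateral enclosing triangle (inscribed circle R/2), generic rotation
  double R = 1.0e4 * diag;
  P.resize(2*(n+3));
  for (int k = 0; k < 3; ++k) {
    double a = 2.0 * M_PI * k / 3.0 + 0.57;
    P[2*(n+k)]   = cx0 + R * std::cos(a);
    P[2*(n+k)+1] = cy0 + R * std::sin(a);
  }

  std::vector<Tri2> tris;
  {
    Tri2 t; t.v[0]=n; t.v[1]=n+1; t.v[2]=n+2; t.alive = true;
    t.orient = orient2d(&P[2*t.v[0]], &P[2*t.v[1]], &P[2*t.v[2]]);
    tris.push_back(t);
  }
  for (int ip = 0; ip < n; ++ip) {
    const double* p = &P[2*ip];
    std::map<std::pair<int,int>, int> edgeCount;
    bool found = false;
    for (size_t it = 0; it < tris.size(); ++it) {
      if (!tris[it].alive) continue;
      Tri2& t = tris[it];
      double val = incircle(&P[2*t.v[0]], &P[2*t.v[1]], &P[2*t.v[2]], p);
      bool inside = (t.orient > 0) ? (val > 0) : (val < 0);
      if (std::fabs(t.orient) < 1e-300) inside = true;
      if (!inside) continue;
      found = true;
      t.alive = false;
      for (int e = 0; e < 3; ++e) {
        int a = t.v[e], b = t.v[(e+1)%3];
        if (a > b) std::swap(a, b);
        edgeCount[std::make_pair(a,b)]++;
      }
    }
    if (!found) throw std::runtime_error("Delaunay insertion failed");
    for (std::map<std::pair<int,int>,int>::iterator e = edgeCount.begin(); e != edgeCount.end(); ++e) {
      if (e->second != 1) continue;
      Tri2 nt;
      nt.v[0] = e->first.first; nt.v[1] = e->first.second; nt.v[2] = ip;
      nt.alive = true;
      nt.orient = orient2d(&P[2*nt.v[0]], &P[2*nt.v[1]], &P[2*nt.v[2]]);
      tris.push_back(nt);
    }
    if (tris.size() > 64u && ip % 16 == 15) {
      std::vector<Tri2> keep;
      keep.reserve(tris.size());
      for (size_t it = 0; it < tris.size(); ++it)
        if (tris[it].alive) keep.push_back(tris[it]);
      tris.swap(keep);
    }
  }
  std::vector<int> out;
  for (size_t it = 0; it < tris.size(); ++it) {
    if (!tris[it].alive) continue;
    const int* v = tris[it].v;
    if (v[0] >= n || v[1] >= n || v[2] >= n) continue;
    out.push_back(v[0]); out.push_back(v[1]); out.push_back(v[2]);
  }
  if (out.empty()) throw std::runtime_error("triangulation produced no interior triangles");
  return out;
}
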