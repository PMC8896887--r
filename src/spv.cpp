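// 2D self-propelled Voronoi dynamics in a periodic box: shape-energy
// forces through the Voronoi tessellation (chain rule via circumcenter
// Jacobians) plus persistent active motion with rotational diffusion.

#include <Rcpp.h>
#include "delaunay.h"
#include <cmath>
#include <vector>
#include <algorithm>
#include <random>

using namespace Rcpp;

namespace {

struct Repl {
  std::vector<double> pts;   // replicated coordinates, xy interleaved
  std::vector<int> base;     // base index per replicated point
  std::vector<int> base_rep; // index of the (0,0)-image of each base point
};

// Replicate points near the boundary so the central copies see correct
// periodic neighbours. margin in absolute units.
Repl replicate_margin(const std::vector<double>& x, const std::vector<double>& y,
                      double box, double margin) {
  Repl r;
  int n = (int)x.size();
  r.base_rep.resize(n);
  for (int i = 0; i < n; ++i) {
    r.base_rep[i] = (int)r.base.size();
    r.pts.push_back(x[i]); r.pts.push_back(y[i]); r.base.push_back(i);
  }
  for (int i = 0; i < n; ++i)
    for (int ox = -1; ox <= 1; ++ox)
      for (int oy = -1; oy <= 1; ++oy) {
        if (ox == 0 && oy == 0) continue;
        double px = x[i] + ox * box, py = y[i] + oy * box;
        if (px > -margin && px < box + margin && py > -margin && py < box + margin) {
          r.pts.push_back(px); r.pts.push_back(py); r.base.push_back(i);
        }
      }
  return r;
}

struct Star {
  std::vector<int> tri;      // ordered incident triangle ids
  double A, P;
};

double circum(const double* a, const double* b, const double* c, double* out) {
  double d = 2.0 * (a[0]*(b[1]-c[1]) + b[0]*(c[1]-a[1]) + c[0]*(a[1]-b[1]));
  double a2 = a[0]*a[0]+a[1]*a[1], b2 = b[0]*b[0]+b[1]*b[1], c2 = c[0]*c[0]+c[1]*c[1];
  out[0] = (a2*(b[1]-c[1]) + b2*(c[1]-a[1]) + c2*(a[1]-b[1])) / d;
  out[1] = (a2*(c[0]-b[0]) + b2*(a[0]-c[0]) + c2*(b[0]-a[0])) / d;
  return d;
}

struct Tess {
  std::vector<int> tris;                 // triangle vertex triples (replicated ids)
  std::vector<double> cc;                // circumcenters per triangle
  std::vector<Star> stars;               // per base cell
  bool ok;
};

// Build tessellation geometry: per-base-cell ordered Voronoi polygon.
Tess build_tess(const Repl& R, int n_base) {
  Tess T;
  T.ok = true;
  int m = (int)R.pts.size() / 2;
  T.tris = delaunay2_tris(R.pts, m);
  int nt = (int)T.tris.size() / 3;
  T.cc.resize(2 * nt);
  for (int t = 0; t < nt; ++t) {
    circum(&R.pts[2*T.tris[3*t]], &R.pts[2*T.tris[3*t+1]], &R.pts[2*T.tris[3*t+2]],
           &T.cc[2*t]);
  }
  // incidence of base replicas
  T.stars.assign(n_base, Star());
  std::vector<std::vector<int> > inc(m);
  for (int t = 0; t < nt; ++t)
    for (int k = 0; k < 3; ++k) inc[T.tris[3*t+k]].push_back(t);
  for (int i = 0; i < n_base; ++i) {
    int rep = R.base_rep[i];
    std::vector<int>& tr = inc[rep];
    if (tr.size() < 3) { T.ok = false; return T; }
    double gx = R.pts[2*rep], gy = R.pts[2*rep+1];
    std::vector<std::pair<double,int> > byang;
    for (size_t k = 0; k < tr.size(); ++k) {
      double ang = std::atan2(T.cc[2*tr[k]+1] - gy, T.cc[2*tr[k]] - gx);
      byang.push_back(std::make_pair(ang, tr[k]));
    }
    std::sort(byang.begin(), byang.end());
    Star st;
    for (size_t k = 0; k < byang.size(); ++k) st.tri.push_back(byang[k].second);
    // polygon area / perimeter
    int nv = (int)st.tri.size();
    double A = 0, P = 0;
    for (int k = 0; k < nv; ++k) {
      const double* h = &T.cc[2*st.tri[k]];
      const double* hn = &T.cc[2*st.tri[(k+1)%nv]];
      A += h[0]*hn[1] - hn[0]*h[1];
      P += std::sqrt((hn[0]-h[0])*(hn[0]-h[0]) + (hn[1]-h[1])*(hn[1]-h[1]));
    }
    st.A = 0.5 * std::fabs(A);
    st.P = P;
    T.stars[i] = st;
  }
  return T;
}

} // namespace

// [[Rcpp::export]]
List cpp_voronoi_geom(NumericMatrix centers, double box, double margin) {
  int n = centers.nrow();
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = centers(i,0); y[i] = centers(i,1); }
  Repl R = replicate_margin(x, y, box, margin);
  Tess T = build_tess(R, n);
  if (!T.ok) stop("degenerate tessellation; increase the margin");
  NumericVector A(n), P(n);
  for (int i = 0; i < n; ++i) { A[i] = T.stars[i].A; P[i] = T.stars[i].P; }
  // neighbour pairs from Delaunay edges touching base replicas
  std::vector<std::pair<int,int> > nb;
  int nt = (int)T.tris.size() / 3;
  for (int t = 0; t < nt; ++t)
    for (int k = 0; k < 3; ++k) {
      int a = T.tris[3*t+k], b = T.tris[3*t+(k+1)%3];
      int ba = R.base[a], bb = R.base[b];
      if (ba == bb) continue;
      int lo = std::min(ba, bb), hi = std::max(ba, bb);
      nb.push_back(std::make_pair(lo, hi));
    }
  std::sort(nb.begin(), nb.end());
  nb.erase(std::unique(nb.begin(), nb.end()), nb.end());
  IntegerMatrix NB((int)nb.size(), 2);
  for (size_t k = 0; k < nb.size(); ++k) {
    NB(k,0) = nb[k].first + 1; NB(k,1) = nb[k].second + 1;
  }
  return List::create(_["area"] = A, _["perimeter"] = P, _["neighbors"] = NB);
}

// [[Rcpp::export]]
List cpp_spv_run(NumericMatrix centers, NumericVector theta_in,
                 NumericVector A0, NumericVector P0,
                 double KA, double KP, double box,
                 double v0, double Dr, double dt, double mobility,
                 int nsteps, bool shape_forces, double margin, int seed,
                 bool wrap) {
  int n = centers.nrow();
  std::vector<double> x(n), y(n), th(n);
  for (int i = 0; i < n; ++i) {
    x[i] = centers(i,0); y[i] = centers(i,1); th[i] = theta_in[i];
  }
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::vector<double> fx(n), fy(n);
  double sq = std::sqrt(2.0 * Dr * dt);
  double eps = 1e-6 * box;

  for (int s = 0; s < nsteps; ++s) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    if (shape_forces) {
      Repl R = replicate_margin(x, y, box, margin);
      Tess T = build_tess(R, n);
      if (!T.ok) stop("degenerate tessellation during SPV run");
      int nt = (int)T.tris.size() / 3;
      // accumulate dE/dh per triangle instance from each base cell's star
      std::vector<double> dEdh(2 * nt, 0.0);
      for (int i = 0; i < n; ++i) {
        const Star& st = T.stars[i];
        int nv = (int)st.tri.size();
        double cA = 2.0 * KA * (st.A - A0[i]);
        double cP = 2.0 * KP * (st.P - P0[i]);
        // polygon orientation for the area derivative
        double Asig = 0;
        for (int k = 0; k < nv; ++k) {
          const double* h = &T.cc[2*st.tri[k]];
          const double* hn = &T.cc[2*st.tri[(k+1)%nv]];
          Asig += h[0]*hn[1] - hn[0]*h[1];
        }
        double sgn = (Asig >= 0) ? 1.0 : -1.0;
        for (int k = 0; k < nv; ++k) {
          int t = st.tri[k];
          const double* h  = &T.cc[2*t];
          const double* hp = &T.cc[2*st.tri[(k-1+nv)%nv]];
          const double* hn = &T.cc[2*st.tri[(k+1)%nv]];
          double dAx = 0.5 * sgn * (hn[1] - hp[1]);
          double dAy = 0.5 * sgn * (hp[0] - hn[0]);
          double lp = std::sqrt((h[0]-hp[0])*(h[0]-hp[0]) + (h[1]-hp[1])*(h[1]-hp[1]));
          double ln = std::sqrt((h[0]-hn[0])*(h[0]-hn[0]) + (h[1]-hn[1])*(h[1]-hn[1]));
          double dPx = 0, dPy = 0;
          if (lp > 1e-14) { dPx += (h[0]-hp[0])/lp; dPy += (h[1]-hp[1])/lp; }
          if (ln > 1e-14) { dPx += (h[0]-hn[0])/ln; dPy += (h[1]-hn[1])/ln; }
          dEdh[2*t]   += cA * dAx + cP * dPx;
          dEdh[2*t+1] += cA * dAy + cP * dPy;
        }
      }
      // chain rule through circumcenters (numeric Jacobian per generator)
      for (int t = 0; t < nt; ++t) {
        double gx = dEdh[2*t], gy = dEdh[2*t+1];
        if (gx == 0.0 && gy == 0.0) continue;
        double p[3][2];
        for (int k = 0; k < 3; ++k) {
          p[k][0] = R.pts[2*T.tris[3*t+k]];
          p[k][1] = R.pts[2*T.tris[3*t+k]+1];
        }
        for (int k = 0; k < 3; ++k) {
          int bi = R.base[T.tris[3*t+k]];
          double hplus[2], hminus[2], save;
          double J[2][2];
          for (int d = 0; d < 2; ++d) {
            save = p[k][d];
            p[k][d] = save + eps;
            circum(p[0], p[1], p[2], hplus);
            p[k][d] = save - eps;
            circum(p[0], p[1], p[2], hminus);
            p[k][d] = save;
            J[0][d] = (hplus[0] - hminus[0]) / (2 * eps);
            J[1][d] = (hplus[1] - hminus[1]) / (2 * eps);
          }
          fx[bi] -= J[0][0] * gx + J[1][0] * gy;
          fy[bi] -= J[0][1] * gx + J[1][1] * gy;
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      x[i] += dt * (mobility * fx[i] + v0 * std::cos(th[i]));
      y[i] += dt * (mobility * fy[i] + v0 * std::sin(th[i]));
      if (wrap) {
        x[i] -= box * std::floor(x[i] / box);
        y[i] -= box * std::floor(y[i] / box);
      }
      th[i] += sq * gauss(rng);
    }
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix out(n, 2);
  NumericVector thout(n);
  for (int i = 0; i < n; ++i) { out(i,0) = x[i]; out(i,1) = y[i]; thout[i] = th[i]; }
  return List::create(_["centers"] = out, _["theta"] = thout);
}
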