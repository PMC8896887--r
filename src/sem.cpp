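// Subcellular-element cell-sorting engine: Morse inter-element forces,
// per-cell Delaunay cortex-tension network with interfacial scaling and
// sinusoidal tension modulation, first-order overdamped integration.

#include <Rcpp.h>
#include "delaunay.h"
#include <cmath>
#include <vector>
#include <stdexcept>

using namespace Rcpp;

namespace {

struct SemParams {
  double gamma_cm, adhesion_AM, beta, epsilon, delta_epi, tau;
  double morse_depth, morse_range, morse_req;
  double drag, dt;
  double cutoff;            // Morse pair cutoff
  double tension_max_edge;  // cortex-network edge length cutoff for tension
  double cone_deg;          // cortex-identification cone half-angle
  double s_ee, s_pp, s_het; // interfacial cortical-tension scales by pair type
  double adhesion_gain;     // calibration of the adhesive well depth
};

SemParams read_params(const List& cfg) {
  SemParams p;
  p.gamma_cm     = as<double>(cfg["gamma_cm"]);
  p.adhesion_AM  = as<double>(cfg["adhesion_AM"]);
  p.beta         = as<double>(cfg["beta"]);
  p.epsilon      = as<double>(cfg["epsilon"]);
  p.delta_epi    = as<double>(cfg["delta_epi"]);
  p.tau          = as<double>(cfg["tau"]);
  p.morse_depth  = as<double>(cfg["morse_depth"]);
  p.morse_range  = as<double>(cfg["morse_range"]);
  p.morse_req    = as<double>(cfg["morse_req"]);
  p.drag         = as<double>(cfg["drag"]);
  p.dt           = as<double>(cfg["dt"]);
  p.cutoff           = cfg.containsElementNamed("cutoff") ? as<double>(cfg["cutoff"]) : 2.0 * p.morse_req;
  p.tension_max_edge = cfg.containsElementNamed("tension_max_edge") ? as<double>(cfg["tension_max_edge"]) : 2.5 * p.morse_req;
  p.cone_deg         = cfg.containsElementNamed("cone_deg") ? as<double>(cfg["cone_deg"]) : 20.0;
  p.adhesion_gain    = cfg.containsElementNamed("adhesion_gain") ? as<double>(cfg["adhesion_gain"]) : 1.0;
  p.s_pp = cfg.containsElementNamed("s_pp") ? as<double>(cfg["s_pp"]) : 1.0;
  p.s_ee = cfg.containsElementNamed("s_ee") ? as<double>(cfg["s_ee"]) : p.s_pp * p.beta;
  p.s_het = cfg.containsElementNamed("s_het") ? as<double>(cfg["s_het"]) : 0.5 * (p.s_ee + p.s_pp);
  return p;
}

inline double morse_force(double r, double depth, double range, double req) {
  double e1 = std::exp(-range * (r - req));
  return 2.0 * depth * range * (e1 * e1 - e1);  // positive = repulsive
}

// Cortex identification: an element is cortical when no element of the same
// cell lies radially beyond it within a cone of half-angle cone_deg about
// its direction from the cell centroid; convex-hull vertices are always
// cortical.
std::vector<char> identify_cortex(const std::vector<double>& pos,
                                  const std::vector<int>& members,
                                  double cone_deg, bool with_hull = true) {
  int m = (int)members.size();
  std::vector<char> out(m, 0);
  if (m == 1) { out[0] = 1; return out; }
  double cx = 0, cy = 0, cz = 0;
  for (int k = 0; k < m; ++k) {
    cx += pos[3*members[k]]; cy += pos[3*members[k]+1]; cz += pos[3*members[k]+2];
  }
  cx /= m; cy /= m; cz /= m;
  std::vector<double> vx(m), vy(m), vz(m), r(m);
  for (int k = 0; k < m; ++k) {
    vx[k] = pos[3*members[k]] - cx;
    vy[k] = pos[3*members[k]+1] - cy;
    vz[k] = pos[3*members[k]+2] - cz;
    r[k] = std::sqrt(vx[k]*vx[k] + vy[k]*vy[k] + vz[k]*vz[k]);
  }
  double cos_cone = std::cos(cone_deg * M_PI / 180.0);
  for (int k = 0; k < m; ++k) {
    if (r[k] < 1e-12) { out[k] = 0; continue; }
    bool shadowed = false;
    for (int j = 0; j < m; ++j) {
      if (j == k || r[j] <= r[k]) continue;
      double dot = (vx[k]*vx[j] + vy[k]*vy[j] + vz[k]*vz[j]) / (r[k] * r[j]);
      if (dot > cos_cone) { shadowed = true; break; }
    }
    if (!shadowed) out[k] = 1;
  }
  if (with_hull && m >= 4) {
    std::vector<double> sub(3 * m);
    for (int k = 0; k < m; ++k) {
      sub[3*k] = pos[3*members[k]]; sub[3*k+1] = pos[3*members[k]+1]; sub[3*k+2] = pos[3*members[k]+2];
    }
    try {
      std::vector<int> hull;
      delaunay3_edges(sub, m, &hull);
      for (size_t h = 0; h < hull.size(); ++h) out[hull[h]] = 1;
    } catch (...) {
      // degenerate cloud: cone rule alone
    }
  }
  return out;
}

struct Networks {
  std::vector<char> cortex;                 // per element
  std::vector<int> e_a, e_b;                // cortical edges, global indices
  std::vector<double> e_scale;              // interfacial scale per edge
  std::vector<int> p_a, p_b;                // Morse pair list (within cutoff + skin)
};

void build_networks(const std::vector<double>& pos, int n,
                    const std::vector<int>& cell,      // 0-based per element
                    const std::vector<int>& ctype,     // per cell, 0=EPI 1=PrE
                    const SemParams& P, double skin,
                    Networks& net) {
  net.cortex.assign(n, 0);
  net.e_a.clear(); net.e_b.clear(); net.e_scale.clear();
  net.p_a.clear(); net.p_b.clear();
  int n_cells = 0;
  for (int i = 0; i < n; ++i) n_cells = std::max(n_cells, cell[i] + 1);
  std::vector<std::vector<int> > members(n_cells);
  for (int i = 0; i < n; ++i) members[cell[i]].push_back(i);

  // ---- pair list via linked grid ----
  double rl = P.cutoff + skin;
  double lo[3] = {1e300,1e300,1e300}, hi[3] = {-1e300,-1e300,-1e300};
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], pos[3*i+d]);
      hi[d] = std::max(hi[d], pos[3*i+d]);
    }
  int nb[3];
  for (int d = 0; d < 3; ++d) {
    nb[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / rl) + 1);
    nb[d] = std::min(nb[d], 128);
  }
  std::vector<std::vector<int> > grid(nb[0] * (size_t)nb[1] * nb[2]);
  std::vector<int> gidx(n);
  for (int i = 0; i < n; ++i) {
    int g[3];
    for (int d = 0; d < 3; ++d) {
      g[d] = (int)((pos[3*i+d] - lo[d]) / rl);
      if (g[d] < 0) g[d] = 0;
      if (g[d] >= nb[d]) g[d] = nb[d] - 1;
    }
    gidx[i] = g[0] + nb[0] * (g[1] + nb[1] * g[2]);
    grid[gidx[i]].push_back(i);
  }
  double rl2 = rl * rl;
  for (int i = 0; i < n; ++i) {
    int gi = gidx[i];
    int gx = gi % nb[0], gy = (gi / nb[0]) % nb[1], gz = gi / (nb[0] * nb[1]);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int x = gx + dx, y = gy + dy, z = gz + dz;
          if (x < 0 || y < 0 || z < 0 || x >= nb[0] || y >= nb[1] || z >= nb[2]) continue;
          const std::vector<int>& cellv = grid[x + nb[0] * (y + nb[1] * z)];
          for (size_t q = 0; q < cellv.size(); ++q) {
            int j = cellv[q];
            if (j <= i) continue;
            double ddx = pos[3*i]-pos[3*j], ddy = pos[3*i+1]-pos[3*j+1], ddz = pos[3*i+2]-pos[3*j+2];
            if (ddx*ddx + ddy*ddy + ddz*ddz <= rl2) {
              net.p_a.push_back(i);
              net.p_b.push_back(j);
            }
          }
        }
  }

  // ---- cortex flags (cone rule; the hull union is exposed through the
  // API but adds a second per-cell triangulation the dynamics do not need) ----
  for (int c = 0; c < n_cells; ++c) {
    std::vector<char> fl = identify_cortex(pos, members[c], P.cone_deg, false);
    for (size_t k = 0; k < members[c].size(); ++k)
      net.cortex[members[c][k]] = fl[k];
  }

  // ---- heterotypic contact flags: nearest foreign cortex partner type ----
  std::vector<int> partner(n, -1);
  std::vector<double> partner_d2(n, 1e300);
  double ad2 = P.cutoff * P.cutoff;
  for (size_t q = 0; q < net.p_a.size(); ++q) {
    int i = net.p_a[q], j = net.p_b[q];
    if (cell[i] == cell[j] || !net.cortex[i] || !net.cortex[j]) continue;
    double ddx = pos[3*i]-pos[3*j], ddy = pos[3*i+1]-pos[3*j+1], ddz = pos[3*i+2]-pos[3*j+2];
    double d2 = ddx*ddx + ddy*ddy + ddz*ddz;
    if (d2 > ad2) continue;
    if (d2 < partner_d2[i]) { partner_d2[i] = d2; partner[i] = ctype[cell[j]]; }
    if (d2 < partner_d2[j]) { partner_d2[j] = d2; partner[j] = ctype[cell[i]]; }
  }

  // ---- cortical tension edges: boundary triangulation of each cell's
  // cortex cloud (the surface facets of its Delaunay tetrahedralization);
  // interior diagonals are excluded so the edge degree stays ~6 and the
  // tension acts tangentially, like a discrete surface tension ----
  double max_e2 = P.tension_max_edge * P.tension_max_edge;
  for (int c = 0; c < n_cells; ++c) {
    std::vector<int> cx;
    for (size_t k = 0; k < members[c].size(); ++k)
      if (net.cortex[members[c][k]]) cx.push_back(members[c][k]);
    if (cx.size() < 2) continue;
    std::vector<std::pair<int,int> > edges;
    bool ok = false;
    if (cx.size() >= 4) {
      std::vector<double> sub(3 * cx.size());
      for (size_t k = 0; k < cx.size(); ++k) {
        sub[3*k] = pos[3*cx[k]]; sub[3*k+1] = pos[3*cx[k]+1]; sub[3*k+2] = pos[3*cx[k]+2];
      }
      try {
        delaunay3_edges(sub, (int)cx.size(), 0, &edges);
        ok = true;
      } catch (...) { ok = false; }
    }
    if (!ok) {
      // tiny or degenerate cortex: connect all pairs within the cutoff
      edges.clear();
      for (size_t a = 0; a < cx.size(); ++a)
        for (size_t b = a + 1; b < cx.size(); ++b)
          edges.push_back(std::make_pair((int)a, (int)b));
    }
    for (size_t e = 0; e < edges.size(); ++e) {
      int i = cx[edges[e].first], j = cx[edges[e].second];
      double ddx = pos[3*i]-pos[3*j], ddy = pos[3*i+1]-pos[3*j+1], ddz = pos[3*i+2]-pos[3*j+2];
      if (ddx*ddx + ddy*ddy + ddz*ddz <= max_e2) {
        net.e_a.push_back(i); net.e_b.push_back(j);
      }
    }
  }
  // interfacial scale per edge from endpoint contact states: cortical
  // tension is downregulated wherever the cortex adheres to another cell
  // (that reduced interfacial tension sets the contact angle), with the
  // EPI/PrE asymmetry carried by the pair-type scales
  net.e_scale.resize(net.e_a.size());
  for (size_t e = 0; e < net.e_a.size(); ++e) {
    int i = net.e_a[e], j = net.e_b[e];
    int a = ctype[cell[i]];
    double s = 1.0;
    if (partner[i] >= 0 && partner[j] >= 0) {
      double si = (a == 0 && partner[i] == 0) ? P.s_ee : ((a == 1 && partner[i] == 1) ? P.s_pp : P.s_het);
      double sj = (a == 0 && partner[j] == 0) ? P.s_ee : ((a == 1 && partner[j] == 1) ? P.s_pp : P.s_het);
      s = 0.5 * (si + sj);
    }
    net.e_scale[e] = s;
  }
}

// Accumulate forces into F (must be zeroed by caller).
void accumulate_forces(const std::vector<double>& pos, int n,
                       const std::vector<int>& cell,
                       const std::vector<int>& ctype,
                       const std::vector<double>& phase,
                       const SemParams& P, const Networks& net,
                       double t, std::vector<double>& F) {
  double cut2 = P.cutoff * P.cutoff;
  for (size_t q = 0; q < net.p_a.size(); ++q) {
    int i = net.p_a[q], j = net.p_b[q];
    double dx = pos[3*i]-pos[3*j], dy = pos[3*i+1]-pos[3*j+1], dz = pos[3*i+2]-pos[3*j+2];
    double d2 = dx*dx + dy*dy + dz*dz;
    if (d2 > cut2) continue;
    double r = std::sqrt(d2);
    if (r < 1e-12) stop("coincident elements %d and %d", i + 1, j + 1);
    double f;
    if (cell[i] == cell[j]) {
      f = morse_force(r, P.morse_depth, P.morse_range, P.morse_req);
    } else if (net.cortex[i] && net.cortex[j]) {
      f = morse_force(r, P.adhesion_AM * P.adhesion_gain, P.morse_range, P.morse_req);
    } else {
      f = morse_force(r, P.morse_depth, P.morse_range, P.morse_req);
      if (f < 0) f = 0;  // volume exclusion only between non-cortex foreign elements
    }
    double inv = f / r;
    F[3*i]   += inv * dx; F[3*i+1] += inv * dy; F[3*i+2] += inv * dz;
    F[3*j]   -= inv * dx; F[3*j+1] -= inv * dy; F[3*j+2] -= inv * dz;
  }
  double omega = 2.0 * M_PI * 10.0 / P.tau;
  for (size_t e = 0; e < net.e_a.size(); ++e) {
    int i = net.e_a[e], j = net.e_b[e];
    double dx = pos[3*i]-pos[3*j], dy = pos[3*i+1]-pos[3*j+1], dz = pos[3*i+2]-pos[3*j+2];
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (r < 1e-12) continue;
    double di = P.delta_epi * (ctype[cell[i]] == 1 ? (1.0 + P.epsilon) : 1.0);
    double dj = P.delta_epi * (ctype[cell[j]] == 1 ? (1.0 + P.epsilon) : 1.0);
    double mod = 1.0 + 0.5 * (di * std::sin(omega * t + phase[i]) +
                              dj * std::sin(omega * t + phase[j]));
    if (mod < 0) mod = 0;
    double mag = P.gamma_cm * net.e_scale[e] * mod;
    double inv = -mag / r;  // attractive: pull endpoints together
    F[3*i]   += inv * dx; F[3*i+1] += inv * dy; F[3*i+2] += inv * dz;
    F[3*j]   -= inv * dx; F[3*j+1] -= inv * dy; F[3*j+2] -= inv * dz;
  }
  for (int i = 0; i < 3 * n; ++i)
    if (!std::isfinite(F[i]))
      stop("non-finite force on element %d; diagnostic: position (%g, %g, %g)",
           i / 3 + 1, pos[3*(i/3)], pos[3*(i/3)+1], pos[3*(i/3)+2]);
}

} // namespace

// [[Rcpp::export]]
List cpp_delaunay3(NumericMatrix pts) {
  int n = pts.nrow();
  std::vector<double> P(3 * n);
  for (int i = 0; i < n; ++i) {
    P[3*i] = pts(i,0); P[3*i+1] = pts(i,1); P[3*i+2] = pts(i,2);
  }
  std::vector<int> hull;
  std::vector<std::pair<int,int> > edges = delaunay3_edges(P, n, &hull);
  IntegerMatrix E((int)edges.size(), 2);
  for (size_t e = 0; e < edges.size(); ++e) {
    E(e,0) = edges[e].first + 1;
    E(e,1) = edges[e].second + 1;
  }
  IntegerVector H((int)hull.size());
  for (size_t h = 0; h < hull.size(); ++h) H[h] = hull[h] + 1;
  return List::create(_["edges"] = E, _["hull"] = H);
}

// [[Rcpp::export]]
IntegerMatrix cpp_delaunay2(NumericMatrix pts) {
  int n = pts.nrow();
  std::vector<double> P(2 * n);
  for (int i = 0; i < n; ++i) { P[2*i] = pts(i,0); P[2*i+1] = pts(i,1); }
  std::vector<int> tris = delaunay2_tris(P, n);
  int m = (int)tris.size() / 3;
  IntegerMatrix T(m, 3);
  for (int k = 0; k < m; ++k) {
    T(k,0) = tris[3*k] + 1; T(k,1) = tris[3*k+1] + 1; T(k,2) = tris[3*k+2] + 1;
  }
  return T;
}

// [[Rcpp::export]]
LogicalVector cpp_identify_cortex(NumericMatrix pts, double cone_deg) {
  int n = pts.nrow();
  std::vector<double> P(3 * n);
  std::vector<int> members(n);
  for (int i = 0; i < n; ++i) {
    P[3*i] = pts(i,0); P[3*i+1] = pts(i,1); P[3*i+2] = pts(i,2);
    members[i] = i;
  }
  std::vector<char> fl = identify_cortex(P, members, cone_deg);
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = fl[i] != 0;
  return out;
}

// [[Rcpp::export]]
List cpp_sem_forces(NumericMatrix pos_in, IntegerVector cell_in,
                    IntegerVector ctype_in, NumericVector phase_in,
                    List cfg, double t) {
  SemParams P = read_params(cfg);
  int n = pos_in.nrow();
  std::vector<double> pos(3 * n);
  std::vector<int> cell(n);
  std::vector<double> phase(n);
  for (int i = 0; i < n; ++i) {
    pos[3*i] = pos_in(i,0); pos[3*i+1] = pos_in(i,1); pos[3*i+2] = pos_in(i,2);
    cell[i] = cell_in[i] - 1;
    phase[i] = phase_in[i];
  }
  std::vector<int> ctype(ctype_in.begin(), ctype_in.end());
  Networks net;
  build_networks(pos, n, cell, ctype, P, 0.0, net);
  std::vector<double> F(3 * n, 0.0);
  accumulate_forces(pos, n, cell, ctype, phase, P, net, t, F);
  NumericMatrix Fout(n, 3);
  LogicalVector cortex(n);
  for (int i = 0; i < n; ++i) {
    Fout(i,0) = F[3*i]; Fout(i,1) = F[3*i+1]; Fout(i,2) = F[3*i+2];
    cortex[i] = net.cortex[i] != 0;
  }
  IntegerMatrix E((int)net.e_a.size(), 2);
  NumericVector Escale((int)net.e_a.size());
  for (size_t e = 0; e < net.e_a.size(); ++e) {
    E(e,0) = net.e_a[e] + 1; E(e,1) = net.e_b[e] + 1;
    Escale[e] = net.e_scale[e];
  }
  return List::create(_["forces"] = Fout, _["cortex"] = cortex,
                      _["edges"] = E, _["edge_scale"] = Escale);
}

// [[Rcpp::export]]
List cpp_sem_advance(NumericMatrix pos_in, IntegerVector cell_in,
                     IntegerVector ctype_in, NumericVector phase_in,
                     List cfg, double t0, int nsteps, int rebuild_every) {
  SemParams P = read_params(cfg);
  int n = pos_in.nrow();
  std::vector<double> pos(3 * n);
  std::vector<int> cell(n);
  std::vector<double> phase(n);
  for (int i = 0; i < n; ++i) {
    pos[3*i] = pos_in(i,0); pos[3*i+1] = pos_in(i,1); pos[3*i+2] = pos_in(i,2);
    cell[i] = cell_in[i] - 1;
    phase[i] = phase_in[i];
  }
  std::vector<int> ctype(ctype_in.begin(), ctype_in.end());
  Networks net;
  std::vector<double> F(3 * n);
  double t = t0;
  double max_disp = 0.5 * P.morse_req;
  double skin = 0.5 * P.morse_req;
  for (int s = 0; s < nsteps; ++s) {
    if (s % rebuild_every == 0)
      build_networks(pos, n, cell, ctype, P, skin, net);
    // adaptive substepping: rare stiff transients (deep overlaps after
    // division or element insertion) are integrated with a reduced dt
    double remaining = P.dt;
    int guard = 0;
    while (remaining > 0.0) {
      std::fill(F.begin(), F.end(), 0.0);
      accumulate_forces(pos, n, cell, ctype, phase, P, net, t, F);
      double fmax = 0.0;
      for (int i = 0; i < n; ++i) {
        double f2 = F[3*i]*F[3*i] + F[3*i+1]*F[3*i+1] + F[3*i+2]*F[3*i+2];
        if (f2 > fmax) fmax = f2;
      }
      fmax = std::sqrt(fmax);
      double h = remaining / P.drag;
      double dt_sub = remaining;
      if (fmax * h > max_disp) {
        dt_sub = 0.5 * max_disp * P.drag / fmax;
        if (++guard > 64)
          stop("timestep too large: forces do not relax under substepping (max |F| = %.3g)", fmax);
      }
      double hs = dt_sub / P.drag;
      for (int i = 0; i < n; ++i) {
        pos[3*i]   += hs * F[3*i];
        pos[3*i+1] += hs * F[3*i+1];
        pos[3*i+2] += hs * F[3*i+2];
      }
      t += dt_sub;
      remaining -= dt_sub;
    }
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i,0) = pos[3*i]; out(i,1) = pos[3*i+1]; out(i,2) = pos[3*i+2];
  }
  return List::create(_["positions"] = out, _["time"] = t);
}
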