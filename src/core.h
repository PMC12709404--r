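// Core geometry, energetics and topology for the triangulated-vesicle
// simulator.  Positions are flat arrays (3*i + d); triangle indices are
// 0-based and consistently oriented so the enclosed signed volume of a
// closed surface is positive (outward normals).
#ifndef TRIVESICLE_CORE_H
#define TRIVESICLE_CORE_H

#include <vector>
#include <array>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <random>
#include <stdexcept>

namespace ves {

inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }

// ---------------------------------------------------------------------------
// Topology: closed orientable triangulation with edge->triangle maps and
// support for diagonal (bond) flips.
// ---------------------------------------------------------------------------
struct Topo {
  int nv = 0;
  std::vector<std::array<int, 3>> F;       // oriented triangles
  std::vector<std::array<int, 2>> E;       // edges, v0 < v1
  std::vector<std::array<int, 2>> Etri;    // the two triangles of each edge
  std::vector<std::vector<int>> vtri;      // vertex -> incident triangles
  std::vector<std::vector<int>> vedge;     // vertex -> incident edges
  std::unordered_map<std::uint64_t, int> eidx;

  std::uint64_t ekey(int a, int b) const {
    if (a > b) std::swap(a, b);
    return (std::uint64_t)a * (std::uint64_t)nv + (std::uint64_t)b;
  }
  bool has_edge(int a, int b) const { return eidx.count(ekey(a, b)) > 0; }
  int edge_id(int a, int b) const {
    auto it = eidx.find(ekey(a, b));
    return it == eidx.end() ? -1 : it->second;
  }
  int degree(int v) const { return (int)vedge[v].size(); }

  void build(const std::vector<std::array<int, 3>>& tris, int nverts) {
    nv = nverts;
    F = tris;
    E.clear(); Etri.clear(); eidx.clear();
    vtri.assign(nv, {});
    vedge.assign(nv, {});
    for (int t = 0; t < (int)F.size(); ++t)
      for (int c = 0; c < 3; ++c) {
        int v = F[t][c];
        if (v < 0 || v >= nv) throw std::runtime_error("triangle index out of range");
        vtri[v].push_back(t);
      }
    for (int t = 0; t < (int)F.size(); ++t) {
      for (int c = 0; c < 3; ++c) {
        int a = F[t][c], b = F[t][(c + 1) % 3];
        std::uint64_t k = ekey(a, b);
        auto it = eidx.find(k);
        if (it == eidx.end()) {
          int id = (int)E.size();
          eidx[k] = id;
          E.push_back({std::min(a, b), std::max(a, b)});
          Etri.push_back({t, -1});
        } else {
          int id = it->second;
          if (Etri[id][1] != -1)
            throw std::runtime_error("edge borders more than two triangles");
          Etri[id][1] = t;
        }
      }
    }
    for (int e = 0; e < (int)E.size(); ++e) {
      if (Etri[e][1] == -1)
        throw std::runtime_error("mesh is not closed: boundary edge found");
      vedge[E[e][0]].push_back(e);
      vedge[E[e][1]].push_back(e);
    }
  }

  // Opposite vertices of an edge (the third vertex of each adjacent triangle).
  std::array<int, 2> opposite(int e) const {
    std::array<int, 2> out;
    for (int s = 0; s < 2; ++s) {
      int t = Etri[e][s];
      out[s] = -1;
      for (int c = 0; c < 3; ++c) {
        int v = F[t][c];
        if (v != E[e][0] && v != E[e][1]) { out[s] = v; break; }
      }
    }
    return out;
  }

  // Orient the quad of edge e: returns (a, b, c, d) with t1 containing the
  // directed edge a->b (third vertex c) and t2 the directed edge b->a
  // (third vertex d).
  void quad(int e, int& a, int& b, int& c, int& d, int& t1, int& t2) const {
    t1 = Etri[e][0]; t2 = Etri[e][1];
    int va = E[e][0], vb = E[e][1];
    // find orientation of (va, vb) in t1
    bool fwd = false;
    for (int k = 0; k < 3; ++k)
      if (F[t1][k] == va && F[t1][(k + 1) % 3] == vb) { fwd = true; break; }
    a = fwd ? va : vb;
    b = fwd ? vb : va;
    c = -1; d = -1;
    for (int k = 0; k < 3; ++k) {
      if (F[t1][k] != a && F[t1][k] != b) c = F[t1][k];
      if (F[t2][k] != a && F[t2][k] != b) d = F[t2][k];
    }
  }

  bool flip_valid(int e, const double* pos, double min_area = 1e-12) const {
    int a, b, c, d, t1, t2;
    quad(e, a, b, c, d, t1, t2);
    if (has_edge(c, d)) return false;
    if (degree(a) <= 3 || degree(b) <= 3) return false;
    // non-degenerate new triangles (a,d,c) and (d,b,c)
    double u[3], v[3], n[3];
    vsub(pos + 3 * d, pos + 3 * a, u);
    vsub(pos + 3 * c, pos + 3 * a, v);
    vcross(u, v, n);
    if (0.5 * vnorm(n) < min_area) return false;
    vsub(pos + 3 * b, pos + 3 * d, u);
    vsub(pos + 3 * c, pos + 3 * d, v);
    vcross(u, v, n);
    if (0.5 * vnorm(n) < min_area) return false;
    return true;
  }

  // Flip edge e in place.  The move is an involution on connectivity:
  // flipping the resulting edge restores the original triangulation.
  void flip(int e) {
    int a, b, c, d, t1, t2;
    quad(e, a, b, c, d, t1, t2);
    // replace triangles
    F[t1] = {a, d, c};
    F[t2] = {d, b, c};
    // the flipped edge now joins c and d
    eidx.erase(ekey(a, b));
    E[e] = {std::min(c, d), std::max(c, d)};
    eidx[ekey(c, d)] = e;
    // outer edges keep their ids; update their triangle memberships
    auto retri = [&](int va, int vb, int from, int to) {
      int id = edge_id(va, vb);
      if (Etri[id][0] == from) Etri[id][0] = to;
      else if (Etri[id][1] == from) Etri[id][1] = to;
    };
    // (a,d) moves from t2 to t1; (b,c) moves from t1 to t2
    retri(a, d, t2, t1);
    retri(b, c, t1, t2);
    // vertex -> triangle incidence
    auto drop = [](std::vector<int>& v, int x) {
      v.erase(std::find(v.begin(), v.end(), x));
    };
    drop(vtri[b], t1); vtri[d].push_back(t1);
    drop(vtri[a], t2); vtri[c].push_back(t2);
    // vertex -> edge incidence
    drop(vedge[a], e); drop(vedge[b], e);
    vedge[c].push_back(e); vedge[d].push_back(e);
  }
};

// ---------------------------------------------------------------------------
// Triangle and global geometry
// ---------------------------------------------------------------------------
inline double tri_area_normal(const double* pos, const std::array<int, 3>& f,
                              double* nrm /* unnormalized, |n| = 2A */) {
  double u[3], v[3];
  vsub(pos + 3 * f[1], pos + 3 * f[0], u);
  vsub(pos + 3 * f[2], pos + 3 * f[0], v);
  vcross(u, v, nrm);
  return 0.5 * vnorm(nrm);
}

inline double total_area(const double* pos, const std::vector<std::array<int, 3>>& F) {
  double A = 0, n[3];
  for (const auto& f : F) A += tri_area_normal(pos, f, n);
  return A;
}

inline double total_volume(const double* pos, const std::vector<std::array<int, 3>>& F) {
  double V = 0, c[3];
  for (const auto& f : F) {
    vcross(pos + 3 * f[1], pos + 3 * f[2], c);
    V += vdot(pos + 3 * f[0], c);
  }
  return V / 6.0;
}

// Per-vertex gradient of total area: grad (3*nv).
inline void area_gradient(const double* pos, const std::vector<std::array<int, 3>>& F,
                          int nv, double* grad) {
  std::fill(grad, grad + 3 * nv, 0.0);
  double n[3], e[3], g[3];
  for (const auto& f : F) {
    double A = tri_area_normal(pos, f, n);
    if (A <= 0) continue;
    double inv = 1.0 / (2.0 * A);  // unit normal = n * inv
    for (int c = 0; c < 3; ++c) {
      int i = f[c], j = f[(c + 1) % 3], k = f[(c + 2) % 3];
      vsub(pos + 3 * k, pos + 3 * j, e);       // opposite edge
      vcross(n, e, g);                          // n-hat x e, times 2A
      for (int d = 0; d < 3; ++d) grad[3 * i + d] += 0.5 * inv * g[d];
    }
  }
}

// Per-vertex gradient of enclosed volume.
inline void volume_gradient(const double* pos, const std::vector<std::array<int, 3>>& F,
                            int nv, double* grad) {
  std::fill(grad, grad + 3 * nv, 0.0);
  double c[3];
  for (const auto& f : F)
    for (int r = 0; r < 3; ++r) {
      int i = f[r], j = f[(r + 1) % 3], k = f[(r + 2) % 3];
      vcross(pos + 3 * j, pos + 3 * k, c);
      for (int d = 0; d < 3; ++d) grad[3 * i + d] += c[d] / 6.0;
    }
}

// ---------------------------------------------------------------------------
// Discrete mean curvature: cotangent Laplacian with Meyer mixed Voronoi areas.
// M_i = sign(K . n) |K| / 2 with K = Hvec / (2 A_mixed).
// ---------------------------------------------------------------------------
struct VertexCurv { double M; double A; };

inline VertexCurv vertex_curvature_one(int i, const Topo& topo, const double* pos) {
  double H[3] = {0, 0, 0};
  double nrm[3] = {0, 0, 0};
  double Amix = 0;
  double u[3], v[3], w[3], n[3];
  for (int t : topo.vtri[i]) {
    const auto& f = topo.F[t];
    int c0 = (f[0] == i) ? 0 : (f[1] == i ? 1 : 2);
    int j = f[(c0 + 1) % 3], k = f[(c0 + 2) % 3];
    const double *xi = pos + 3 * i, *xj = pos + 3 * j, *xk = pos + 3 * k;
    // angles
    vsub(xi, xj, u); vsub(xk, xj, v);           // at j
    double cj[3]; vcross(u, v, cj);
    double cot_j = vdot(u, v) / std::max(vnorm(cj), 1e-300);
    vsub(xi, xk, u); vsub(xj, xk, v);           // at k
    double ck[3]; vcross(u, v, ck);
    double cot_k = vdot(u, v) / std::max(vnorm(ck), 1e-300);
    vsub(xj, xi, u); vsub(xk, xi, v);           // at i
    vcross(u, v, n);
    double twoA = vnorm(n);
    double area = 0.5 * twoA;
    double cos_i = vdot(u, v);
    // Hvec accumulation: cot_k * (xi - xj) + cot_j * (xi - xk)
    vsub(xi, xj, u); vsub(xi, xk, v);
    for (int d = 0; d < 3; ++d) {
      H[d] += cot_k * u[d] + cot_j * v[d];
      nrm[d] += n[d];                            // area-weighted normal
    }
    // Meyer mixed area
    double lij2 = vdot(u, u), lik2 = vdot(v, v);
    if (cos_i < 0) Amix += area / 2.0;           // obtuse at i
    else if (cot_j < 0 || cot_k < 0) Amix += area / 4.0;  // obtuse elsewhere
    else Amix += (lij2 * cot_k + lik2 * cot_j) / 8.0;
  }
  VertexCurv out;
  out.A = Amix;
  double Klen = vnorm(H) / (2.0 * std::max(Amix, 1e-300));
  double sgn = (vdot(H, nrm) >= 0) ? 1.0 : -1.0;
  out.M = 0.5 * sgn * Klen;
  return out;
}

inline double vertex_bend_energy(int i, const Topo& topo, const double* pos,
                                 double kappa) {
  VertexCurv c = vertex_curvature_one(i, topo, pos);
  return 2.0 * kappa * c.M * c.M * c.A;
}

// Bending energy of the whole mesh.
inline double bending_energy(const Topo& topo, const double* pos, double kappa) {
  double E = 0;
  for (int i = 0; i < topo.nv; ++i) E += vertex_bend_energy(i, topo, pos, kappa);
  return E;
}

// Bending forces by local-stencil centered finite differences of the exact
// discrete energy.  Moving vertex p only changes M and A of p and its
// 1-ring neighbours, so the differenced energy is the sum over that stencil.
inline void bending_forces(const Topo& topo, std::vector<double>& pos, double kappa,
                           double* force, double h = 1e-5) {
  double* p = pos.data();
  std::vector<int> stencil;
  for (int i = 0; i < topo.nv; ++i) {
    stencil.clear();
    stencil.push_back(i);
    for (int e : topo.vedge[i]) {
      int o = (topo.E[e][0] == i) ? topo.E[e][1] : topo.E[e][0];
      stencil.push_back(o);
    }
    auto local = [&]() {
      double s = 0;
      for (int v : stencil) s += vertex_bend_energy(v, topo, p, kappa);
      return s;
    };
    for (int d = 0; d < 3; ++d) {
      double x0 = p[3 * i + d];
      p[3 * i + d] = x0 + h;
      double ep = local();
      p[3 * i + d] = x0 - h;
      double em = local();
      p[3 * i + d] = x0;
      force[3 * i + d] = -(ep - em) / (2.0 * h);
    }
  }
}

// ---------------------------------------------------------------------------
// Tether (edge bond) potential: half-harmonic repulsive core below r_rep and
// half-harmonic attractive tail above r_att, flat in between.
// ---------------------------------------------------------------------------
inline double bond_U(double r, double kb, double rrep, double ratt) {
  if (r < rrep) { double d = r - rrep; return 0.5 * kb * d * d; }
  if (r > ratt) { double d = r - ratt; return 0.5 * kb * d * d; }
  return 0.0;
}
inline double bond_dU(double r, double kb, double rrep, double ratt) {
  if (r < rrep) return kb * (r - rrep);
  if (r > ratt) return kb * (r - ratt);
  return 0.0;
}

// Total edge-bond energy and per-vertex forces; optionally per-edge pair
// virials f_i . (r_i - r_j) with the mechanical force on the first vertex.
inline double edge_bond_all(const Topo& topo, const double* pos, double kb,
                            double rrep, double ratt, double* force,
                            double* edge_virial = nullptr) {
  double E = 0, u[3];
  for (int e = 0; e < (int)topo.E.size(); ++e) {
    int i = topo.E[e][0], j = topo.E[e][1];
    vsub(pos + 3 * i, pos + 3 * j, u);
    double r = vnorm(u);
    E += bond_U(r, kb, rrep, ratt);
    double dU = bond_dU(r, kb, rrep, ratt);
    if (edge_virial) edge_virial[e] = -dU * r;  // f_i . (r_i - r_j)
    if (dU != 0.0 && force) {
      double s = -dU / r;
      for (int d = 0; d < 3; ++d) {
        force[3 * i + d] += s * u[d];
        force[3 * j + d] -= s * u[d];
      }
    }
  }
  return E;
}

// ---------------------------------------------------------------------------
// Hash-grid cell list for short-range pair interactions.
// ---------------------------------------------------------------------------
struct CellGrid {
  double cell;
  std::unordered_map<std::int64_t, std::vector<int>> cells;
  static std::int64_t key(int x, int y, int z) {
    return ((std::int64_t)(x + (1 << 20)) << 42) |
           ((std::int64_t)(y + (1 << 20)) << 21) |
           (std::int64_t)(z + (1 << 20));
  }
  void build(const double* pos, int n, double cutoff) {
    cell = cutoff;
    cells.clear();
    for (int i = 0; i < n; ++i) {
      int cx = (int)std::floor(pos[3 * i] / cell);
      int cy = (int)std::floor(pos[3 * i + 1] / cell);
      int cz = (int)std::floor(pos[3 * i + 2] / cell);
      cells[key(cx, cy, cz)].push_back(i);
    }
  }
  template <typename Fn>
  void neighbours(const double* q, Fn&& fn) const {
    int cx = (int)std::floor(q[0] / cell);
    int cy = (int)std::floor(q[1] / cell);
    int cz = (int)std::floor(q[2] / cell);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = cells.find(key(cx + dx, cy + dy, cz + dz));
          if (it == cells.end()) continue;
          for (int j : it->second) fn(j);
        }
  }
};

// Harmonic overlap penalty 0.5 k (r - range)^2 for r < range between point
// sets A and B.  If same_set, pairs are drawn within A (i < j) and pairs with
// equal group id are excluded (used for same-chain beads); exclude(i,j) can
// veto further pairs (used for bonded mesh vertices).
template <typename Excl>
inline double pair_repulsion(const double* A, int nA, const double* B, int nB,
                             bool same_set, double k, double range,
                             const int* groupA, Excl&& exclude,
                             double* fA, double* fB, bool use_grid = true) {
  double E = 0, u[3];
  auto handle = [&](int i, int j) {
    if (same_set) {
      if (j <= i) return;
      if (groupA && groupA[i] == groupA[j]) return;
    }
    if (exclude(i, j)) return;
    const double* bj = same_set ? A + 3 * j : B + 3 * j;
    vsub(A + 3 * i, bj, u);
    if (std::abs(u[0]) >= range || std::abs(u[1]) >= range ||
        std::abs(u[2]) >= range) return;
    double r = vnorm(u);
    if (r >= range || r <= 0) return;
    double d = r - range;
    E += 0.5 * k * d * d;
    double s = -k * d / r;  // repulsive: d < 0 so s > 0
    double* fj = same_set ? fA + 3 * j : fB + 3 * j;
    for (int c = 0; c < 3; ++c) {
      fA[3 * i + c] += s * u[c];
      fj[c] -= s * u[c];
    }
  };
  if (use_grid) {
    CellGrid grid;
    const double* tgt = same_set ? A : B;
    int ntgt = same_set ? nA : nB;
    grid.build(tgt, ntgt, range);
    for (int i = 0; i < nA; ++i)
      grid.neighbours(A + 3 * i, [&](int j) { handle(i, j); });
  } else {
    int ntgt = same_set ? nA : nB;
    for (int i = 0; i < nA; ++i)
      for (int j = 0; j < ntgt; ++j) handle(i, j);
  }
  return E;
}

// ---------------------------------------------------------------------------
// Filament chain potentials
// ---------------------------------------------------------------------------
inline double chain_bond_forces(const double* X, int nb, int nf, int nbf,
                                double kfb, double r0, double* force) {
  (void)nb;
  double E = 0, u[3];
  for (int f = 0; f < nf; ++f)
    for (int b = 0; b < nbf - 1; ++b) {
      int i = f * nbf + b, j = i + 1;
      vsub(X + 3 * i, X + 3 * j, u);
      double r = vnorm(u);
      if (r <= 0) throw std::runtime_error("coincident consecutive beads");
      double d = r - r0;
      E += 0.5 * kfb * d * d;
      double s = -kfb * d / r;
      for (int c = 0; c < 3; ++c) {
        force[3 * i + c] += s * u[c];
        force[3 * j + c] -= s * u[c];
      }
    }
  return E;
}

inline double chain_bend_forces(const double* X, int nf, int nbf,
                                double kappa_f, double* force) {
  double E = 0;
  double u[3], v[3];
  for (int f = 0; f < nf; ++f)
    for (int b = 1; b < nbf - 1; ++b) {
      int ia = f * nbf + b - 1, ib = f * nbf + b, ic = f * nbf + b + 1;
      vsub(X + 3 * ia, X + 3 * ib, u);
      vsub(X + 3 * ic, X + 3 * ib, v);
      double lu = vnorm(u), lv = vnorm(v);
      if (lu <= 0 || lv <= 0) throw std::runtime_error("zero-length filament bond");
      double ct = vdot(u, v) / (lu * lv);
      ct = std::max(-1.0, std::min(1.0, ct));
      double th = std::acos(ct);
      double dth = th - M_PI;
      E += 0.5 * kappa_f * dth * dth;
      double st = std::sqrt(std::max(1.0 - ct * ct, 0.0));
      // force = g * grad(cos th) with g = kappa_f (th - pi) / sin th,
      // which tends to -kappa_f at the straight ground state.
      double g = (st > 1e-8) ? kappa_f * dth / st : -kappa_f;
      for (int c = 0; c < 3; ++c) {
        double ga = (v[c] / lv - ct * u[c] / lu) / lu;
        double gc = (u[c] / lu - ct * v[c] / lv) / lv;
        force[3 * ia + c] += g * ga;
        force[3 * ic + c] += g * gc;
        force[3 * ib + c] -= g * (ga + gc);
      }
    }
  return E;
}

// Tangential propulsion along the local bond direction.  Bead i < last gets
// f_p * unit(r_{i+1} - r_i); the terminal bead follows tail_drive.  Single
// beads (nbf = 1) are apolar and get no thrust.
inline void active_forces(const double* X, int nf, int nbf, double fp,
                          bool tail_drive, double* force) {
  if (nbf < 2 || fp == 0.0) return;
  double u[3];
  for (int f = 0; f < nf; ++f) {
    for (int b = 0; b < nbf - 1; ++b) {
      int i = f * nbf + b;
      vsub(X + 3 * (i + 1), X + 3 * i, u);
      double r = vnorm(u);
      if (r <= 0) throw std::runtime_error("zero-length filament bond");
      for (int c = 0; c < 3; ++c) force[3 * i + c] += fp * u[c] / r;
    }
    if (tail_drive) {
      int i = f * nbf + nbf - 1;
      vsub(X + 3 * i, X + 3 * (i - 1), u);
      double r = vnorm(u);
      if (r <= 0) throw std::runtime_error("zero-length filament bond");
      for (int c = 0; c < 3; ++c) force[3 * i + c] += fp * u[c] / r;
    }
  }
}

}  // namespace ves

#endif
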