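// R-facing wrappers around the simulation core, plus the Langevin run loop.
#include <Rcpp.h>
#include "core.h"

using namespace Rcpp;
using namespace ves;

// --------------------------------------------------------------------------
// conversion helpers (R is 1-based, core is 0-based)
// --------------------------------------------------------------------------
static std::vector<std::array<int, 3>> tris_in(const IntegerMatrix& F) {
  std::vector<std::array<int, 3>> out(F.nrow());
  for (int t = 0; t < F.nrow(); ++t)
    out[t] = {F(t, 0) - 1, F(t, 1) - 1, F(t, 2) - 1};
  return out;
}
static std::vector<double> pos_in(const NumericMatrix& V) {
  std::vector<double> p(3 * V.nrow());
  for (int i = 0; i < V.nrow(); ++i)
    for (int d = 0; d < 3; ++d) p[3 * i + d] = V(i, d);
  return p;
}
static NumericMatrix mat_out(const std::vector<double>& p) {
  int n = (int)p.size() / 3;
  NumericMatrix m(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) m(i, d) = p[3 * i + d];
  return m;
}
static IntegerMatrix tris_out(const std::vector<std::array<int, 3>>& F) {
  IntegerMatrix m((int)F.size(), 3);
  for (int t = 0; t < (int)F.size(); ++t)
    for (int c = 0; c < 3; ++c) m(t, c) = F[t][c] + 1;
  return m;
}

// [[Rcpp::export]]
List cpp_build_topology(const IntegerMatrix& F, int nv) {
  Topo topo;
  topo.build(tris_in(F), nv);
  // deterministic lexicographic edge order
  std::vector<int> ord(topo.E.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (topo.E[a][0] != topo.E[b][0]) return topo.E[a][0] < topo.E[b][0];
    return topo.E[a][1] < topo.E[b][1];
  });
  IntegerMatrix E((int)topo.E.size(), 2);
  for (int r = 0; r < (int)ord.size(); ++r) {
    E(r, 0) = topo.E[ord[r]][0] + 1;
    E(r, 1) = topo.E[ord[r]][1] + 1;
  }
  return List::create(_["edges"] = E,
                      _["n_edges"] = (int)topo.E.size(),
                      _["n_triangles"] = (int)topo.F.size());
}

// [[Rcpp::export]]
List cpp_mesh_props(const NumericMatrix& V, const IntegerMatrix& F) {
  auto pos = pos_in(V);
  auto tris = tris_in(F);
  NumericVector tareas(F.nrow());
  double n[3];
  for (int t = 0; t < F.nrow(); ++t) tareas[t] = tri_area_normal(pos.data(), tris[t], n);
  return List::create(_["area"] = total_area(pos.data(), tris),
                      _["volume"] = total_volume(pos.data(), tris),
                      _["tri_areas"] = tareas);
}

// [[Rcpp::export]]
List cpp_vertex_curvature(const NumericMatrix& V, const IntegerMatrix& F) {
  Topo topo;
  topo.build(tris_in(F), V.nrow());
  auto pos = pos_in(V);
  NumericVector M(V.nrow()), A(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) {
    VertexCurv c = vertex_curvature_one(i, topo, pos.data());
    M[i] = c.M;
    A[i] = c.A;
  }
  return List::create(_["M"] = M, _["A_mixed"] = A);
}

// [[Rcpp::export]]
List cpp_area_volume_gradients(const NumericMatrix& V, const IntegerMatrix& F) {
  auto pos = pos_in(V);
  auto tris = tris_in(F);
  std::vector<double> gA(3 * V.nrow()), gV(3 * V.nrow());
  area_gradient(pos.data(), tris, V.nrow(), gA.data());
  volume_gradient(pos.data(), tris, V.nrow(), gV.data());
  return List::create(_["grad_area"] = mat_out(gA), _["grad_volume"] = mat_out(gV));
}

// [[Rcpp::export]]
List cpp_bending(const NumericMatrix& V, const IntegerMatrix& F, double kappa,
                 double h = 1e-5) {
  Topo topo;
  topo.build(tris_in(F), V.nrow());
  auto pos = pos_in(V);
  std::vector<double> force(3 * V.nrow(), 0.0);
  bending_forces(topo, pos, kappa, force.data(), h);
  return List::create(_["energy"] = bending_energy(topo, pos.data(), kappa),
                      _["forces"] = mat_out(force));
}

// [[Rcpp::export]]
List cpp_constraint(const NumericMatrix& V, const IntegerMatrix& F, double k,
                    double X0, std::string which) {
  auto pos = pos_in(V);
  auto tris = tris_in(F);
  std::vector<double> grad(3 * V.nrow());
  double X;
  if (which == "area") {
    X = total_area(pos.data(), tris);
    area_gradient(pos.data(), tris, V.nrow(), grad.data());
  } else if (which == "volume") {
    X = total_volume(pos.data(), tris);
    volume_gradient(pos.data(), tris, V.nrow(), grad.data());
  } else {
    stop("which must be 'area' or 'volume'");
  }
  double pref = -k * (X - X0) / X0;
  for (auto& g : grad) g *= pref;
  double E = k * (X - X0) * (X - X0) / (2.0 * X0);
  return List::create(_["energy"] = E, _["forces"] = mat_out(grad), _["value"] = X);
}

// [[Rcpp::export]]
List cpp_edge_bond(const NumericMatrix& V, const IntegerMatrix& E, double kb,
                   double r_rep, double r_att) {
  auto pos = pos_in(V);
  Topo topo;  // only need edges; fabricate a minimal edge container
  topo.nv = V.nrow();
  topo.E.resize(E.nrow());
  for (int e = 0; e < E.nrow(); ++e)
    topo.E[e] = {E(e, 0) - 1, E(e, 1) - 1};
  std::vector<double> force(3 * V.nrow(), 0.0), ev(E.nrow());
  double energy = edge_bond_all(topo, pos.data(), kb, r_rep, r_att,
                                force.data(), ev.data());
  return List::create(_["energy"] = energy, _["forces"] = mat_out(force),
                      _["edge_virial"] = NumericVector(ev.begin(), ev.end()));
}

// [[Rcpp::export]]
List cpp_vertex_exclusion(const NumericMatrix& V, const IntegerMatrix& E,
                          double k, double sigma_vv, bool use_grid = true) {
  auto pos = pos_in(V);
  Topo topo;
  topo.nv = V.nrow();
  for (int e = 0; e < E.nrow(); ++e)
    topo.eidx[topo.ekey(E(e, 0) - 1, E(e, 1) - 1)] = e;
  std::vector<double> force(3 * V.nrow(), 0.0);
  double energy = pair_repulsion(
      pos.data(), V.nrow(), nullptr, 0, true, k, sigma_vv, nullptr,
      [&](int i, int j) { return topo.has_edge(i, j); },
      force.data(), nullptr, use_grid);
  return List::create(_["energy"] = energy, _["forces"] = mat_out(force));
}

// [[Rcpp::export]]
List cpp_chain_forces(const NumericMatrix& X, int nf, int nbf, double kfb,
                      double r0, double kappa_f) {
  auto pos = pos_in(X);
  std::vector<double> force(3 * X.nrow(), 0.0);
  double Eb = chain_bond_forces(pos.data(), X.nrow(), nf, nbf, kfb, r0, force.data());
  double Ea = (nbf >= 3) ? chain_bend_forces(pos.data(), nf, nbf, kappa_f, force.data())
                         : 0.0;
  return List::create(_["energy_bond"] = Eb, _["energy_bend"] = Ea,
                      _["forces"] = mat_out(force));
}

// [[Rcpp::export]]
NumericMatrix cpp_active_forces(const NumericMatrix& X, int nf, int nbf,
                                double fp, bool tail_drive) {
  auto pos = pos_in(X);
  std::vector<double> force(3 * X.nrow(), 0.0);
  active_forces(pos.data(), nf, nbf, fp, tail_drive, force.data());
  return mat_out(force);
}

// [[Rcpp::export]]
List cpp_pair_repulsion(const NumericMatrix& A, const NumericMatrix& B,
                        bool same_set, double k, double range,
                        const IntegerVector& groupA, bool use_grid = true) {
  auto pa = pos_in(A);
  auto pb = pos_in(B);
  std::vector<double> fa(3 * A.nrow(), 0.0), fb(3 * B.nrow(), 0.0);
  std::vector<int> grp;
  const int* gptr = nullptr;
  if (groupA.size() == A.nrow()) {
    grp.assign(groupA.begin(), groupA.end());
    gptr = grp.data();
  }
  double E = pair_repulsion(pa.data(), A.nrow(), pb.data(), B.nrow(), same_set,
                            k, range, gptr, [](int, int) { return false; },
                            fa.data(), fb.data(), use_grid);
  return List::create(_["energy"] = E, _["forces_A"] = mat_out(fa),
                      _["forces_B"] = mat_out(fb));
}

// --------------------------------------------------------------------------
// flips
// --------------------------------------------------------------------------
// [[Rcpp::export]]
bool cpp_flip_valid(const NumericMatrix& V, const IntegerMatrix& F, int v1, int v2) {
  Topo topo;
  topo.build(tris_in(F), V.nrow());
  int e = topo.edge_id(v1 - 1, v2 - 1);
  if (e < 0) stop("no such edge");
  auto pos = pos_in(V);
  return topo.flip_valid(e, pos.data());
}

struct FlipParams {
  double kappa, kA, A0, kV, V0, kb, r_rep, r_att;
};

static double flip_delta_U(Topo& topo, const double* pos, int e,
                           const FlipParams& pp, double Acur, double Vcur,
                           double* Anew = nullptr, double* Vnew = nullptr) {
  int a, b, c, d, t1, t2;
  topo.quad(e, a, b, c, d, t1, t2);
  int quadv[4] = {a, b, c, d};
  double n[3];
  double Eb0 = 0, At0 = 0, Vt0 = 0;
  for (int q = 0; q < 4; ++q) Eb0 += vertex_bend_energy(quadv[q], topo, pos, pp.kappa);
  for (int t : {t1, t2}) {
    At0 += tri_area_normal(pos, topo.F[t], n);
    double cx[3];
    vcross(pos + 3 * topo.F[t][1], pos + 3 * topo.F[t][2], cx);
    Vt0 += vdot(pos + 3 * topo.F[t][0], cx) / 6.0;
  }
  double u[3];
  vsub(pos + 3 * a, pos + 3 * b, u);
  double Ebond0 = bond_U(vnorm(u), pp.kb, pp.r_rep, pp.r_att);

  topo.flip(e);

  double Eb1 = 0, At1 = 0, Vt1 = 0;
  for (int q = 0; q < 4; ++q) Eb1 += vertex_bend_energy(quadv[q], topo, pos, pp.kappa);
  for (int t : {t1, t2}) {
    At1 += tri_area_normal(pos, topo.F[t], n);
    double cx[3];
    vcross(pos + 3 * topo.F[t][1], pos + 3 * topo.F[t][2], cx);
    Vt1 += vdot(pos + 3 * topo.F[t][0], cx) / 6.0;
  }
  vsub(pos + 3 * c, pos + 3 * d, u);
  double Ebond1 = bond_U(vnorm(u), pp.kb, pp.r_rep, pp.r_att);

  double A1 = Acur + (At1 - At0), V1 = Vcur + (Vt1 - Vt0);
  if (Anew) *Anew = A1;
  if (Vnew) *Vnew = V1;
  double dUA = pp.kA * ((A1 - pp.A0) * (A1 - pp.A0) - (Acur - pp.A0) * (Acur - pp.A0)) /
               (2.0 * pp.A0);
  double dUV = pp.kV * ((V1 - pp.V0) * (V1 - pp.V0) - (Vcur - pp.V0) * (Vcur - pp.V0)) /
               (2.0 * pp.V0);
  return (Eb1 - Eb0) + dUA + dUV + (Ebond1 - Ebond0);
}

static FlipParams flip_params_in(const List& params) {
  FlipParams pp;
  pp.kappa = as<double>(params["kappa"]);
  pp.kA = as<double>(params["k_A"]);
  pp.A0 = as<double>(params["A_0"]);
  pp.kV = as<double>(params["k_V"]);
  pp.V0 = as<double>(params["V_0"]);
  pp.kb = as<double>(params["k_b"]);
  pp.r_rep = as<double>(params["r_rep"]);
  pp.r_att = as<double>(params["r_att"]);
  return pp;
}

// [[Rcpp::export]]
double cpp_flip_delta_energy(const NumericMatrix& V, const IntegerMatrix& F,
                             int v1, int v2, const List& params) {
  Topo topo;
  topo.build(tris_in(F), V.nrow());
  int e = topo.edge_id(v1 - 1, v2 - 1);
  if (e < 0) stop("no such edge");
  auto pos = pos_in(V);
  if (!topo.flip_valid(e, pos.data())) stop("flip is not valid for this edge");
  FlipParams pp = flip_params_in(params);
  double A = total_area(pos.data(), topo.F);
  double Vol = total_volume(pos.data(), topo.F);
  double dU = flip_delta_U(topo, pos.data(), e, pp, A, Vol);
  topo.flip(e);  // restore (involution)
  return dU;
}

// One Metropolis sweep over the edges: each edge attempted with probability
// q in a random order; accepted if dU < 0, else with prob exp(-dU / kBT).
static int flip_sweep_inplace(Topo& topo, const double* pos, const FlipParams& pp,
                              double q, double kBT, std::mt19937_64& rng,
                              double& Acur, double& Vcur, int& attempted) {
  std::vector<int> order(topo.E.size());
  for (size_t i = 0; i < order.size(); ++i) order[i] = (int)i;
  std::shuffle(order.begin(), order.end(), rng);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  int accepted = 0;
  attempted = 0;
  for (int e : order) {
    if (q < 1.0 && unif(rng) >= q) continue;
    if (!topo.flip_valid(e, pos)) continue;
    ++attempted;
    double A1, V1;
    double dU = flip_delta_U(topo, pos, e, pp, Acur, Vcur, &A1, &V1);
    // flip_delta_U leaves the flip applied; revert on rejection
    bool accept = (dU < 0) || (unif(rng) < std::exp(-dU / kBT));
    if (accept) {
      ++accepted;
      Acur = A1;
      Vcur = V1;
    } else {
      topo.flip(e);
    }
  }
  return accepted;
}

// [[Rcpp::export]]
List cpp_flip_sweep(const NumericMatrix& V, const IntegerMatrix& F,
                    const List& params, double q, double kBT, int seed) {
  Topo topo;
  topo.build(tris_in(F), V.nrow());
  auto pos = pos_in(V);
  FlipParams pp = flip_params_in(params);
  std::mt19937_64 rng((std::uint64_t)seed);
  double A = total_area(pos.data(), topo.F);
  double Vol = total_volume(pos.data(), topo.F);
  int attempted = 0;
  int accepted = flip_sweep_inplace(topo, pos.data(), pp, q, kBT, rng, A, Vol,
                                    attempted);
  return List::create(_["triangles"] = tris_out(topo.F),
                      _["attempted"] = attempted, _["accepted"] = accepted);
}

// --------------------------------------------------------------------------
// per-vertex virial for the tension estimator
// --------------------------------------------------------------------------
// Constraint (area+volume) virial per triangle about the mesh centroid, each
// triangle's three-vertex sum distributed equally to its vertices (the /3 of
// the combination rule); bond virial in relative pair coordinates (/2).
// [[Rcpp::export]]
List cpp_vertex_virial(const NumericMatrix& V, const IntegerMatrix& F,
                       const IntegerMatrix& E, double kA, double A0, double kV,
                       double V0, double kb, double r_rep, double r_att) {
  auto pos = pos_in(V);
  auto tris = tris_in(F);
  int nv = V.nrow();
  double A = total_area(pos.data(), tris);
  double Vol = total_volume(pos.data(), tris);
  double cen[3] = {0, 0, 0};
  for (int i = 0; i < nv; ++i)
    for (int d = 0; d < 3; ++d) cen[d] += pos[3 * i + d] / nv;

  double prefA = -kA * (A - A0) / A0;   // mechanical force prefactor
  double prefV = -kV * (Vol - V0) / V0;
  std::vector<double> Vi(nv, 0.0), Ai(nv, 0.0);
  double n[3], e[3], g[3], cx[3];
  for (const auto& f : tris) {
    double At = tri_area_normal(pos.data(), f, n);
    double W = 0.0;  // triangle virial: sum over its 3 vertices of f . (r - centroid)
    double inv = (At > 0) ? 1.0 / (2.0 * At) : 0.0;
    for (int c = 0; c < 3; ++c) {
      int i = f[c], j = f[(c + 1) % 3], k = f[(c + 2) % 3];
      // area-constraint force share from this triangle
      vsub(pos.data() + 3 * k, pos.data() + 3 * j, e);
      vcross(n, e, g);
      double fi[3];
      for (int d = 0; d < 3; ++d) fi[d] = prefA * 0.5 * inv * g[d];
      // volume-constraint force share from this triangle
      vcross(pos.data() + 3 * j, pos.data() + 3 * k, cx);
      for (int d = 0; d < 3; ++d) fi[d] += prefV * cx[d] / 6.0;
      for (int d = 0; d < 3; ++d) W += fi[d] * (pos[3 * i + d] - cen[d]);
    }
    for (int c = 0; c < 3; ++c) {
      Vi[f[c]] += W / 3.0;
      Ai[f[c]] += At / 3.0;
    }
  }
  // bond pair virial, half to each endpoint.  Internal pair forces enter a
  // tension estimate with the opposite sign of external loads, so the
  // gradient convention dU'(r) * r is used here (stretched bonds raise the
  // tension).
  double u[3];
  for (int r = 0; r < E.nrow(); ++r) {
    int i = E(r, 0) - 1, j = E(r, 1) - 1;
    vsub(pos.data() + 3 * i, pos.data() + 3 * j, u);
    double len = vnorm(u);
    double w = bond_dU(len, kb, r_rep, r_att) * len;
    Vi[i] += w / 2.0;
    Vi[j] += w / 2.0;
  }
  return List::create(_["virial"] = NumericVector(Vi.begin(), Vi.end()),
                      _["A_i"] = NumericVector(Ai.begin(), Ai.end()),
                      _["area"] = A, _["volume"] = Vol);
}

// --------------------------------------------------------------------------
// Langevin engine: Gronbech-Jensen/Farago velocity Verlet.
// --------------------------------------------------------------------------
struct RunParams {
  double kappa, kA, A0, kV, kb, r_rep, r_att;
  double V0_start, V0_end;
  long ramp_steps;
  double k_bb, k_bv, k_vv, sigma, sigma_bv, sigma_vv;
  double kfb, r0, kappa_f, fp;
  double gamma, m_b, m_v, kBT, dt;
  bool tail_drive, vv_exclusion;
  int nf, nbf;
  double fd_h;
};

static RunParams run_params_in(const List& p) {
  RunParams rp;
  rp.kappa = as<double>(p["kappa"]);
  rp.kA = as<double>(p["k_A"]);
  rp.A0 = as<double>(p["A_0"]);
  rp.kV = as<double>(p["k_V"]);
  rp.V0_start = as<double>(p["V0_start"]);
  rp.V0_end = as<double>(p["V0_end"]);
  rp.ramp_steps = as<long>(p["ramp_steps"]);
  rp.kb = as<double>(p["k_b"]);
  rp.r_rep = as<double>(p["r_rep"]);
  rp.r_att = as<double>(p["r_att"]);
  rp.k_bb = as<double>(p["k_bb"]);
  rp.k_bv = as<double>(p["k_bv"]);
  rp.k_vv = as<double>(p["k_vv"]);
  rp.sigma = as<double>(p["sigma"]);
  rp.sigma_bv = as<double>(p["sigma_bv"]);
  rp.sigma_vv = as<double>(p["sigma_vv"]);
  rp.kfb = as<double>(p["k_fb"]);
  rp.r0 = as<double>(p["r_0"]);
  rp.kappa_f = as<double>(p["kappa_f"]);
  rp.fp = as<double>(p["f_p"]);
  rp.gamma = as<double>(p["gamma"]);
  rp.m_b = as<double>(p["m_b"]);
  rp.m_v = as<double>(p["m_v"]);
  rp.kBT = as<double>(p["k_BT"]);
  rp.dt = as<double>(p["dt"]);
  rp.tail_drive = as<bool>(p["tail_drive"]);
  rp.vv_exclusion = as<bool>(p["vv_exclusion"]);
  rp.nf = as<int>(p["n_f"]);
  rp.nbf = as<int>(p["n_bf"]);
  rp.fd_h = as<double>(p["fd_h"]);
  return rp;
}

struct Energies {
  double bend = 0, area = 0, volume = 0, bond = 0, excl = 0;
  double fil_bond = 0, fil_bend = 0, bb = 0, bv = 0;
};

// Total forces on vertices (fv) and beads (fx); returns energy breakdown.
static Energies total_forces(Topo& topo, std::vector<double>& pos,
                             std::vector<double>& X, const RunParams& rp,
                             double V0_now, std::vector<double>& fv,
                             std::vector<double>& fx,
                             std::vector<int>& chain_id, bool want_energy) {
  int nv = topo.nv;
  int nb = (int)X.size() / 3;
  std::fill(fv.begin(), fv.end(), 0.0);
  std::fill(fx.begin(), fx.end(), 0.0);
  Energies en;

  // bending
  bending_forces(topo, pos, rp.kappa, fv.data(), rp.fd_h);
  if (want_energy) en.bend = bending_energy(topo, pos.data(), rp.kappa);

  // area / volume constraints
  double A = total_area(pos.data(), topo.F);
  double Vol = total_volume(pos.data(), topo.F);
  {
    std::vector<double> grad(3 * nv);
    area_gradient(pos.data(), topo.F, nv, grad.data());
    double pref = -rp.kA * (A - rp.A0) / rp.A0;
    for (int i = 0; i < 3 * nv; ++i) fv[i] += pref * grad[i];
    volume_gradient(pos.data(), topo.F, nv, grad.data());
    double prefV = -rp.kV * (Vol - V0_now) / V0_now;
    for (int i = 0; i < 3 * nv; ++i) fv[i] += prefV * grad[i];
    en.area = rp.kA * (A - rp.A0) * (A - rp.A0) / (2.0 * rp.A0);
    en.volume = rp.kV * (Vol - V0_now) * (Vol - V0_now) / (2.0 * V0_now);
  }

  // tether bonds
  en.bond = edge_bond_all(topo, pos.data(), rp.kb, rp.r_rep, rp.r_att, fv.data());

  // membrane self-avoidance
  if (rp.vv_exclusion) {
    en.excl = pair_repulsion(
        pos.data(), nv, nullptr, 0, true, rp.k_vv, rp.sigma_vv, nullptr,
        [&](int i, int j) { return topo.has_edge(i, j); }, fv.data(), nullptr,
        true);
  }

  if (nb > 0) {
    en.fil_bond = chain_bond_forces(X.data(), nb, rp.nf, rp.nbf, rp.kfb, rp.r0,
                                    fx.data());
    if (rp.nbf >= 3)
      en.fil_bend = chain_bend_forces(X.data(), rp.nf, rp.nbf, rp.kappa_f,
                                      fx.data());
    active_forces(X.data(), rp.nf, rp.nbf, rp.fp, rp.tail_drive, fx.data());
    // bead-bead (different chains only)
    if (rp.nf > 1)
      en.bb = pair_repulsion(X.data(), nb, nullptr, 0, true, rp.k_bb, rp.sigma,
                             chain_id.data(), [](int, int) { return false; },
                             fx.data(), nullptr, true);
    // bead-vertex (membrane receives the counterforce)
    en.bv = pair_repulsion(X.data(), nb, pos.data(), nv, false, rp.k_bv,
                           rp.sigma_bv, nullptr, [](int, int) { return false; },
                           fx.data(), fv.data(), true);
  }
  return en;
}

// [[Rcpp::export]]
List cpp_run(const NumericMatrix& V, const IntegerMatrix& F,
             const NumericMatrix& X, const NumericMatrix& vel_v,
             const NumericMatrix& vel_x, const List& params, long n_steps,
             long sample_every, long flip_every, double flip_q, int seed_thermo,
             int seed_flip, double t0 = 0.0, bool record_frames = true,
             bool record_virial = true) {
  RunParams rp = run_params_in(params);
  Topo topo;
  topo.build(tris_in(F), V.nrow());
  auto pos = pos_in(V);
  auto xb = pos_in(X);
  auto vv = pos_in(vel_v);
  auto vx = pos_in(vel_x);
  int nv = V.nrow(), nb = X.nrow();
  std::vector<int> chain_id(nb);
  for (int i = 0; i < nb; ++i) chain_id[i] = (rp.nbf > 0) ? i / rp.nbf : 0;

  std::mt19937_64 rng_t((std::uint64_t)seed_thermo);
  std::mt19937_64 rng_f((std::uint64_t)seed_flip);
  std::normal_distribution<double> gauss(0.0, 1.0);

  // GJF coefficients per particle type
  auto gjf = [&](double m, double& a, double& b) {
    double x = rp.gamma * rp.dt / (2.0 * m);
    b = 1.0 / (1.0 + x);
    a = (1.0 - x) * b;
  };
  double a_v, b_v, a_b, b_b;
  gjf(rp.m_v, a_v, b_v);
  gjf(rp.m_b, a_b, b_b);
  double noise_sd = std::sqrt(2.0 * rp.gamma * rp.kBT * rp.dt);

  std::vector<double> fv(3 * nv), fx(3 * nb), fv1(3 * nv), fx1(3 * nb);
  std::vector<double> beta_v(3 * nv), beta_x(3 * nb);

  auto V0_at = [&](long step) {
    if (rp.ramp_steps <= 0 || step >= rp.ramp_steps) return rp.V0_end;
    double s = (double)step / (double)rp.ramp_steps;
    return rp.V0_start + s * (rp.V0_end - rp.V0_start);
  };

  Energies en = total_forces(topo, pos, xb, rp, V0_at(0), fv, fx, chain_id, false);

  long n_frames = (sample_every > 0) ? n_steps / sample_every : 0;
  List frames(record_frames ? (int)(n_frames + 1) : 0);
  std::vector<double> obs_t, obs_A, obs_V, obs_v, obs_da, obs_Eb, obs_EA,
      obs_EV, obs_Ebond, obs_Eexcl, obs_Efil, obs_Ekin, obs_lambda, obs_acc;
  long flips_attempted = 0, flips_accepted = 0;

  auto record = [&](long step, int frame_idx, double acc_rate) {
    double A = total_area(pos.data(), topo.F);
    double Vol = total_volume(pos.data(), topo.F);
    double sumMA = 0, sumA = 0, lam = 0;
    for (int i = 0; i < nv; ++i) {
      VertexCurv c = vertex_curvature_one(i, topo, pos.data());
      sumMA += c.M * c.A;
      sumA += c.A;
    }
    Energies e2 = total_forces(topo, pos, xb, rp, V0_at(step), fv1, fx1,
                               chain_id, true);
    if (record_virial) {
      // per-vertex virial with the current constraint state
      double cen[3] = {0, 0, 0};
      for (int i = 0; i < nv; ++i)
        for (int d = 0; d < 3; ++d) cen[d] += pos[3 * i + d] / nv;
      std::vector<double> Vi(nv, 0.0), Ai(nv, 0.0);
      double prefA = -rp.kA * (A - rp.A0) / rp.A0;
      double prefV = -rp.kV * (Vol - V0_at(step)) / V0_at(step);
      double n[3], e[3], g[3], cx[3];
      for (const auto& f : topo.F) {
        double At = tri_area_normal(pos.data(), f, n);
        double inv = (At > 0) ? 1.0 / (2.0 * At) : 0.0;
        double W = 0.0;
        for (int c = 0; c < 3; ++c) {
          int j = f[(c + 1) % 3], k = f[(c + 2) % 3];
          vsub(pos.data() + 3 * k, pos.data() + 3 * j, e);
          vcross(n, e, g);
          double fi[3];
          for (int d = 0; d < 3; ++d) fi[d] = prefA * 0.5 * inv * g[d];
          vcross(pos.data() + 3 * j, pos.data() + 3 * k, cx);
          for (int d = 0; d < 3; ++d) fi[d] += prefV * cx[d] / 6.0;
          for (int d = 0; d < 3; ++d)
            W += fi[d] * (pos[3 * f[c] + d] - cen[d]);
        }
        for (int c = 0; c < 3; ++c) {
          Vi[f[c]] += W / 3.0;
          Ai[f[c]] += At / 3.0;
        }
      }
      double u[3];
      for (size_t ed = 0; ed < topo.E.size(); ++ed) {
        int i = topo.E[ed][0], j = topo.E[ed][1];
        vsub(pos.data() + 3 * i, pos.data() + 3 * j, u);
        double len = vnorm(u);
        double w = bond_dU(len, rp.kb, rp.r_rep, rp.r_att) * len;
        Vi[i] += w / 2.0;
        Vi[j] += w / 2.0;
      }
      for (int i = 0; i < nv; ++i)
        lam += (Vi[i] + 2.0 * rp.kBT) / (2.0 * Ai[i]);
      lam /= nv;
    }
    obs_t.push_back(t0 + step * rp.dt);
    obs_A.push_back(A);
    obs_V.push_back(Vol);
    obs_v.push_back(6.0 * std::sqrt(M_PI) * Vol / std::pow(A, 1.5));
    obs_da.push_back(sumMA / (2.0 * std::sqrt(M_PI * sumA)));
    obs_Eb.push_back(e2.bend);
    obs_EA.push_back(e2.area);
    obs_EV.push_back(e2.volume);
    obs_Ebond.push_back(e2.bond);
    obs_Eexcl.push_back(e2.excl);
    obs_Efil.push_back(e2.fil_bond + e2.fil_bend + e2.bb + e2.bv);
    double ek = 0;
    for (int i = 0; i < 3 * nv; ++i) ek += 0.5 * rp.m_v * vv[i] * vv[i];
    for (int i = 0; i < 3 * nb; ++i) ek += 0.5 * rp.m_b * vx[i] * vx[i];
    obs_Ekin.push_back(ek);
    obs_lambda.push_back(lam);
    obs_acc.push_back(acc_rate);
    if (record_frames) {
      frames[frame_idx] = List::create(
          _["vertices"] = mat_out(pos), _["triangles"] = tris_out(topo.F),
          _["beads"] = mat_out(xb), _["vel_vertices"] = mat_out(vv),
          _["vel_beads"] = mat_out(vx));
    }
  };

  int frame_idx = 0;
  record(0, frame_idx++, NA_REAL);

  FlipParams fp_flip;
  fp_flip.kappa = rp.kappa; fp_flip.kA = rp.kA; fp_flip.A0 = rp.A0;
  fp_flip.kV = rp.kV; fp_flip.kb = rp.kb; fp_flip.r_rep = rp.r_rep;
  fp_flip.r_att = rp.r_att;

  for (long step = 1; step <= n_steps; ++step) {
    double V0_now = V0_at(step);
    // draw noise
    if (rp.gamma > 0 && rp.kBT > 0) {
      for (auto& z : beta_v) z = noise_sd * gauss(rng_t);
      for (auto& z : beta_x) z = noise_sd * gauss(rng_t);
    } else {
      std::fill(beta_v.begin(), beta_v.end(), 0.0);
      std::fill(beta_x.begin(), beta_x.end(), 0.0);
    }
    // position half of GJF
    for (int i = 0; i < 3 * nv; ++i)
      pos[i] += b_v * rp.dt * vv[i] +
                b_v * rp.dt * rp.dt / (2.0 * rp.m_v) * fv[i] +
                b_v * rp.dt / (2.0 * rp.m_v) * beta_v[i];
    for (int i = 0; i < 3 * nb; ++i)
      xb[i] += b_b * rp.dt * vx[i] +
               b_b * rp.dt * rp.dt / (2.0 * rp.m_b) * fx[i] +
               b_b * rp.dt / (2.0 * rp.m_b) * beta_x[i];
    // new forces
    Energies e1 = total_forces(topo, pos, xb, rp, V0_now, fv1, fx1, chain_id,
                               false);
    (void)e1;
    // velocity update
    for (int i = 0; i < 3 * nv; ++i)
      vv[i] = a_v * vv[i] + rp.dt / (2.0 * rp.m_v) * (a_v * fv[i] + fv1[i]) +
              b_v / rp.m_v * beta_v[i];
    for (int i = 0; i < 3 * nb; ++i)
      vx[i] = a_b * vx[i] + rp.dt / (2.0 * rp.m_b) * (a_b * fx[i] + fx1[i]) +
              b_b / rp.m_b * beta_x[i];
    std::swap(fv, fv1);
    std::swap(fx, fx1);

    // blow-up guard
    if (step % 200 == 0) {
      for (int i = 0; i < 3 * nv; ++i)
        if (!std::isfinite(pos[i]))
          stop("simulation blew up at step %ld (non-finite vertex coordinate); reduce dt", step);
      Rcpp::checkUserInterrupt();
    }

    double acc_rate = NA_REAL;
    if (flip_every > 0 && step % flip_every == 0) {
      double Acur = total_area(pos.data(), topo.F);
      double Vcur = total_volume(pos.data(), topo.F);
      FlipParams pp = fp_flip;
      pp.V0 = V0_now;
      int attempted = 0;
      int acc = flip_sweep_inplace(topo, pos.data(), pp, flip_q, rp.kBT, rng_f,
                                   Acur, Vcur, attempted);
      flips_attempted += attempted;
      flips_accepted += acc;
      acc_rate = attempted > 0 ? (double)acc / attempted : NA_REAL;
      // connectivity changed: refresh forces for the next step
      total_forces(topo, pos, xb, rp, V0_now, fv, fx, chain_id, false);
    }

    if (sample_every > 0 && step % sample_every == 0)
      record(step, frame_idx++, acc_rate);
  }

  DataFrame obs = DataFrame::create(
      _["t"] = obs_t, _["A"] = obs_A, _["V"] = obs_V, _["v"] = obs_v,
      _["da"] = obs_da, _["E_bend"] = obs_Eb, _["E_area"] = obs_EA,
      _["E_volume"] = obs_EV, _["E_bond"] = obs_Ebond, _["E_excl"] = obs_Eexcl,
      _["E_filament"] = obs_Efil, _["E_kin"] = obs_Ekin,
      _["lambda"] = obs_lambda, _["flip_accept"] = obs_acc);

  return List::create(
      _["vertices"] = mat_out(pos), _["triangles"] = tris_out(topo.F),
      _["beads"] = mat_out(xb), _["vel_vertices"] = mat_out(vv),
      _["vel_beads"] = mat_out(vx), _["observables"] = obs,
      _["frames"] = frames, _["flips_attempted"] = flips_attempted,
      _["flips_accepted"] = flips_accepted,
      _["t_final"] = t0 + n_steps * rp.dt);
}
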