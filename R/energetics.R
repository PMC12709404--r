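#' Model parameters for the vesicle + filament system
#'
#' Collects every physical constant and numerical knob of the model in
#' reduced units: the bead diameter \eqn{\sigma} is the length unit, the
#' thermal energy \eqn{k_BT} the energy unit, and bead/vertex masses the
#' mass unit, so the time unit is \eqn{\tau = \sigma\sqrt{m/k_BT}}.
#'
#' Membrane: bending rigidity `kappa` (Helfrich energy
#' \eqn{2\kappa\oint M^2 dA} with zero spontaneous curvature), harmonic
#' area and volume constraints with coefficients `k_A`, `k_V` and targets
#' `A_0`, `V_0`, and a two-part tether bond on each mesh edge (half-harmonic
#' repulsive core below `r_rep` and attractive tail above `r_att`, free in
#' between, stiffness `k_b`).  Nonneighbouring vertices repel through a
#' harmonic overlap penalty of range `sigma_vv` to prevent membrane
#' self-intersection.  The repulsive cutoff is named `r_rep` (not the bare
#' symbol used for it in shape analysis) to avoid a clash with the junction
#' retraction rate.
#'
#' Filaments: harmonic bonds (`k_fb`, rest length `r_0`), harmonic angle
#' bending about the straight state (`kappa_f`), bead-bead repulsion between
#' different chains (`k_bb`, range `sigma`), bead-vertex repulsion
#' (`k_bv = k_bb`, range `sigma_bv = sigma`), and a tangential propulsion
#' force of magnitude `f_p` per bead (Peclet number
#' \eqn{Pe = \sigma f_p / k_BT}).
#'
#' Dynamics: friction `gamma`, masses `m_b`, `m_v`, timestep `dt`;
#' membrane fluidity by Metropolis bond flips attempted with per-edge
#' probability `q` at sweep frequency `omega` (per unit time).
#'
#' @param kappa Membrane bending rigidity (k_BT). Default 20.
#' @param k_A,k_V Area/volume constraint coefficients. Defaults hold
#'   relative fluctuations below ~0.5\% at the default mesh size.
#' @param A_0,V_0 Reference area and target volume (set from the mesh by
#'   the state builders when `NA`).
#' @param k_b Tether bond stiffness (k_BT/sigma^2).
#' @param l_0 Reference edge length; `r_rep`/`r_att` default to 0.8 and
#'   1.2 `l_0`.
#' @param r_rep,r_att Repulsive / attractive bond cutoffs.
#' @param k_bb,k_bv,k_vv Overlap-penalty coefficients (bead-bead,
#'   bead-vertex, vertex-vertex).
#' @param sigma,sigma_bv,sigma_vv Interaction ranges (bead diameter).
#' @param k_fb Filament bond stiffness; `r_0` filament rest bond length.
#' @param r_0 Filament equilibrium bond length.
#' @param kappa_f Filament bending stiffness (k_BT); stiffness ratio
#'   \eqn{\chi = \kappa_f/\kappa}.
#' @param f_p Propulsion force magnitude (k_BT/sigma).
#' @param gamma Friction coefficient.
#' @param m_b,m_v Bead and vertex masses.
#' @param k_BT Thermal energy (1 in reduced units).
#' @param omega Flip-sweep frequency (sweeps per unit time).
#' @param q Per-edge flip attempt probability.
#' @param dt Integrator timestep.
#' @param tail_mode `"drive"`: the terminal bead is propelled along its
#'   incoming bond so total chain thrust is `n_bf * f_p`; `"free"`: no
#'   thrust on the last bead.
#' @param vv_exclusion Enable membrane self-avoidance (costly; required for
#'   strongly deflated shapes where membrane faces approach).
#' @param fd_h Step for the local finite differencing of the bending
#'   forces.
#' @return A classed list `model_params`.
#' @export
model_params <- function(kappa = 20, k_A = 250, k_V = 250,
                         A_0 = NA_real_, V_0 = NA_real_,
                         k_b = 80, l_0 = 1,
                         r_rep = 0.8 * l_0, r_att = 1.2 * l_0,
                         k_bb = 200, k_bv = k_bb, k_vv = k_bb,
                         sigma = 1, sigma_bv = sigma, sigma_vv = sigma,
                         k_fb = 200, r_0 = 1.024, kappa_f = 500,
                         f_p = 3.75, gamma = 1, m_b = 1, m_v = 1,
                         k_BT = 1, omega = 10, q = 0.3, dt = 1e-3,
                         tail_mode = c("drive", "free"),
                         vv_exclusion = TRUE, fd_h = 1e-5) {
  tail_mode <- match.arg(tail_mode)
  p <- list(kappa = kappa, k_A = k_A, k_V = k_V, A_0 = A_0, V_0 = V_0,
            k_b = k_b, l_0 = l_0, r_rep = r_rep, r_att = r_att,
            k_bb = k_bb, k_bv = k_bv, k_vv = k_vv, sigma = sigma,
            sigma_bv = sigma_bv, sigma_vv = sigma_vv, k_fb = k_fb,
            r_0 = r_0, kappa_f = kappa_f, f_p = f_p, gamma = gamma,
            m_b = m_b, m_v = m_v, k_BT = k_BT, omega = omega, q = q,
            dt = dt, tail_mode = tail_mode, vv_exclusion = vv_exclusion,
            fd_h = fd_h)
  validate_params(p)
  class(p) <- "model_params"
  p
}

validate_params <- function(p) {
  pos <- c("l_0", "sigma", "sigma_bv", "sigma_vv", "r_0", "m_b", "m_v",
           "k_BT", "dt")
  for (nm in pos)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] <= 0)
      stop(sprintf("parameter '%s' must be a positive scalar", nm))
  nng <- c("kappa", "k_A", "k_V", "k_b", "k_bb", "k_bv", "k_vv", "k_fb",
           "kappa_f", "gamma")
  for (nm in nng)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] < 0)
      stop(sprintf("parameter '%s' must be a non-negative scalar", nm))
  if (!(p$r_rep < p$l_0 && p$l_0 < p$r_att))
    stop("cutoffs must satisfy r_rep < l_0 < r_att")
  if (p$q < 0 || p$q > 1) stop("q must lie in [0, 1]")
  if (p$omega < 0) stop("omega must be non-negative")
  if (p$f_p < 0) stop("f_p must be non-negative")
  invisible(TRUE)
}

#' @export
print.model_params <- function(x, ...) {
  cat("model_params (reduced units: sigma = length, k_BT = energy):\n")
  cat(sprintf("  membrane: kappa = %g, k_A = %g, k_V = %g, k_b = %g, l_0 = %g, cutoffs [%g, %g]\n",
              x$kappa, x$k_A, x$k_V, x$k_b, x$l_0, x$r_rep, x$r_att))
  cat(sprintf("  filaments: k_fb = %g, r_0 = %g, kappa_f = %g (chi = %g), f_p = %g (Pe = %g)\n",
              x$k_fb, x$r_0, x$kappa_f, x$kappa_f / x$kappa, x$f_p,
              x$sigma * x$f_p / x$k_BT))
  cat(sprintf("  dynamics: gamma = %g, dt = %g, flips omega = %g, q = %g, tail '%s'\n",
              x$gamma, x$dt, x$omega, x$q, x$tail_mode))
  invisible(x)
}

#' Helfrich bending energy and forces
#'
#' Discrete bending energy \eqn{2\kappa \sum_i M_i^2 A_i} from the
#' cotangent-Laplacian curvature field, and the corresponding vertex forces
#' computed by centered finite differences of the exact local energy
#' (moving a vertex only changes the curvature of the vertex and its
#' one-ring, so the differencing is local and O(N) per evaluation).
#'
#' @param mesh A `tri_mesh`.
#' @param kappa Bending rigidity.
#' @param fd_h Finite-difference step.
#' @return List with `energy` and `forces` (N_v x 3).
#' @export
bending_energy_forces <- function(mesh, kappa, fd_h = 1e-5) {
  stopifnot(inherits(mesh, "tri_mesh"), kappa >= 0)
  cpp_bending(mesh$positions, mesh$triangles, kappa, fd_h)
}

#' Harmonic area / volume constraint energy and forces
#'
#' \eqn{U = k (X - X_0)^2 / (2 X_0)} with \eqn{X} the mesh area or enclosed
#' volume; forces are the exact analytic gradients of the constrained
#' quantity times the restoring prefactor.
#'
#' @param mesh A `tri_mesh`.
#' @param k Constraint coefficient.
#' @param X_0 Target value (> 0).
#' @param which `"area"` or `"volume"`.
#' @return List with `energy`, `forces`, and `value` (current X).
#' @export
harmonic_constraint <- function(mesh, k, X_0, which = c("area", "volume")) {
  which <- match.arg(which)
  stopifnot(inherits(mesh, "tri_mesh"), k >= 0, X_0 > 0)
  cpp_constraint(mesh$positions, mesh$triangles, k, X_0, which)
}

#' Tether bond potential of a single edge
#'
#' Two-part half-harmonic potential keeping edge lengths in a band:
#' \eqn{U = k_b (r - r_{rep})^2/2} below the repulsive cutoff,
#' zero in the dead zone, and \eqn{k_b (r - r_{att})^2/2} beyond the
#' attractive cutoff; continuous with continuous first derivative.
#'
#' @param r Edge length(s).
#' @param k_b Bond stiffness.
#' @param r_rep,r_att Repulsive and attractive cutoffs.
#' @return Data frame with `r`, `energy`, and `force` (magnitude of the
#'   restoring force, positive toward the dead zone).
#' @export
edge_bond_potential <- function(r, k_b, r_rep, r_att) {
  stopifnot(all(r > 0), r_rep < r_att)
  energy <- ifelse(r < r_rep, 0.5 * k_b * (r - r_rep)^2,
                   ifelse(r > r_att, 0.5 * k_b * (r - r_att)^2, 0))
  dU <- ifelse(r < r_rep, k_b * (r - r_rep),
               ifelse(r > r_att, k_b * (r - r_att), 0))
  data.frame(r = r, energy = energy, force = -dU)
}

#' Tether bond energy and forces of all mesh edges
#'
#' @param mesh A `tri_mesh`.
#' @param params A `model_params` (uses `k_b`, `r_rep`, `r_att`).
#' @return List with `energy`, `forces`, and per-edge pair virials
#'   `edge_virial` (\eqn{f_i \cdot (r_i - r_j)}).
#' @export
mesh_bond_forces <- function(mesh, params) {
  stopifnot(inherits(mesh, "tri_mesh"))
  cpp_edge_bond(mesh$positions, mesh$edges, params$k_b, params$r_rep,
                params$r_att)
}

#' Membrane self-avoidance energy and forces
#'
#' Harmonic overlap penalty \eqn{k_{vv}(r-\sigma_{vv})^2 H(\sigma_{vv}-r)/2}
#' between every pair of nonneighbouring vertices (pairs sharing an edge
#' are excluded; nearest neighbours are already kept apart by the bond dead
#' zone).  Evaluated with a hash-grid spatial partition; `method = "brute"`
#' forces the all-pairs sum (testing oracle).
#'
#' @param mesh A `tri_mesh`.
#' @param params A `model_params` (uses `k_vv`, `sigma_vv`).
#' @param method `"grid"` or `"brute"`.
#' @return List with `energy` and `forces`.
#' @export
self_exclusion <- function(mesh, params, method = c("grid", "brute")) {
  method <- match.arg(method)
  cpp_vertex_exclusion(mesh$positions, mesh$edges, params$k_vv,
                       params$sigma_vv, method == "grid")
}
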