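#' Validity of a bond flip
#'
#' A flip replaces the two triangles sharing an edge by the two triangles
#' on the opposite diagonal of their quad.  The move is valid when the
#' opposite-diagonal edge does not already exist, neither endpoint of the
#' flipped edge would drop below degree 3, and both new triangles are
#' non-degenerate.
#'
#' @param mesh A `tri_mesh`.
#' @param edge Integer pair of (1-based) vertex indices naming an existing
#'   edge.
#' @return Logical.
#' @export
flip_valid <- function(mesh, edge) {
  stopifnot(inherits(mesh, "tri_mesh"), length(edge) == 2)
  cpp_flip_valid(mesh$positions, mesh$triangles, edge[1], edge[2])
}

#' Energy change of a bond flip
#'
#' \eqn{\Delta U = \Delta U_{bend} + \Delta U_A + \Delta U_V + \Delta U_r +
#' \Delta U_a} evaluated locally: only the four quad vertices change their
#' curvature and mixed area, the area/volume change comes from the two
#' retriangulated faces, and the bond term compares the removed diagonal
#' with the inserted one.  The local value equals a global before/after
#' recomputation to machine precision.
#'
#' @param mesh A `tri_mesh`.
#' @param params A `model_params` with `A_0` and `V_0` set.
#' @param edge Integer vertex pair.
#' @return Scalar energy change.
#' @export
flip_delta_energy <- function(mesh, params, edge) {
  stopifnot(inherits(mesh, "tri_mesh"), is.finite(params$A_0),
            is.finite(params$V_0))
  cpp_flip_delta_energy(mesh$positions, mesh$triangles, edge[1], edge[2],
                        params)
}

#' Metropolis flip sweep
#'
#' Attempts each edge with probability `q` in a random order; a flip is
#' always accepted when \eqn{\Delta U < 0} and otherwise with probability
#' \eqn{\exp(-\Delta U / k_BT)}.  Vertex count, edge count and triangle
#' count are invariant; only the connectivity changes.  Vertex velocities
#' are untouched (connectivity is not a dynamical coordinate).
#'
#' @param mesh A `tri_mesh`.
#' @param params A `model_params` with `A_0`, `V_0` set.
#' @param q Per-edge attempt probability (overrides `params$q` when given).
#' @param seed Integer seed for the sweep's RNG stream.
#' @return List with the updated `mesh` and counters `attempted`,
#'   `accepted`.
#' @export
flip_sweep <- function(mesh, params, q = params$q, seed = 1L) {
  stopifnot(inherits(mesh, "tri_mesh"), q >= 0, q <= 1)
  out <- cpp_flip_sweep(mesh$positions, mesh$triangles, params, q,
                        params$k_BT, as.integer(seed))
  list(mesh = tri_mesh(mesh$positions, out$triangles),
       attempted = out$attempted, accepted = out$accepted)
}
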