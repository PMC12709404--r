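#' Per-vertex virial contributions of constraint and bond forces
#'
#' Building block of the membrane-tension estimator.  The area/volume
#' constraint forces are treated as the external load on each triangular
#' element: every triangle contributes the sum of (force share) dot
#' (vertex position relative to the mesh centroid) over its three
#' vertices, distributed equally to them (the 1/3 of the combination
#' rule).  The elastic tether bonds are internal pair forces and enter
#' through the relative-coordinate pair virial \eqn{f_i\cdot(r_i - r_j)},
#' half to each endpoint, with the sign flipped so that stretched bonds
#' pull the tension up (internal forces enter a tension estimate with the
#' opposite sign of external loads).  Centroid referencing and the pair
#' form keep the estimator independent of the coordinate origin.  Bending
#' forces are excluded: they act perpendicular to the surface and carry no
#' in-plane stress.
#'
#' @param mesh A `tri_mesh`.
#' @param params A `model_params` with `A_0`, `V_0` set (the constraint
#'   state defines the forces).
#' @param include_repulsion Also add the self-avoidance (vertex-vertex)
#'   pair virial; off by default (the estimator's force list is constraint
#'   + bond).
#' @return List with per-vertex `virial`, per-vertex areas `A_i` (one third
#'   of the surrounding triangle area), and the current `area` and
#'   `volume`.
#' @export
vertex_virial <- function(mesh, params, include_repulsion = FALSE) {
  stopifnot(inherits(mesh, "tri_mesh"), is.finite(params$A_0),
            is.finite(params$V_0))
  out <- cpp_vertex_virial(mesh$positions, mesh$triangles, mesh$edges,
                           params$k_A, params$A_0, params$k_V, params$V_0,
                           params$k_b, params$r_rep, params$r_att)
  if (include_repulsion) {
    ex <- self_exclusion(mesh, params)
    # pair virial of the repulsion forces, relative coordinates
    # (forces returned per vertex; recompute pairwise for the virial)
    P <- mesh$positions
    n <- nrow(P)
    add <- numeric(n)
    rng <- params$sigma_vv
    for (i in seq_len(n - 1)) {
      d <- P[(i + 1):n, , drop = FALSE] -
        matrix(P[i, ], n - i, 3, byrow = TRUE)
      r <- sqrt(rowSums(d^2))
      js <- which(r < rng & r > 0) + i
      for (j in js) {
        if (any(mesh$edges[, 1] == min(i, j) & mesh$edges[, 2] == max(i, j)))
          next
        rij <- sqrt(sum((P[i, ] - P[j, ])^2))
        w <- params$k_vv * (rij - rng) * rij   # gradient-convention pair virial
        add[i] <- add[i] + w / 2
        add[j] <- add[j] + w / 2
      }
    }
    out$virial <- out$virial + add
  }
  out
}

#' Reference tension scale
#'
#' \eqn{\lambda_0 = R^2 k_BT / (\pi \sigma^4)}: the scale against which the
#' measured tension is compared; vesicles with \eqn{\bar\lambda/\lambda_0}
#' well below one are floppy (shape set by constraints and activity, not
#' tension).
#'
#' @param R Vesicle nominal radius.
#' @param k_BT Thermal energy.
#' @param sigma Bead diameter.
#' @return Scalar tension scale.
#' @export
lambda0 <- function(R, k_BT = 1, sigma = 1) {
  stopifnot(R > 0)
  R^2 * k_BT / (pi * sigma^4)
}

#' Mean membrane tension of a trajectory tail
#'
#' Spatial and temporal average of the local stresses:
#' \eqn{\bar\lambda = \langle (V_i(t) + 2 k_BT) / (2 A_i)\rangle_{i,t}} with
#' \eqn{V_i} the per-vertex virial of the constraint and bond forces, the
#' kinetic \eqn{2 k_BT} from equipartition, and the factor of two for the
#' two-dimensional membrane.  The per-frame vertex average is recorded
#' during the run; this function averages it over the configured tail
#' window.
#'
#' @param traj A `ves_trajectory` (or a data frame with columns `t` and
#'   `lambda`).
#' @param window Averaging window: the last `window` time units (default:
#'   the trailing 60\% of the run).
#' @param R Vesicle radius for the reference scale; default from `A_0`.
#' @return List of class `tension_report`: `lambda_bar`, `lambda_0`,
#'   `ratio`, `n_frames`, `window`.
#' @export
mean_tension <- function(traj, window = NULL, R = NULL) {
  obs <- if (is.data.frame(traj)) traj else traj$observables
  stopifnot(all(c("t", "lambda") %in% names(obs)))
  tmax <- max(obs$t)
  if (is.null(window)) window <- 0.6 * (tmax - min(obs$t))
  keep <- obs$t >= tmax - window
  if (!any(keep)) stop("empty averaging window")
  lam <- mean(obs$lambda[keep])
  if (is.null(R)) {
    A0 <- if (!is.data.frame(traj) && !is.null(traj$A_0)) traj$A_0
          else mean(obs$A[keep])
    R <- sqrt(A0 / (4 * pi))
  }
  l0 <- lambda0(R)
  structure(list(lambda_bar = lam, lambda_0 = l0, ratio = lam / l0,
                 n_frames = sum(keep), window = window),
            class = "tension_report")
}

#' @export
print.tension_report <- function(x, ...) {
  cat(sprintf("membrane tension: lambda_bar = %.4g, lambda_0 = %.4g, ratio = %.4g\n",
              x$lambda_bar, x$lambda_0, x$ratio))
  cat(sprintf("  averaged over %d frames (window %.3g time units)\n",
              x$n_frames, x$window))
  invisible(x)
}
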