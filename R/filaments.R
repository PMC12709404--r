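#' Construct a system of semiflexible filaments
#'
#' Active filaments are bead-spring chains: `n_f` chains of `n_bf` beads
#' each, with harmonic bonds, harmonic angle bending about the straight
#' state, excluded volume against beads of other chains and against the
#' membrane vertices, and a tangential propulsion force along the local
#' bond direction.
#'
#' @param positions Numeric matrix (n_f * n_bf x 3) of bead coordinates;
#'   beads of chain k occupy rows ((k-1) n_bf + 1) : (k n_bf).
#' @param n_f Number of chains.
#' @param n_bf Beads per chain (>= 1).
#' @return A classed list `filament_system`.
#' @export
filament_system <- function(positions, n_f, n_bf) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  stopifnot(ncol(positions) == 3 || nrow(positions) == 0,
            n_f >= 0, n_bf >= 1, nrow(positions) == n_f * n_bf)
  structure(list(positions = positions, n_f = as.integer(n_f),
                 n_bf = as.integer(n_bf)),
            class = "filament_system")
}

#' @export
print.filament_system <- function(x, ...) {
  cat(sprintf("filament_system: %d chains x %d beads\n", x$n_f, x$n_bf))
  invisible(x)
}

#' Chain bond energy and forces
#'
#' Harmonic bonds \eqn{k_{fb}(r - r_0)^2 / 2} between consecutive beads of
#' each chain.
#'
#' @param fil A `filament_system`.
#' @param k_fb Bond stiffness.
#' @param r_0 Rest length.
#' @return List with `energy` and `forces`.
#' @export
chain_bond <- function(fil, k_fb, r_0) {
  stopifnot(inherits(fil, "filament_system"), fil$n_bf >= 2)
  out <- cpp_chain_forces(fil$positions, fil$n_f, fil$n_bf, k_fb, r_0, 0)
  list(energy = out$energy_bond, forces = out$forces)
}

#' Chain bending energy and forces
#'
#' Harmonic angle potential \eqn{\kappa_f (\theta - \pi)^2 / 2} over the
#' `n_bf - 2` angles between consecutive bead triples; a straight chain is
#' the zero-energy ground state.
#'
#' @param fil A `filament_system`.
#' @param kappa_f Filament bending stiffness.
#' @return List with `energy` and `forces`.
#' @export
chain_bend <- function(fil, kappa_f) {
  stopifnot(inherits(fil, "filament_system"), fil$n_bf >= 3)
  out <- cpp_chain_forces(fil$positions, fil$n_f, fil$n_bf, 1, 1, kappa_f)
  # bond forces were computed with dummy stiffness: recompute bend only
  out2 <- cpp_chain_forces(fil$positions, fil$n_f, fil$n_bf, 0, 1, kappa_f)
  list(energy = out$energy_bend, forces = out2$forces)
}

#' Harmonic overlap repulsion between point sets
#'
#' \eqn{U = k (r - range)^2 H(range - r)/2} for each pair within range.
#' With one point set, pairs inside the same chain (equal `group`) are
#' excluded: intra-chain overlap is controlled by bonds and bending alone.
#' The default evaluation uses a hash-grid spatial partition; the brute
#' all-pairs sum is kept as a testing oracle.
#'
#' @param A,B Point matrices (set `B = NULL` for within-set pairs).
#' @param k Repulsion coefficient.
#' @param range Interaction range.
#' @param group Optional integer group ids for within-set exclusions.
#' @param method `"grid"` or `"brute"`.
#' @return List with `energy`, `forces_A`, `forces_B`.
#' @export
pairwise_repulsion <- function(A, B = NULL, k, range, group = NULL,
                               method = c("grid", "brute")) {
  method <- match.arg(method)
  A <- as.matrix(A)
  same <- is.null(B)
  Bm <- if (same) matrix(0, 0, 3) else as.matrix(B)
  grp <- if (is.null(group)) integer(0) else as.integer(group)
  out <- cpp_pair_repulsion(A, Bm, same, k, range, grp, method == "grid")
  if (same) out["forces_B"] <- list(NULL)
  out
}

#' Tangential propulsion forces
#'
#' Every bead is driven with force `f_p` along the bond to its successor;
#' the terminal bead follows `tail_mode` (`"drive"`: along its incoming
#' bond, so total chain thrust is `n_bf * f_p`; `"free"`: none).  Single
#' beads (`n_bf = 1`) are apolar and receive no thrust.
#'
#' @param fil A `filament_system`.
#' @param f_p Propulsion magnitude.
#' @param tail_mode `"drive"` or `"free"`.
#' @return Force matrix (rows match bead positions).
#' @export
active_force <- function(fil, f_p, tail_mode = c("drive", "free")) {
  tail_mode <- match.arg(tail_mode)
  stopifnot(inherits(fil, "filament_system"))
  cpp_active_forces(fil$positions, fil$n_f, fil$n_bf, f_p,
                    tail_mode == "drive")
}

#' Filament descriptors
#'
#' Dimensionless descriptors of a filament system inside a vesicle of
#' nominal radius `R`: the rescaled contour length
#' \eqn{L = (r_0 (n_{bf} - 1) + \sigma)/\sigma}, the volume-fraction
#' concentration \eqn{\phi = n_f n_{bf} (\sigma / 2R)^3} (reported in
#' percent), the Peclet number \eqn{Pe = \sigma f_p / k_BT}, the stiffness
#' ratio \eqn{\chi = \kappa_f / \kappa}, and the persistence-length proxy
#' `P`: the mean end-to-end distance over chains in units of
#' \eqn{\sigma}.
#'
#' @param fil A `filament_system`.
#' @param params A `model_params`.
#' @param R Vesicle nominal radius (from the reference area
#'   \eqn{A_0 = 4\pi R^2}).
#' @return List of class `filament_metrics`: `L`, `phi_percent`, `Pe`,
#'   `chi`, `P`.
#' @export
filament_metrics <- function(fil, params, R) {
  stopifnot(inherits(fil, "filament_system"), R > 0)
  L <- (params$r_0 * (fil$n_bf - 1) + params$sigma) / params$sigma
  if (fil$n_bf == 1) L <- 1
  phi <- fil$n_f * fil$n_bf * (params$sigma / (2 * R))^3
  P <- NA_real_
  if (fil$n_f > 0) {
    ee <- vapply(seq_len(fil$n_f), function(k) {
      i0 <- (k - 1) * fil$n_bf + 1
      i1 <- k * fil$n_bf
      sqrt(sum((fil$positions[i1, ] - fil$positions[i0, ])^2))
    }, numeric(1))
    P <- mean(ee) / params$sigma
  }
  structure(list(L = L, phi_percent = 100 * phi,
                 Pe = params$sigma * params$f_p / params$k_BT,
                 chi = params$kappa_f / params$kappa, P = P),
            class = "filament_metrics")
}

#' @export
print.filament_metrics <- function(x, ...) {
  cat(sprintf("filaments: L = %.3g, phi = %.3g%%, Pe = %.3g, chi = %.3g, P = %.3g\n",
              x$L, x$phi_percent, x$Pe, x$chi, x$P))
  invisible(x)
}

#' Filament rest bond length for a target contour length
#'
#' Inverts \eqn{L = (r_0 (n_{bf} - 1) + \sigma)/\sigma} for `r_0`.
#' @param L Target rescaled length (> 1).
#' @param n_bf Beads per chain (>= 2).
#' @param sigma Bead diameter.
#' @return Rest bond length `r_0`.
#' @export
bond_length_for_L <- function(L, n_bf, sigma = 1) {
  stopifnot(L > 1, n_bf >= 2)
  sigma * (L - 1) / (n_bf - 1)
}

#' Seed straight filaments inside a sphere
#'
#' Places `n_f` straight rods of `n_bf` beads at uniformly random interior
#' positions and orientations, rejection-sampling each candidate against
#' overlap with the membrane (all beads at least `margin` inside radius
#' `R`) and with previously placed chains (no two beads of different
#' chains closer than `sigma`).
#'
#' @param n_f,n_bf Chain count and beads per chain.
#' @param r_0 Bond rest length.
#' @param R Vesicle radius.
#' @param sigma Bead diameter.
#' @param margin Clearance from the membrane (default `sigma`).
#' @param max_tries Attempts per chain before giving up.
#' @return A `filament_system`.  Uses the R RNG (seed with [set.seed()]).
#' @export
seed_filaments <- function(n_f, n_bf, r_0, R, sigma = 1, margin = sigma,
                           max_tries = 2000L) {
  if (n_f == 0) return(filament_system(matrix(0, 0, 3), 0, n_bf))
  rod_len <- r_0 * (n_bf - 1)
  if (rod_len + 2 * margin >= 2 * R)
    stop("filaments are too long to fit inside the vesicle")
  placed <- list()
  for (k in seq_len(n_f)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      ctr <- repeat_sample_center(R - margin - rod_len / 2)
      s <- (seq_len(n_bf) - (n_bf + 1) / 2) * r_0
      pts <- cbind(ctr[1] + s * u[1], ctr[2] + s * u[2], ctr[3] + s * u[3])
      if (max(sqrt(rowSums(pts^2))) > R - margin) next
      clash <- FALSE
      for (q in placed) {
        d2 <- outer(rowSums(pts^2), rowSums(q^2), "+") - 2 * pts %*% t(q)
        if (min(d2) < sigma^2) { clash <- TRUE; break }
      }
      if (!clash) { placed[[k]] <- pts; ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf("could not place chain %d without overlap (packing too dense)", k))
  }
  filament_system(do.call(rbind, placed), n_f, n_bf)
}

# uniform point in a ball of the given radius
repeat_sample_center <- function(rmax) {
  if (rmax <= 0) return(c(0, 0, 0))
  repeat {
    p <- runif(3, -rmax, rmax)
    if (sum(p^2) <= rmax^2) return(p)
  }
}
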