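# shared helpers for the test suite

# a slightly roughened icosphere: generic positions (no symmetry-degenerate
# configurations) while remaining a valid closed mesh
noisy_icosphere <- function(subdivisions = 1, radius = 2, sd = 0.05,
                            seed = 7) {
  set.seed(seed)
  m <- build_icosphere(subdivisions, radius)
  tri_mesh(m$positions + matrix(rnorm(m$n_vertices * 3, 0, sd), ncol = 3),
           m$triangles)
}

# dense centered finite-difference gradient of a scalar function of a
# position matrix
num_grad <- function(efun, X, h = 1e-6) {
  G <- X * 0
  for (i in seq_len(nrow(X))) {
    for (d in 1:3) {
      Xp <- X; Xm <- X
      Xp[i, d] <- Xp[i, d] + h
      Xm[i, d] <- Xm[i, d] - h
      G[i, d] <- (efun(Xp) - efun(Xm)) / (2 * h)
    }
  }
  G
}

# total potential energy of a passive membrane under the given parameters
membrane_energy <- function(mesh, p) {
  bending_energy_forces(mesh, p$kappa, p$fd_h)$energy +
    harmonic_constraint(mesh, p$k_A, p$A_0, "area")$energy +
    harmonic_constraint(mesh, p$k_V, p$V_0, "volume")$energy +
    mesh_bond_forces(mesh, p)$energy +
    self_exclusion(mesh, p)$energy
}

# apply a single bond flip at R level (both windings tried; the orientation
# check in tri_mesh() picks the consistent one)
apply_flip_R <- function(mesh, e) {
  F <- mesh$triangles
  ts <- which(apply(F, 1, function(tr) all(e %in% tr)))
  c1 <- setdiff(F[ts[1], ], e)
  c2 <- setdiff(F[ts[2], ], e)
  a <- e[1]; b <- e[2]
  F1 <- F; F1[ts[1], ] <- c(a, c2, c1); F1[ts[2], ] <- c(b, c1, c2)
  tryCatch(tri_mesh(mesh$positions, F1),
           error = function(err) {
             F2 <- F
             F2[ts[1], ] <- c(a, c1, c2); F2[ts[2], ] <- c(b, c2, c1)
             tri_mesh(mesh$positions, F2)
           })
}

# canonical face set for connectivity comparison (flip involutions restore
# the face set, not necessarily the row order or rotation)
canon_faces <- function(F) {
  s <- t(apply(F, 1, sort))
  s[order(s[, 1], s[, 2], s[, 3]), , drop = FALSE]
}
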