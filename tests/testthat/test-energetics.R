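test_that("discrete bending energy of a sphere approaches 8 pi kappa", {
  for (kappa in c(1, 20)) {
    m <- build_icosphere(3, 4)
    E <- bending_energy_forces(m, kappa)$energy
    expect_equal(E, 8 * pi * kappa, tolerance = 5e-3)
  }
})

test_that("bending forces match dense finite differences", {
  m <- noisy_icosphere(1, 2, 0.05)
  f <- bending_energy_forces(m, 20)$forces
  g <- num_grad(function(X) {
    bending_energy_forces(tri_mesh(X, m$triangles), 20)$energy
  }, m$positions)
  expect_lt(max(abs(f + g)) / max(abs(f)), 1e-5)
})

test_that("constraint forces are exact gradients", {
  m <- noisy_icosphere(1, 2, 0.05)
  A0 <- mesh_area(m) * 1.05
  V0 <- mesh_volume(m) * 0.9
  fa <- harmonic_constraint(m, 250, A0, "area")
  ga <- num_grad(function(X)
    harmonic_constraint(tri_mesh(X, m$triangles), 250, A0, "area")$energy,
    m$positions)
  expect_lt(max(abs(fa$forces + ga)) / max(abs(fa$forces)), 1e-5)
  fv <- harmonic_constraint(m, 250, V0, "volume")
  gv <- num_grad(function(X)
    harmonic_constraint(tri_mesh(X, m$triangles), 250, V0, "volume")$energy,
    m$positions)
  expect_lt(max(abs(fv$forces + gv)) / max(abs(fv$forces)), 1e-5)
  # energies follow the harmonic forms
  expect_equal(fa$energy, 250 * (mesh_area(m) - A0)^2 / (2 * A0))
  expect_equal(fv$energy, 250 * (mesh_volume(m) - V0)^2 / (2 * V0))
})

test_that("tether bond potential is two-part with a flat dead zone", {
  p <- model_params()
  r <- c(0.5, 0.8, 1.0, 1.2, 1.5)
  tab <- edge_bond_potential(r, p$k_b, p$r_rep, p$r_att)
  expect_equal(tab$energy,
               c(0.5 * p$k_b * 0.3^2, 0, 0, 0, 0.5 * p$k_b * 0.3^2))
  expect_equal(tab$force, c(p$k_b * 0.3, 0, 0, 0, -p$k_b * 0.3))
  # continuity at the cutoffs
  eps <- 1e-9
  near <- edge_bond_potential(c(p$r_rep - eps, p$r_rep + eps,
                                p$r_att - eps, p$r_att + eps),
                              p$k_b, p$r_rep, p$r_att)
  expect_lt(max(abs(near$energy)), 1e-12)
  expect_lt(max(abs(near$force)), 1e-6)
})

test_that("mesh bond forces match finite differences on a stretched mesh", {
  p <- model_params()
  m0 <- noisy_icosphere(1, 2, 0.05)
  m <- tri_mesh(m0$positions * 1.3, m0$triangles)
  out <- mesh_bond_forces(m, p)
  expect_gt(out$energy, 0)
  g <- num_grad(function(X)
    mesh_bond_forces(tri_mesh(X, m$triangles), p)$energy, m$positions)
  expect_lt(max(abs(out$forces + g)) / max(abs(out$forces)), 1e-5)
})

test_that("per-edge bond virial is the mechanical pair virial", {
  # a single stretched edge of length r_att + delta carries
  # f . (r_i - r_j) = -k_b * delta * (r_att + delta)
  p <- model_params()
  delta <- 0.25
  scale <- (p$r_att + delta)  # tetrahedron with unit edges, rescaled
  V <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    scale / sqrt(8)
  m <- tri_mesh(V, rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3)))
  expect_equal(edge_lengths(m), rep(p$r_att + delta, 6), tolerance = 1e-12)
  out <- mesh_bond_forces(m, p)
  expect_equal(out$edge_virial,
               rep(-p$k_b * delta * (p$r_att + delta), 6), tolerance = 1e-10)
})

test_that("self-exclusion grid agrees with the brute-force oracle", {
  p <- model_params()
  m0 <- noisy_icosphere(1, 2, 0.05)
  m <- tri_mesh(m0$positions * 0.35, m0$triangles)  # squeezed: overlaps
  a <- self_exclusion(m, p, "grid")
  b <- self_exclusion(m, p, "brute")
  expect_gt(a$energy, 0)
  expect_equal(a$energy, b$energy, tolerance = 1e-12)
  expect_equal(a$forces, b$forces, tolerance = 1e-12)
})

test_that("edge-sharing vertex pairs are excluded from self-avoidance", {
  # a regular mesh with all edges shorter than sigma_vv would otherwise
  # blow up; only non-neighbour pairs may contribute
  m <- build_icosphere(2, 0.5 * icosphere_radius_for_edge(2))
  p <- model_params()
  el <- edge_lengths(m)
  expect_true(all(el < p$sigma_vv))
  out <- self_exclusion(m, p, "brute")
  # contributions exist (opposite-side vertices of the small sphere overlap)
  # but none from bonded pairs: energy must be finite and forces balanced
  expect_true(is.finite(out$energy))
  expect_equal(colSums(out$forces), c(0, 0, 0), tolerance = 1e-9)
})

test_that("model_params validates its inputs", {
  expect_error(model_params(r_rep = 1.1), "r_rep < l_0")
  expect_error(model_params(dt = -1), "positive")
  expect_error(model_params(kappa = -3), "non-negative")
  expect_error(model_params(q = 2), "q must lie")
  p <- model_params(kappa = 0, k_A = 0)   # zero stiffnesses are legal
  expect_s3_class(p, "model_params")
})
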