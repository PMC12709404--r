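test_that("icosphere counts follow the subdivision formulas", {
  for (s in 0:2) {
    m <- build_icosphere(s)
    expect_identical(m$n_vertices, as.integer(10 * 4^s + 2))
    expect_identical(m$n_triangles, as.integer(20 * 4^s))
    expect_identical(m$n_triangles, 2L * (m$n_vertices - 2L))
    expect_identical(m$n_vertices - m$n_edges + m$n_triangles, 2L)
  }
})

test_that("icosphere geometry converges to the sphere", {
  m <- build_icosphere(4, 1)
  expect_equal(mesh_area(m), 4 * pi, tolerance = 2e-3)
  expect_equal(mesh_volume(m), 4 * pi / 3, tolerance = 3e-3)
  expect_equal(reduced_volume(m), 1, tolerance = 1e-3)
  expect_true(all(abs(sqrt(rowSums(m$positions^2)) - 1) < 1e-12))
})

test_that("mesh validation rejects broken inputs", {
  m <- build_icosphere(1)
  # degenerate triangle
  F <- m$triangles
  F[1, 2] <- F[1, 1]
  expect_error(tri_mesh(m$positions, F), "degenerate")
  # open surface (drop a face): boundary edge detected
  expect_error(tri_mesh(m$positions, m$triangles[-1, ]), "closed|Euler")
  # globally inverted orientation: negative signed volume
  expect_error(tri_mesh(m$positions, m$triangles[, c(1, 3, 2)]),
               "volume")
  # two faces flipped locally: directed-edge duplication
  F2 <- m$triangles
  F2[1, ] <- F2[1, c(1, 3, 2)]
  expect_error(tri_mesh(m$positions, F2), "orient")
  # out-of-range index
  F3 <- m$triangles
  F3[1, 1] <- m$n_vertices + 5L
  expect_error(tri_mesh(m$positions, F3), "range")
})

test_that("curvature field recovers sphere mean curvature M = 1/R", {
  for (R in c(1, 3)) {
    m <- build_icosphere(3, R)
    cv <- vertex_curvature(m)
    expect_equal(mean(cv$M), 1 / R, tolerance = 1e-3)
    expect_equal(sum(cv$A_mixed), mesh_area(m), tolerance = 1e-10)
  }
})

test_that("membrane asymmetry is 1 for a sphere, any radius", {
  da1 <- membrane_asymmetry(build_icosphere(3, 1))
  da5 <- membrane_asymmetry(build_icosphere(3, 5))
  expect_equal(da1, 1, tolerance = 5e-3)   # discrete sphere, 0.25% off
  expect_equal(da5, da1, tolerance = 1e-10)  # exactly scale invariant
})

test_that("curvature sign flips for concave regions", {
  # push one vertex far inward: its neighbourhood becomes concave
  m <- build_icosphere(2, 3)
  P <- m$positions
  P[1, ] <- P[1, ] * 0.3
  m2 <- tri_mesh(P, m$triangles)
  cv <- vertex_curvature(m2)
  expect_lt(cv$M[1], 0)
})

test_that("edge-length helpers are mutually consistent", {
  s <- 3
  R <- icosphere_radius_for_edge(s, 1)
  m <- build_icosphere(s, R)
  expect_equal(mean(edge_lengths(m)), 1, tolerance = 0.08)
  expect_equal(reference_edge_length(mesh_area(m), m$n_triangles),
               sqrt(4 * mesh_area(m) / (sqrt(3) * m$n_triangles)))
})

test_that("reduced volume matches its definition", {
  m <- build_icosphere(2, 2)
  expect_equal(reduced_volume(m),
               6 * sqrt(pi) * mesh_volume(m) / mesh_area(m)^1.5)
})
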