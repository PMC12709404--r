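test_that("flip validity follows the quad rules", {
  m <- noisy_icosphere(1, 2, 0.05)
  # every edge of a generic icosphere with degree > 3 vertices and no
  # pre-existing opposite diagonal is flippable
  ok <- vapply(seq_len(nrow(m$edges)), function(i)
    flip_valid(m, m$edges[i, ]), logical(1))
  expect_true(any(ok))
  expect_error(flip_valid(m, c(1L, 2L)), "no such edge")  # 1-2 not an edge
})

test_that("local flip delta energy matches global recomputation", {
  m <- noisy_icosphere(1, 2, 0.05)
  p <- model_params(A_0 = mesh_area(m) * 1.02, V_0 = mesh_volume(m) * 0.95)
  U0 <- membrane_energy(m, p) - self_exclusion(m, p)$energy
  n_checked <- 0
  for (ei in seq_len(nrow(m$edges))) {
    e <- m$edges[ei, ]
    if (!flip_valid(m, e)) next
    dU_local <- flip_delta_energy(m, p, e)
    m2 <- apply_flip_R(m, e)
    dU_global <- membrane_energy(m2, p) - self_exclusion(m2, p)$energy - U0
    expect_equal(dU_local, dU_global, tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 50)
})

test_that("flip sweeps preserve counts and the Euler identity", {
  m <- noisy_icosphere(2, 3.2, 0.05)
  p <- model_params(A_0 = mesh_area(m), V_0 = mesh_volume(m))
  out <- flip_sweep(m, p, q = 0.5, seed = 3)
  m2 <- out$mesh
  expect_identical(m2$n_vertices, m$n_vertices)
  expect_identical(m2$n_edges, m$n_edges)
  expect_identical(m2$n_triangles, m$n_triangles)
  expect_identical(m2$n_vertices - m2$n_edges + m2$n_triangles, 2L)
  expect_gte(out$attempted, 1)
  expect_gte(out$accepted, 0)
  expect_lte(out$accepted, out$attempted)
})

test_that("a zero-probability sweep is the identity", {
  m <- noisy_icosphere(1, 2, 0.05)
  p <- model_params(A_0 = mesh_area(m), V_0 = mesh_volume(m))
  out <- flip_sweep(m, p, q = 0, seed = 3)
  expect_identical(canon_faces(out$mesh$triangles), canon_faces(m$triangles))
  expect_identical(out$attempted, 0L)
})

test_that("flipping the new diagonal restores the original face set", {
  m <- noisy_icosphere(1, 2, 0.05)
  e <- NULL
  for (ei in seq_len(nrow(m$edges)))
    if (flip_valid(m, m$edges[ei, ])) { e <- m$edges[ei, ]; break }
  m2 <- apply_flip_R(m, e)
  # the new diagonal joins the two off-edge vertices of the quad
  ts <- which(apply(m$triangles, 1, function(tr) all(e %in% tr)))
  diag2 <- c(setdiff(m$triangles[ts[1], ], e),
             setdiff(m$triangles[ts[2], ], e))
  m3 <- apply_flip_R(m2, sort(diag2))
  expect_identical(canon_faces(m3$triangles), canon_faces(m$triangles))
})

test_that("sweeps are reproducible for a fixed seed", {
  m <- noisy_icosphere(2, 3.2, 0.05)
  p <- model_params(A_0 = mesh_area(m), V_0 = mesh_volume(m))
  a <- flip_sweep(m, p, q = 0.5, seed = 17)
  b <- flip_sweep(m, p, q = 0.5, seed = 17)
  expect_identical(a$mesh$triangles, b$mesh$triangles)
  expect_identical(a$accepted, b$accepted)
})

test_that("flips relax a high-energy triangulation", {
  # stretch one diagonal family by displacing vertices: repeated sweeps at
  # low temperature should not increase the membrane energy
  m <- noisy_icosphere(2, 3.2, 0.15, seed = 21)
  # near-zero temperature: only downhill flips are accepted
  p <- model_params(A_0 = mesh_area(m), V_0 = mesh_volume(m), k_BT = 1e-9)
  U0 <- membrane_energy(m, p) - self_exclusion(m, p)$energy
  cur <- m
  for (i in 1:5) cur <- flip_sweep(cur, p, q = 0.3, seed = i)$mesh
  U1 <- membrane_energy(cur, p) - self_exclusion(cur, p)$energy
  expect_lte(U1, U0 + 1e-9)
})
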