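test_that("the virial tension reproduces the Laplace law on a sphere", {
  # inflate (V_0 > V) and deflate (V_0 < V): lambda = P R / 2 with
  # P = -dU_V/dV = -k_V (V - V_0)/V_0
  m <- build_icosphere(3, 4)
  R <- 4
  for (fac in c(1.04, 0.96)) {
    p <- model_params(A_0 = mesh_area(m), V_0 = mesh_volume(m) * fac,
                      k_A = 0, k_b = 0)
    P <- -p$k_V * (mesh_volume(m) - p$V_0) / p$V_0
    vv <- vertex_virial(m, p)
    lam_static <- mean(vv$virial / (2 * vv$A_i))
    expect_equal(lam_static, P * R / 2, tolerance = 0.01)
  }
})

test_that("bond contribution matches the stretched-network identity", {
  # uniformly stretched sphere: lambda = sum_e t_e r_e / (2 A)
  p <- model_params(k_A = 0, k_V = 0)
  m0 <- build_icosphere(2, icosphere_radius_for_edge(2))
  m <- tri_mesh(m0$positions * 1.3, m0$triangles)
  p$A_0 <- mesh_area(m); p$V_0 <- mesh_volume(m)
  vv <- vertex_virial(m, p)
  lam <- sum(vv$virial) / (2 * mesh_area(m))
  el <- edge_lengths(m)
  bt <- edge_bond_potential(el, p$k_b, p$r_rep, p$r_att)
  lam_ref <- sum(-bt$force * el) / (2 * mesh_area(m))
  expect_equal(lam, lam_ref, tolerance = 1e-10)
  expect_gt(lam, 0)   # stretched bonds pull inward: positive tension
})

test_that("lambda0 follows the entropic scale R^2 kBT / (pi sigma^4)", {
  expect_equal(lambda0(6.64), 6.64^2 / pi)
  expect_equal(lambda0(2, k_BT = 3, sigma = 2), 4 * 3 / (pi * 16))
})

test_that("mean_tension averages the trailing window of a run", {
  m <- build_icosphere(2, icosphere_radius_for_edge(2))
  p <- model_params(omega = 0, f_p = 0)
  tr <- sim_run(sim_state(m), p, duration = 2, sample_every = 0.1, seed = 6,
                flips = FALSE, record_frames = FALSE)
  rep1 <- mean_tension(tr)
  expect_s3_class(rep1, "tension_report")
  expect_true(is.finite(rep1$lambda_bar))
  expect_gt(rep1$lambda_0, 0)
  expect_equal(rep1$ratio, rep1$lambda_bar / rep1$lambda_0)
  # explicit window restricts the frames used
  rep2 <- mean_tension(tr, window = 0.5)
  expect_lt(rep2$n_frames, rep1$n_frames)
  obs <- tr$observables
  expect_equal(rep2$lambda_bar, mean(obs$lambda[obs$t >= max(obs$t) - 0.5]),
               tolerance = 1e-12)
})
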