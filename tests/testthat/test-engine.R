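test_that("runs are deterministic in the seed", {
  m <- build_icosphere(1, icosphere_radius_for_edge(1))
  p <- model_params(omega = 0)
  st <- sim_state(m)
  a <- sim_run(st, p, duration = 0.2, sample_every = 0.05, seed = 5)
  b <- sim_run(st, p, duration = 0.2, sample_every = 0.05, seed = 5)
  c <- sim_run(st, p, duration = 0.2, sample_every = 0.05, seed = 6)
  expect_identical(a$observables, b$observables)
  expect_identical(a$state$mesh$positions, b$state$mesh$positions)
  expect_false(identical(c$observables$A, a$observables$A))
})

test_that("derived RNG streams are distinct and stable", {
  s <- derive_seeds(42L)
  expect_named(s, c("thermostat", "flips", "init"))
  expect_identical(s, derive_seeds(42L))
  expect_true(all(s >= 0 & s < 2^31))
  expect_identical(length(unique(s)), 3L)
})

test_that("gamma = 0, T = 0 dynamics conserve energy (velocity Verlet limit)", {
  m <- build_icosphere(2, icosphere_radius_for_edge(2))
  p <- model_params(gamma = 0, k_BT = 1e-12, omega = 0, dt = 1e-3)
  set.seed(2)
  st <- sim_state(m)
  st$vel_vertices <- matrix(rnorm(m$n_vertices * 3, 0, 0.3), ncol = 3)
  tr <- sim_run(st, p, duration = 2, sample_every = 0.05, seed = 4,
                flips = FALSE, record_frames = FALSE)
  obs <- tr$observables
  Etot <- obs$E_kin + obs$E_bend + obs$E_area + obs$E_volume +
    obs$E_bond + obs$E_excl
  expect_lt((max(Etot) - min(Etot)) / abs(mean(Etot)), 1e-4)
})

test_that("thermostat reaches the target temperature (membrane)", {
  m <- build_icosphere(2, icosphere_radius_for_edge(2))
  p <- model_params(omega = 0, dt = 1e-3)
  st <- sim_state(m)
  tr <- sim_run(st, p, duration = 15, sample_every = 0.05, seed = 9,
                flips = FALSE, record_frames = FALSE)
  obs <- tr$observables
  keep <- obs$t > 5
  Tkin <- mean(obs$E_kin[keep]) / (1.5 * m$n_vertices)
  expect_equal(Tkin, 1, tolerance = 0.05)
})

test_that("constraints hold area and volume near their targets", {
  m <- build_icosphere(2, icosphere_radius_for_edge(2))
  p <- model_params(omega = 0, f_p = 0)
  st <- sim_state(m)
  tr <- sim_run(st, p, duration = 10, sample_every = 0.05, seed = 3,
                flips = FALSE, record_frames = FALSE)
  obs <- tr$observables
  keep <- obs$t > 3
  expect_lt(mean(abs(obs$A[keep] / tr$A_0 - 1)), 0.01)
  expect_lt(mean(abs(obs$V[keep] / tr$V_0 - 1)), 0.01)
})

test_that("the volume ramp reaches its target reduced volume", {
  m <- build_icosphere(2, icosphere_radius_for_edge(2))
  p <- model_params(omega = 10, q = 0.3)
  st <- sim_state(m)
  tr <- sim_run(st, p, duration = 6, sample_every = 0.1, seed = 8,
                v_ramp = list(v_target = 0.7, ramp_time = 4),
                record_frames = FALSE)
  A0 <- tr$A_0
  V_target <- 0.7 * A0^1.5 / (6 * sqrt(pi))
  expect_equal(tr$V_0, V_target, tolerance = 1e-12)
  obs <- tr$observables
  expect_equal(tail(obs$V, 1), V_target, tolerance = 0.05)
  expect_lt(tail(obs$v, 1), 0.8)
})

test_that("flips run during dynamics and keep the mesh closed", {
  m <- build_icosphere(2, icosphere_radius_for_edge(2))
  p <- model_params(omega = 10, q = 0.3)
  st <- sim_state(m)
  tr <- sim_run(st, p, duration = 1, sample_every = 0.2, seed = 2)
  expect_gt(tr$flips_attempted, 0)
  m2 <- tr$state$mesh
  expect_s3_class(m2, "tri_mesh")   # constructor re-validates closure
  expect_identical(m2$n_edges, m$n_edges)
})

test_that("sim_step advances time by one dt", {
  m <- build_icosphere(1, icosphere_radius_for_edge(1))
  p <- model_params(omega = 0)
  st <- sim_state(m)
  st2 <- sim_step(st, p)
  expect_equal(st2$time, p$dt)
  expect_false(identical(st2$vel_vertices, st$vel_vertices))
})

test_that("filaments are advanced and stay coupled to the membrane", {
  set.seed(4)
  m <- build_icosphere(2, icosphere_radius_for_edge(2))
  p <- model_params(omega = 10)
  fil <- seed_filaments(2, 4, 1.0, icosphere_radius_for_edge(2), 1)
  st <- sim_state(m, fil)
  tr <- sim_run(st, p, duration = 1, sample_every = 0.5, seed = 13)
  X <- tr$state$filaments$positions
  expect_false(identical(X, fil$positions))
  # beads remain near or inside the (fluctuating) vesicle
  R <- icosphere_radius_for_edge(2)
  expect_true(all(sqrt(rowSums(X^2)) < 1.5 * R))
})
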