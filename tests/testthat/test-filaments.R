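test_that("a straight chain at rest length has zero energy and forces", {
  p <- model_params()
  X <- cbind(seq(0, 5) * p$r_0, 0, 0)
  fil <- filament_system(X, 1, 6)
  cb <- chain_bond(fil, p$k_fb, p$r_0)
  cf <- chain_bend(fil, p$kappa_f)
  expect_equal(cb$energy, 0)
  expect_equal(cf$energy, 0)
  expect_equal(max(abs(cb$forces)), 0)
  expect_equal(max(abs(cf$forces)), 0)
})

test_that("chain bond and bend forces match finite differences", {
  p <- model_params()
  set.seed(3)
  X <- cbind(seq(0, 5) * p$r_0, 0, 0) + matrix(rnorm(18, 0, 0.15), ncol = 3)
  fil <- filament_system(X, 1, 6)
  b <- chain_bond(fil, p$k_fb, p$r_0)
  gb <- num_grad(function(X)
    chain_bond(filament_system(X, 1, 6), p$k_fb, p$r_0)$energy, X)
  expect_lt(max(abs(b$forces + gb)) / max(abs(b$forces)), 1e-5)
  a <- chain_bend(fil, p$kappa_f)
  ga <- num_grad(function(X)
    chain_bend(filament_system(X, 1, 6), p$kappa_f)$energy, X)
  expect_lt(max(abs(a$forces + ga)) / max(abs(a$forces)), 1e-5)
})

test_that("propulsion is tangential with per-bead magnitude f_p", {
  p <- model_params()
  set.seed(3)
  X <- cbind(seq(0, 5) * p$r_0, 0, 0) + matrix(rnorm(18, 0, 0.1), ncol = 3)
  fil <- filament_system(X, 1, 6)
  f <- active_force(fil, p$f_p, "drive")
  expect_equal(sqrt(rowSums(f^2)), rep(p$f_p, 6), tolerance = 1e-12)
  t1 <- (X[2, ] - X[1, ]) / sqrt(sum((X[2, ] - X[1, ])^2))
  expect_equal(f[1, ], p$f_p * t1, tolerance = 1e-12)
  # tail bead: driven along its incoming bond, or free
  tN <- (X[6, ] - X[5, ]) / sqrt(sum((X[6, ] - X[5, ])^2))
  expect_equal(f[6, ], p$f_p * tN, tolerance = 1e-12)
  f0 <- active_force(fil, p$f_p, "free")
  expect_equal(f0[6, ], c(0, 0, 0))
  expect_equal(f0[1:5, ], f[1:5, ])
})

test_that("single beads are apolar: no thrust", {
  fil <- filament_system(matrix(0, 1, 3), 1, 1)
  expect_equal(max(abs(active_force(fil, 3.75, "drive"))), 0)
})

test_that("filament descriptors reproduce the study conditions", {
  p <- model_params()   # r_0 = 1.024, f_p = 3.75, kappa_f = 500, kappa = 20
  X <- cbind(seq(0, 5) * p$r_0, 0, 0)
  fil <- filament_system(X, 1, 6)
  fm <- filament_metrics(fil, p, R = 6.64)
  expect_equal(fm$L, 6.12, tolerance = 1e-12)
  expect_equal(fm$Pe, 3.75)
  expect_equal(fm$chi, 25)
  # ten hexamer chains in the default vesicle give phi ~ 2.56%
  fil10 <- filament_system(X[rep(1:6, 10), ], 10, 6)
  fm10 <- filament_metrics(fil10, p, R = 6.64)
  expect_equal(fm10$phi_percent, 100 * 60 * (1 / (2 * 6.64))^3,
               tolerance = 1e-12)
  expect_gt(fm10$phi_percent, 2.4)
  expect_lt(fm10$phi_percent, 2.7)
})

test_that("bond_length_for_L inverts the contour-length map", {
  for (L in c(2, 6.12, 10)) {
    r0 <- bond_length_for_L(L, 6)
    expect_equal((r0 * 5 + 1), L)
  }
})

test_that("seeded filaments are interior and non-overlapping", {
  set.seed(11)
  p <- model_params()
  R <- 6.64
  fil <- seed_filaments(10, 6, p$r_0, R, p$sigma)
  expect_identical(nrow(fil$positions), 60L)
  expect_true(all(sqrt(rowSums(fil$positions^2)) <= R - p$sigma + 1e-9))
  chain <- rep(1:10, each = 6)
  D <- as.matrix(dist(fil$positions))
  inter <- D[outer(chain, chain, "!=")]
  expect_true(all(inter >= p$sigma - 1e-9))
})

test_that("pairwise repulsion grid matches the brute-force oracle", {
  set.seed(5)
  A <- matrix(runif(90, -2, 2), ncol = 3)
  B <- matrix(runif(60, -2, 2), ncol = 3)
  r1 <- pairwise_repulsion(A, B, k = 200, range = 1, method = "grid")
  r2 <- pairwise_repulsion(A, B, k = 200, range = 1, method = "brute")
  expect_equal(r1$energy, r2$energy, tolerance = 1e-12)
  expect_equal(r1$forces_A, r2$forces_A, tolerance = 1e-12)
  expect_equal(r1$forces_B, r2$forces_B, tolerance = 1e-12)
  # same-set with group (chain) exclusion
  g <- rep(1:5, each = 6)
  s1 <- pairwise_repulsion(A, NULL, k = 200, range = 1, group = g,
                           method = "grid")
  s2 <- pairwise_repulsion(A, NULL, k = 200, range = 1, group = g,
                           method = "brute")
  expect_equal(s1$energy, s2$energy, tolerance = 1e-12)
  # excluding same-group pairs lowers the energy vs no exclusion
  s3 <- pairwise_repulsion(A, NULL, k = 200, range = 1, method = "brute")
  expect_gt(s3$energy, s1$energy)
})
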