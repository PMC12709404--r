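test_that("straight tubes and spheres have no junctions", {
  cc <- capped_cylinder_mesh(14, 1, h = 0.3)
  J <- count_junctions(cc)
  expect_identical(as.integer(J), 0L)
  expect_false(attr(J, "low_confidence"))
  m <- build_icosphere(3, 6)
  Jm <- count_junctions(m)
  expect_identical(as.integer(Jm), 0L)
})

test_that("Y and H tube fixtures give J = 1 and J = 2", {
  Y <- tube_network_mesh("Y", radius = 1, arm_length = 8, h = 0.35)
  H <- tube_network_mesh("H", radius = 1, arm_length = 8, h = 0.35)
  I <- tube_network_mesh("I", radius = 1, arm_length = 8, h = 0.35)
  expect_identical(as.integer(count_junctions(Y)), 1L)
  expect_identical(as.integer(count_junctions(H)), 2L)
  expect_identical(as.integer(count_junctions(I)), 0L)
})

test_that("junction counting is invariant under rigid motion and refinement", {
  H <- tube_network_mesh("H", radius = 1, arm_length = 8, h = 0.35)
  th <- 0.7
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  H2 <- H
  H2$positions <- H$positions %*% Rz +
    matrix(c(5, -3, 2), nrow(H$positions), 3, byrow = TRUE)
  expect_identical(as.integer(count_junctions(H2)), 2L)
  Yfine <- tube_network_mesh("Y", radius = 1, arm_length = 8, h = 0.22)
  expect_identical(as.integer(count_junctions(Yfine)), 1L)
})

test_that("turnover rates: constant series has zero rates", {
  out <- turnover_rates(rep(2L, 20), times = 10)
  expect_identical(out$r_e, 0)
  expect_identical(out$r_r, 0)
  expect_identical(out$r, 0)
})

test_that("turnover rates: 3 up and 2 down events over 10 s", {
  J <- c(0, 1, 1, 2, 2, 1, 1, 2, 2, 1, 1)
  out <- turnover_rates(J, times = seq(0, 10, length.out = 11))
  expect_equal(out$r_e, 0.3)
  expect_equal(out$r_r, 0.2)
  expect_equal(out$r, 0.5)
  expect_equal(out$r, out$r_e + out$r_r)
  expect_equal(out$emergence_fraction, 0.6)
})

test_that("the persistence window suppresses single-frame flicker", {
  J <- c(1, 1, 1, 2, 1, 1, 1, 1, 1, 1, 1)   # one-frame blip
  loose <- turnover_rates(J, times = 10, window = 1L)
  strict <- turnover_rates(J, times = 10, window = 2L)
  expect_gt(loose$r, 0)
  expect_identical(strict$r, 0)
})

test_that("junction attributes expose the skeleton", {
  Y <- tube_network_mesh("Y", radius = 1, arm_length = 8, h = 0.35)
  J <- count_junctions(Y)
  nodes <- attr(J, "nodes")
  deg <- attr(J, "degree")
  expect_identical(nrow(nodes), length(deg))
  expect_identical(sum(deg == 3), 1L)        # a single three-way node
  expect_identical(sum(deg == 1), 3L)        # three arm tips
})
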