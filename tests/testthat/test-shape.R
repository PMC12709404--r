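test_that("tube model closed forms behave at the sphere limit", {
  tm <- tube_model(0, 1)
  expect_equal(tm$v_T, 1, tolerance = 1e-12)
  expect_equal(tm$da_T, 1, tolerance = 1e-12)
  # long-tube limit: v -> 0 (like 1/sqrt(b)), da grows (like sqrt(b))
  expect_lt(tube_model(1e4)$v_T, 0.05)
  expect_gt(tube_model(1e4)$da_T, 5)
  sm <- sheet_model(0, 1)
  expect_equal(sm$v_S, 1, tolerance = 1e-12)
  expect_equal(sm$da_S, 1, tolerance = 1e-12)
})

test_that("reference asymmetry root-finding inverts the closed forms", {
  for (v in c(0.3, 0.5, 0.75)) {
    ref <- reference_asymmetries(v)
    expect_equal(tube_model(ref$b)$v_T, v, tolerance = 1e-8)
    expect_equal(sheet_model(ref$c)$v_S, v, tolerance = 1e-8)
    expect_equal(tube_model(ref$b)$da_T, ref$da_T, tolerance = 1e-10)
  }
})

test_that("meshed parametric surfaces match their closed forms", {
  cc <- capped_cylinder_mesh(10, 1, h = 0.15)
  tm <- tube_model(10, 1)
  expect_equal(reduced_volume(cc), tm$v_T, tolerance = 0.01)
  expect_equal(membrane_asymmetry(cc), tm$da_T, tolerance = 0.01)
  expect_equal(mesh_area(cc), tm$A_T, tolerance = 0.01)
  expect_equal(mesh_volume(cc), tm$V_T, tolerance = 0.01)
  sh <- toroidal_sheet_mesh(4, 1, h = 0.15)
  sm <- sheet_model(4, 1)
  expect_equal(reduced_volume(sh), sm$v_S, tolerance = 0.01)
  expect_equal(membrane_asymmetry(sh), sm$da_S, tolerance = 0.01)
})

test_that("shape index is ~1 on tube meshes and classification is sane", {
  cc <- capped_cylinder_mesh(10, 1, h = 0.2)
  expect_equal(shape_index(cc), 1, tolerance = 0.02)
  expect_identical(classify_shape(cc), "tube")
  sh <- toroidal_sheet_mesh(4, 1, h = 0.2)
  expect_identical(classify_shape(sh), "sheet")
})

test_that("classification bands order cup < sheet < sheet-tube < tube < compartmentalized", {
  v <- 0.4
  ref <- reference_asymmetries(v)
  labs <- classify_shape(c(0.8 * ref$da_S, ref$da_S,
                           (ref$da_S + ref$da_T) / 2, ref$da_T,
                           1.5 * ref$da_T), rep(v, 5))
  expect_identical(labs, c("cup", "sheet", "sheet-tube", "tube",
                           "compartmentalized"))
})

test_that("reference table is monotone in v with da_T above da_S", {
  rt <- reference_table(seq(0.25, 0.8, by = 0.05))
  expect_true(all(diff(rt$da_T) < 0))
  expect_true(all(diff(rt$da_S) < 0))
  expect_true(all(rt$da_T > rt$da_S))
})
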