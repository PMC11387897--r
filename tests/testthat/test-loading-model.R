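test_that("muscle force follows area times specific tension", {
  expect_equal(unname(muscle_force_from_area(muscle_spec(100))), 3150)
  expect_equal(unname(muscle_force_from_area(muscle_spec(1))), 31.5)
  split <- muscle_force_from_area(
    muscle_spec(10, group_fractions = c(a = 0.6, b = 0.4)))
  expect_equal(split, c(a = 189, b = 126))
  expect_error(muscle_spec(-5), "must be > 0")
  expect_error(muscle_spec(10, group_fractions = c(a = 0.5, b = 0.4)),
               "sum to 1")
})

test_that("even distribution over nodes conserves the total force", {
  d <- distribute_over_nodes(c(0, 0, -300), 1:10)
  expect_equal(d$fz, rep(-30, 10))
  expect_equal(colSums(d[, c("fx", "fy", "fz")]),
               c(fx = 0, fy = 0, fz = -300), tolerance = 1e-12)
  d1 <- distribute_over_nodes(c(0, 0, -300), 5L)
  expect_equal(d1$fz, -300)
  expect_error(distribute_over_nodes(c(1, 0, 0), integer(0)), "0 nodes")
})

test_that("surface-area equalization imposes the reference force/SA ratio", {
  pol <- scaling_policy("sa_equalized", reference_surface_area = 4000,
                        reference_forces = c(adductor = 800))
  expect_equal(scale_to_reference(c(adductor = 123), 4000, pol),
               c(adductor = 800))
  expect_equal(scale_to_reference(c(adductor = 123), 1000, pol),
               c(adductor = 200))
  pol_a <- scaling_policy("actual_size")
  expect_equal(scale_to_reference(c(adductor = 123), 999, pol_a),
               c(adductor = 123))
  expect_error(scaling_policy("sa_equalized"), "reference_surface_area")
})

test_that("built load cases carry the jaw-joint and bite topology", {
  model <- generate_proxy(proxy_params("cranium", resolution = 6))
  lc <- build_load_case(model, muscles = NULL,
                        bite = bite_config("load", 1200))
  expect_equal(nrow(lc$constraints), 18L)     # 6 joint nodes x 3 directions
  expect_setequal(unique(lc$constraints$node), model$mesh$node_sets$joint)
  expect_equal(nrow(lc$bite_loads), 10L)
  expect_equal(lc$bite_loads$fz, rep(-120, 10))
  expect_equal(sum(lc$bite_loads$fz), -1200, tolerance = 1e-12)
  # total applied force equals the sum over per-node loads exactly
  lc2 <- build_load_case(model, muscles = muscle_spec(25),
                         bite = bite_config("load", 1200))
  f <- skullfea:::load_vector(lc2, nrow(model$mesh$nodes))
  expect_equal(colSums(matrix(f, ncol = 3, byrow = TRUE)),
               skullfea:::total_applied_force(lc2), tolerance = 1e-12)
  # muscle magnitude: |sum of adductor load| = area x tension
  g <- lc2$muscle_loads$adductor
  expect_equal(sqrt(sum(colSums(g[, c("fx", "fy", "fz")])^2)),
               25 * 31.5, tolerance = 1e-9)
})

test_that("bite constrain mode pins bite nodes instead of loading them", {
  model <- generate_proxy(proxy_params("mandible", resolution = 6))
  lc <- build_load_case(model, muscles = muscle_spec(25),
                        bite = bite_config("constrain"))
  expect_equal(nrow(lc$constraints), 18L + 10L)
  expect_null(lc$bite_loads)
  field <- solve_fe(model$mesh, material_properties(), lc)
  # bite reaction appears at the bite nodes
  bite_r <- field$reactions[field$reactions$node %in%
                              model$mesh$node_sets$bite, ]
  expect_gt(sum(abs(bite_r$rz)), 0)
})

test_that("missing node sets are reported with the available names", {
  model <- generate_proxy(proxy_params("cranium", resolution = 6))
  model$mesh$node_sets$joint <- NULL
  expect_error(build_load_case(model, muscles = NULL),
               "no node set 'joint'.*available.*bite")
})

test_that("toward-point muscle directions are unit and sensible", {
  model <- generate_proxy(proxy_params("cranium", resolution = 6))
  lc <- muscle_only_case(model)
  g <- lc$muscle_loads$adductor
  tot <- colSums(g[, c("fx", "fy", "fz")])
  expect_equal(sqrt(sum(tot^2)), model$adductor_area * 31.5,
               tolerance = 1e-9)
  expect_lt(tot[3], 0)   # cranial adductors pull ventrally
  lm <- muscle_only_case(generate_proxy(proxy_params("mandible",
                                                     resolution = 6)))
  expect_gt(sum(lm$muscle_loads$adductor$fz), 0)  # mandible pulled dorsally
})

test_that("consistent traction loads sum to traction times area", {
  model <- box_proxy(10, 2, 2, 5, 2, 2)
  endn <- plane_nodes(model$mesh, 1, 10)
  tl <- traction_loads(model$mesh, endn, c(25, 0, 0))
  expect_equal(sum(tl$fx), 25 * 4, tolerance = 1e-12)
  expect_equal(sum(abs(tl$fy)) + sum(abs(tl$fz)), 0)
})

test_that("isometric proxies under sa-equalized loading stress identically", {
  small <- generate_proxy(proxy_params("cranium", resolution = 6))
  large <- isometric_copy(small, 2)
  mat <- material_properties()
  pol <- scaling_policy(
    "sa_equalized",
    reference_surface_area = large$summary$surface_area,
    reference_forces = muscle_force_from_area(
      muscle_spec(large$adductor_area)))
  f_small <- solve_fe(small$mesh, mat, muscle_only_case(small, pol))
  f_large <- solve_fe(large$mesh, mat, muscle_only_case(large, pol))
  # element-by-element identical von Mises: shape is all that differs
  expect_equal(f_small$von_mises, f_large$von_mises,
               tolerance = 1e-6)
})

test_that("actual-size stresses scale linearly with specific tension", {
  model <- generate_proxy(proxy_params("cranium", resolution = 6))
  mat <- material_properties()
  lc1 <- build_load_case(model, muscles = muscle_spec(25,
                                                      specific_tension = 31.5))
  lc2 <- build_load_case(model, muscles = muscle_spec(25,
                                                      specific_tension = 63))
  f1 <- solve_fe(model$mesh, mat, lc1)
  f2 <- solve_fe(model$mesh, mat, lc2)
  expect_equal(f2$von_mises, 2 * f1$von_mises, tolerance = 1e-9)
})
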