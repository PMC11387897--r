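# independent single-element oracle: builds the stiffness by interpolating
# each nodal basis displacement, taking symmetric-gradient strains and the
# Lame-form stress, and contracting energy densities - no B-matrix involved
element_stiffness_oracle <- function(coords, material) {
  E <- material$youngs_modulus
  nu <- material$poisson_ratio
  la <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  A <- cbind(1, coords)                    # N_i(x) = c_i + g_i . x
  C <- solve(A)                            # row 1: constants, rows 2:4: grads
  V <- abs(det(cbind(coords[2, ] - coords[1, ], coords[3, ] - coords[1, ],
                     coords[4, ] - coords[1, ]))) / 6
  basis_strain <- function(i, a) {
    gradN <- C[2:4, i]
    du <- matrix(0, 3, 3)
    du[a, ] <- gradN                       # grad of u = N_i e_a
    (du + t(du)) / 2
  }
  K <- matrix(0, 12, 12)
  for (i in 1:4) for (a in 1:3) for (j in 1:4) for (b in 1:3) {
    ei <- basis_strain(i, a)
    ej <- basis_strain(j, b)
    K[3 * (i - 1) + a, 3 * (j - 1) + b] <-
      V * (la * sum(diag(ei)) * sum(diag(ej)) + 2 * mu * sum(ei * ej))
  }
  K
}

test_that("element stiffness is symmetric with exactly six rigid-body modes", {
  set.seed(11)
  for (rep in 1:5) {
    coords <- unit_tet_coords() + matrix(rnorm(12, sd = 0.15), 4, 3)
    Ke <- element_stiffness(coords, material_properties())
    expect_lt(max(abs(Ke - t(Ke))), 1e-12 * max(abs(Ke)))
    ev <- eigen(Ke, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6L)
    expect_true(all(ev > -1e-8 * max(ev)))
    for (d in 1:3) {
      rigid <- rep(as.numeric(1:3 == d), 4)
      expect_lt(max(abs(Ke %*% rigid)), 1e-9 * max(abs(Ke)))
    }
  }
})

test_that("element stiffness matches the independent energy-form oracle", {
  mat1 <- material_properties(youngs_modulus = 1, poisson_ratio = 0)
  K <- element_stiffness(unit_tet_coords(), mat1)
  K_oracle <- element_stiffness_oracle(unit_tet_coords(), mat1)
  expect_equal(K, K_oracle, tolerance = 1e-10)
  # and with the bone material on a skewed element
  set.seed(3)
  coords <- unit_tet_coords() + matrix(rnorm(12, sd = 0.2), 4, 3)
  mat <- material_properties()
  expect_equal(element_stiffness(coords, mat),
               element_stiffness_oracle(coords, mat),
               tolerance = 1e-9)
})

test_that("vectorized assembly agrees with per-element stiffness", {
  model <- generate_proxy(proxy_params("cranium", resolution = 4,
                                       jitter = 0.1, seed = 5L))
  mesh <- model$mesh
  mat <- material_properties()
  K <- skullfea:::assemble_stiffness(mesh$nodes, mesh$tets, mat)
  Kd <- matrix(0, 3 * nrow(mesh$nodes), 3 * nrow(mesh$nodes))
  for (e in seq_len(nrow(mesh$tets))) {
    dofs <- as.vector(t(outer(3 * (mesh$tets[e, ] - 1), 1:3, `+`)))
    Kd[dofs, dofs] <- Kd[dofs, dofs] +
      element_stiffness(mesh$nodes[mesh$tets[e, ], ], mat)
  }
  expect_lt(max(abs(as.matrix(K) - Kd)), 1e-8 * max(abs(Kd)))
})

test_that("zero loads give an identically zero field", {
  model <- generate_proxy(proxy_params("mandible", resolution = 5))
  lc <- build_load_case(model, muscles = NULL, bite = bite_config("load", 0))
  f <- solve_fe(model$mesh, material_properties(), lc)
  expect_equal(max(abs(f$displacements)), 0)
  expect_equal(max(f$von_mises), 0)
  expect_equal(max(abs(f$element_stress)), 0)
})

test_that("uniaxial patch test recovers the exact constant stress state", {
  pc <- patch_case()
  field <- solve_fe(pc$model$mesh, material_properties(), pc$loads)
  expect_lt(max(abs(field$element_stress[, "xx"] - pc$sigma)) / pc$sigma,
            1e-8)
  expect_lt(max(abs(field$element_stress[, c("yy", "zz", "xy", "yz",
                                             "zx")])) / pc$sigma, 1e-8)
  expect_lt(max(abs(field$von_mises - pc$sigma)) / pc$sigma, 1e-8)
  # strain follows Hooke's law for uniaxial stress
  mat <- material_properties()
  expect_equal(unname(field$element_strain[1, "xx"]),
               pc$sigma / mat$youngs_modulus, tolerance = 1e-8)
  expect_equal(unname(field$element_strain[1, "yy"]),
               -mat$poisson_ratio * pc$sigma / mat$youngs_modulus,
               tolerance = 1e-8)
})

test_that("solution is linear and superposable in the applied loads", {
  model <- generate_proxy(proxy_params("cranium", resolution = 6))
  mat <- material_properties()
  lcA <- muscle_only_case(model)
  lcB <- build_load_case(model, muscles = NULL,
                         bite = bite_config("load", 500))
  fA <- solve_fe(model$mesh, mat, lcA)
  fB <- solve_fe(model$mesh, mat, lcB)
  # scaling: k times the loads scales every output by k
  k <- 3.7
  lcAk <- perturb_loads(lcA, k, "global")
  fAk <- solve_fe(model$mesh, mat, lcAk)
  expect_equal(fAk$displacements, k * fA$displacements, tolerance = 1e-9)
  expect_equal(fAk$element_stress, k * fA$element_stress, tolerance = 1e-9)
  expect_equal(fAk$von_mises, k * fA$von_mises, tolerance = 1e-9)
  # superposition of muscle and bite loading
  lcAB <- build_load_case(model, muscles = muscle_spec(model$adductor_area),
                          bite = bite_config("load", 500))
  fAB <- solve_fe(model$mesh, mat, lcAB)
  expect_equal(fAB$displacements, fA$displacements + fB$displacements,
               tolerance = 1e-8)
})

test_that("reactions balance the applied loads componentwise", {
  model <- generate_proxy(proxy_params("cranium", resolution = 6))
  lc <- build_load_case(model, muscles = muscle_spec(model$adductor_area),
                        bite = bite_config("load", 800))
  field <- solve_fe(model$mesh, material_properties(), lc)
  applied <- skullfea:::total_applied_force(lc)
  reacted <- colSums(field$reactions[, c("rx", "ry", "rz")])
  expect_lt(max(abs(applied + reacted)), 1e-6 * max(abs(applied)))
})

test_that("rigid rotation of mesh and loads leaves von Mises unchanged", {
  model <- generate_proxy(proxy_params("mandible", resolution = 5))
  mat <- material_properties()
  lc <- muscle_only_case(model)
  f0 <- solve_fe(model$mesh, mat, lc)
  R <- rotation_matrix(c(1, -1, 2), 0.9)
  mesh_r <- tet_mesh(model$mesh$nodes %*% t(R), model$mesh$tets,
                     node_sets = model$mesh$node_sets,
                     fix_orientation = FALSE)
  rot_loads <- function(df) {
    if (is.null(df)) return(NULL)
    df[, c("fx", "fy", "fz")] <-
      as.matrix(df[, c("fx", "fy", "fz")]) %*% t(R)
    df
  }
  lc_r <- load_case(lc$constraints, rot_loads(lc$bite_loads),
                    lapply(lc$muscle_loads, rot_loads))
  # constraints must rotate too: replace per-direction pins with full fixes
  # (the joint nodes are fully fixed already, so the constraint set is
  # rotation-closed)
  f1 <- solve_fe(mesh_r, mat, lc_r)
  expect_equal(f1$von_mises, f0$von_mises, tolerance = 1e-8)
  expect_equal(f1$displacements, f0$displacements %*% t(R),
               tolerance = 1e-8)
  expect_equal(f1$max_principal_strain, f0$max_principal_strain,
               tolerance = 1e-8)
})

test_that("insufficient constraints are reported, not silently solved", {
  model <- generate_proxy(proxy_params("cranium", resolution = 4))
  lc <- load_case(data.frame(node = 1L, dir = 1:3),
                  bite_loads = data.frame(node = 10L, fx = 0, fy = 0,
                                          fz = -10))
  expect_error(solve_fe(model$mesh, material_properties(), lc),
               "insufficient constraints|singular|unconstrained")
  expect_error(solve_fe(model$mesh, material_properties(),
                        load_case(data.frame(node = integer(0),
                                             dir = integer(0)))),
               "no constraints")
})

test_that("conjugate-gradient path reproduces the direct solution", {
  model <- generate_proxy(proxy_params("mandible", resolution = 5))
  mat <- material_properties()
  lc <- muscle_only_case(model)
  fd <- solve_fe(model$mesh, mat, lc, method = "direct")
  fc <- solve_fe(model$mesh, mat, lc, method = "cg", cg_tol = 1e-12)
  expect_equal(fc$displacements, fd$displacements, tolerance = 1e-7)
  expect_equal(fc$von_mises, fd$von_mises, tolerance = 1e-7)
})

test_that("von Mises invariants hold on canonical stress states", {
  expect_equal(von_mises_from_tensor(diag(c(10, 0, 0))), 10)
  expect_equal(von_mises_from_tensor(diag(c(7, 7, 7))), 0)
  shear <- matrix(0, 3, 3)
  shear[1, 2] <- shear[2, 1] <- 5
  expect_equal(von_mises_from_tensor(shear), 5 * sqrt(3))
  expect_equal(von_mises_from_tensor(c(10, 0, 0, 0, 0, 0)), 10)
  # rotation invariance on a random symmetric tensor
  set.seed(8)
  S <- crossprod(matrix(rnorm(9), 3, 3))
  R <- rotation_matrix(c(2, 1, -1), 1.1)
  expect_equal(von_mises_from_tensor(R %*% S %*% t(R)),
               von_mises_from_tensor(S), tolerance = 1e-12)
  expect_error(von_mises_from_tensor(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0),
                                            3, 3)), "symmetric")
})

test_that("principal strains sort eigenvalues and respect invariance", {
  expect_equal(principal_strains(diag(c(3, 2, 1) * 1e-4)),
               c(3, 2, 1) * 1e-4)
  expect_equal(principal_strains(matrix(0, 3, 3)), c(0, 0, 0))
  set.seed(9)
  S <- crossprod(matrix(rnorm(9), 3, 3)) * 1e-4
  R <- rotation_matrix(c(0, 1, 1), 0.6)
  expect_equal(principal_strains(R %*% S %*% t(R)), principal_strains(S),
               tolerance = 1e-12)
  # Voigt engineering-shear convention: gamma_xy = 2 eps_xy
  v <- c(1e-4, 2e-4, 3e-4, 4e-4, -2e-4, 1e-4)
  Sm <- matrix(c(v[1], v[4] / 2, v[6] / 2,
                 v[4] / 2, v[2], v[5] / 2,
                 v[6] / 2, v[5] / 2, v[3]), 3, 3)
  expect_equal(principal_strains(v), principal_strains(Sm))
})

test_that("vectorized principal-strain recovery matches eigen per element", {
  set.seed(21)
  V <- matrix(rnorm(60, sd = 1e-3), 10, 6)
  fast <- skullfea:::max_eig_sym_voigt(V, shear = "engineering")
  slow <- apply(V, 1, function(r) principal_strains(r)[1])
  expect_equal(fast, slow, tolerance = 1e-12)
})
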