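test_that("elasticity matrix has the closed-form isotropic structure", {
  D <- elasticity_matrix(material_model(0.7, 0.45))
  expect_equal(D[4, 4], 0.7 / 2.9, tolerance = 1e-12) # mu
  expect_true(isSymmetric(D))
  expect_true(all(eigen(D, symmetric = TRUE, only.values = TRUE)$values > 0))
  # nu = 0: no cross coupling, D11 = E
  D0 <- elasticity_matrix(material_model(1, 0))
  expect_equal(D0[1, 1], 1)
  expect_equal(D0[1, 2], 0)
  # uniaxial strain probe: sigma1/eps1 = lambda + 2 mu
  mat <- material_model(0.7, 0.3)
  lp <- aortafem:::lame_parameters(mat)
  probe <- as.vector(elasticity_matrix(mat) %*% c(1, 0, 0, 0, 0, 0))
  expect_equal(probe[1], lp$lambda + 2 * lp$mu, tolerance = 1e-12)
  expect_error(material_model(poisson_ratio = 0.5), "poisson")
  expect_error(material_model(young_modulus = -1), "young")
})

test_that("element stiffness matches the symbolic reference-tet oracle", {
  # unit reference tet at E = 1, nu = 0, computed once with exact rational
  # arithmetic (sympy) and frozen here; entries are integers / 12
  K12 <- matrix(c(
    4, 1, 1, -2, -1, -1, -1, 0, 0, -1, 0, 0,
    1, 4, 1, 0, -1, 0, -1, -2, -1, 0, -1, 0,
    1, 1, 4, 0, 0, -1, 0, 0, -1, -1, -1, -2,
    -2, 0, 0, 2, 0, 0, 0, 0, 0, 0, 0, 0,
    -1, -1, 0, 0, 1, 0, 1, 0, 0, 0, 0, 0,
    -1, 0, -1, 0, 0, 1, 0, 0, 0, 1, 0, 0,
    -1, -1, 0, 0, 1, 0, 1, 0, 0, 0, 0, 0,
    0, -2, 0, 0, 0, 0, 0, 2, 0, 0, 0, 0,
    0, -1, -1, 0, 0, 0, 0, 0, 1, 0, 1, 0,
    -1, 0, -1, 0, 0, 1, 0, 0, 0, 1, 0, 0,
    0, -1, -1, 0, 0, 0, 0, 0, 1, 0, 1, 0,
    0, 0, -2, 0, 0, 0, 0, 0, 0, 0, 0, 2), 12, 12, byrow = TRUE) / 12
  # nodes in mm; unit tet in metres; E = 1 MPa = 1e6 Pa scales K by 1e6
  tet <- rbind(c(0, 0, 0), c(1000, 0, 0), c(0, 1000, 0), c(0, 0, 1000))
  Ke <- element_stiffness(tet, material_model(1, 0))
  expect_equal(Ke, 1e6 * K12, tolerance = 1e-14)
})

test_that("element stiffness has exactly the six rigid-body zero modes", {
  tet <- rbind(c(0, 0, 0), c(3, 0.2, 0), c(0.5, 2, 0.1), c(0.2, 0.3, 2.5))
  Ke <- element_stiffness(tet, material_model(0.7, 0.45))
  expect_equal(Ke, t(Ke), tolerance = 1e-15)
  for (tr in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 2, -1))) {
    expect_lt(max(abs(Ke %*% rep(tr, 4))), max(abs(Ke)) * 1e-12)
  }
  ev <- eigen(Ke, symmetric = TRUE, only.values = TRUE)$values
  expect_identical(sum(abs(ev) < max(ev) * 1e-12), 6L)
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_error(element_stiffness(flat, material_model()), "degenerate|inverted")
})

test_that("assembly equals the dense scatter-add oracle and is permutation-similar", {
  mat <- material_model(0.7, 0.45)
  nodes <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2), c(2, 2, 2))
  tets <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  K <- as.matrix(assemble(wall_mesh(nodes, tets), mat))
  Kd <- matrix(0, 15, 15)
  for (e in 1:2) {
    ke <- element_stiffness(nodes[tets[e, ], ], mat)
    dofs <- as.vector(t(outer(3 * (tets[e, ] - 1), 1:3, `+`)))
    Kd[dofs, dofs] <- Kd[dofs, dofs] + ke
  }
  expect_equal(K, Kd, tolerance = 1e-12)
  for (tr in list(c(1, 0, 0), c(0, 0, 1))) {
    expect_lt(max(abs(K %*% rep(tr, 5))), max(abs(K)) * 1e-10)
  }
  # renumbering nodes permutes the matrix without changing the physics:
  # solve a constrained problem in both numberings and compare fields
  mesh <- small_wall_mesh(12, 8, 1)
  set.seed(3)
  perm <- sample(nrow(mesh$nodes))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  mesh2 <- wall_mesh(mesh$nodes[perm, , drop = FALSE],
                     matrix(inv[mesh$tets], ncol = 4),
                     inv[mesh$inlet_nodes], inv[mesh$outlet_nodes],
                     matrix(inv[mesh$lumen_faces], ncol = 3),
                     n_base = mesh$n_base)
  lc <- load_case(n_steps = 1)
  u1 <- solve_static(mesh, mat, lc)$displacements_mm[, , 1]
  u2 <- solve_static(mesh2, mat, lc)$displacements_mm[, , 1]
  expect_equal(u2[inv, ], u1, tolerance = 1e-9)
})

test_that("pressure loads satisfy closed-surface and projected-area checks", {
  sph <- uv_sphere(15, 17, 32)
  dummy <- wall_mesh(sph$vertices, matrix(1:4, 1, 4),
                     lumen_faces = sph$triangles[, c(1, 3, 2)])
  f <- pressure_loads(dummy, 1000)
  fm <- matrix(f, ncol = 3, byrow = TRUE)
  expect_lt(max(abs(colSums(fm))), sum(abs(fm)) * 1e-9)
  expect_identical(pressure_loads(dummy, 0), numeric(length(f)))
  expect_error(pressure_loads(wall_mesh(sph$vertices, matrix(1:4, 1, 4)), 10),
               "lumen")
  # open cylinder barrel: x-resultant over the x > 0 half equals p * 2rL
  r <- 12; L <- 60; p <- 2000
  cyl <- anatomy_spec(neck_radius = r, max_radius = r, total_length = L,
                      bulge_center = L / 2)
  surf <- generate_lumen_surface(cyl, 96, 48)
  dummy2 <- wall_mesh(surf$vertices, matrix(1:4, 1, 4),
                      lumen_faces = surf$triangles[, c(1, 3, 2)])
  f2 <- matrix(pressure_loads(dummy2, p), ncol = 3, byrow = TRUE)
  expect_lt(max(abs(colSums(f2))), sum(abs(f2)) * 1e-9) # net lateral zero
  half <- surf$vertices[, 1] > 0
  fx_half <- sum(f2[half, 1])
  expect_equal(fx_half, p * 2 * (r / 1e3) * (L / 1e3), tolerance = 0.01)
})

test_that("solve_static steps are proportional and in equilibrium", {
  mesh <- small_wall_mesh(24, 16, 2)
  mat <- material_model()
  lc <- load_case()
  sol <- solve_static(mesh, mat, lc)
  expect_equal(load_steps(lc), seq(50, 77, by = 3))
  u_fin <- sol$displacements_mm[, , 10]
  for (k in c(1, 4, 7)) {
    u_k <- sol$displacements_mm[, , k]
    expect_lt(max(abs(u_k - u_fin * sol$delta_p_mmhg[k] / sol$delta_p_mmhg[10])),
              1e-8 * max(abs(u_fin)))
  }
  # constrained nodes stay put
  cn <- c(mesh$inlet_nodes, mesh$outlet_nodes)
  expect_identical(max(abs(sol$displacements_mm[cn, , ])), 0)
  # global equilibrium at the final step
  f <- pressure_loads(mesh, convert_pressure(sol$delta_p_mmhg[10], "mmHg", "Pa"))
  R <- numeric(length(f)); R[sol$fixed_dofs] <- sol$reactions[, 10]
  net <- colSums(matrix(f + R, ncol = 3, byrow = TRUE))
  expect_lt(max(abs(net)), 1e-8 * sum(abs(f)))
  # untagged mesh cannot be solved
  untagged <- extrude_wall(generate_lumen_surface(small_spec(), 16, 12), 2, 1)
  expect_error(solve_static(untagged, mat, lc), "inlet/outlet")
})

test_that("mmHg conversion is the fixed 133.322 Pa factor", {
  expect_equal(convert_pressure(77, "mmHg", "Pa"), 10265.794)
  expect_equal(convert_pressure(10265.794, "Pa", "kPa"), 10.265794)
})
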