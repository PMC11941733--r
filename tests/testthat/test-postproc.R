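test_that("strain kinematics are exact for affine fields, null for rigid motion", {
  tet <- rbind(c(0, 0, 0), c(3, 0.2, 0), c(0.5, 2, 0.1), c(0.2, 0.3, 2.5))
  # uniaxial stretch u = (alpha x, 0, 0)
  alpha <- 1e-3
  u <- cbind(alpha * tet[, 1], 0, 0)
  eps <- strain_from_displacement(tet, u)
  expect_equal(eps, diag(c(alpha, 0, 0)), tolerance = 1e-14)
  # small rigid rotation about z: strain vanishes to first order
  th <- 1e-6
  u_rot <- cbind(-th * tet[, 2], th * tet[, 1], 0)
  expect_lt(max(abs(strain_from_displacement(tet, u_rot))), th^2)
  # random affine field matches a central finite-difference oracle
  set.seed(4)
  A <- matrix(rnorm(9, sd = 1e-3), 3, 3)
  u_aff <- tet %*% t(A)
  eps_fd <- matrix(0, 3, 3)
  h <- 1e-4
  for (i in 1:3) for (j in 1:3) {
    # FD on the (globally affine) displacement component i along axis j;
    # units: u in mm, coordinates in mm -> dimensionless gradient
    dplus <- (A %*% (tet[1, ] + h * diag(3)[j, ]))[i]
    dminus <- (A %*% (tet[1, ] - h * diag(3)[j, ]))[i]
    eps_fd[i, j] <- (dplus - dminus) / (2 * h)
  }
  eps_fd <- (eps_fd + t(eps_fd)) / 2
  expect_equal(strain_from_displacement(tet, u_aff), eps_fd, tolerance = 1e-8)
})

test_that("von Mises stress invariants", {
  expect_equal(von_mises(c(5, 0, 0, 0, 0, 0)), 5)
  expect_equal(von_mises(c(3, 3, 3, 0, 0, 0)), 0)
  expect_equal(von_mises(c(0, 0, 0, 2, 0, 0)), sqrt(3) * 2)
  # matrix form consistent with vector form
  m <- rbind(c(5, 0, 0, 0, 0, 0), c(0, 0, 0, 2, 0, 0))
  expect_equal(von_mises(m), c(5, sqrt(3) * 2))
})

test_that("equivalent strain is the normalised deviatoric invariant", {
  expect_equal(equivalent_strain(c(0.1, 0.1, 0.1, 0, 0, 0)), 0)
  e <- 0.02
  expect_equal(equivalent_strain(c(e, -e / 2, -e / 2, 0, 0, 0)), e)
  # random symmetric tensor: principal-strain (eigenvalue) oracle
  set.seed(8)
  for (rep in 1:5) {
    v <- rnorm(6, sd = 0.05)
    M <- matrix(c(v[1], v[4], v[6],
                  v[4], v[2], v[5],
                  v[6], v[5], v[3]), 3, 3)
    lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    dev <- lam - mean(lam)
    expect_equal(equivalent_strain(v), sqrt(2 / 3 * sum(dev^2)),
                 tolerance = 1e-12)
  }
})

test_that("fields scale linearly with pressure and survive renumbering", {
  mesh <- small_wall_mesh(16, 12, 1)
  mat <- material_model()
  lc1 <- load_case(delta_p_first = 20, delta_p_final = 77, n_steps = 2)
  sol <- solve_static(mesh, mat, lc1)
  r_low <- field_result(mesh, mat, sol, step = 1)
  r_fin <- field_result(mesh, mat, sol, step = 2)
  c_ <- 77 / 20
  expect_equal(r_fin$max_von_mises, c_ * r_low$max_von_mises, tolerance = 1e-9)
  expect_equal(r_fin$max_equivalent_strain, c_ * r_low$max_equivalent_strain,
               tolerance = 1e-9)
  expect_equal(r_fin$max_displacement, c_ * r_low$max_displacement,
               tolerance = 1e-9)
  # maxima equal the field extrema
  expect_equal(r_fin$max_von_mises, max(von_mises(r_fin$element_stress)))
  expect_gte(min(von_mises(r_fin$element_stress)), 0)
  # node renumbering leaves the maxima untouched
  set.seed(5)
  perm <- sample(nrow(mesh$nodes))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  mesh2 <- wall_mesh(mesh$nodes[perm, , drop = FALSE],
                     matrix(inv[mesh$tets], ncol = 4),
                     inv[mesh$inlet_nodes], inv[mesh$outlet_nodes],
                     matrix(inv[mesh$lumen_faces], ncol = 3),
                     n_base = mesh$n_base)
  sol2 <- solve_static(mesh2, mat, lc1)
  r2 <- field_result(mesh2, mat, sol2, step = 2)
  expect_equal(r2$max_von_mises, r_fin$max_von_mises, tolerance = 1e-9)
  expect_equal(r2$max_displacement, r_fin$max_displacement, tolerance = 1e-9)
})

test_that("case summaries follow the Dsys = Ddias + max displacement convention", {
  fake <- structure(list(max_von_mises = 0.35, max_equivalent_strain = 0.5,
                         max_displacement = 18, node_displacement = NULL),
                    class = "field_result")
  rec <- case_summary(fake, 68, "T1-P9")
  expect_equal(rec$systolic_diameter, 86)
  rec2 <- case_summary(structure(list(max_von_mises = 0.55,
                                      max_equivalent_strain = 0.7,
                                      max_displacement = 35,
                                      node_displacement = NULL),
                                 class = "field_result"), 48, "T1-P10")
  expect_equal(rec2$systolic_diameter, 83)
  fake0 <- structure(list(max_von_mises = 0, max_equivalent_strain = 0,
                          max_displacement = 0, node_displacement = NULL),
                     class = "field_result")
  expect_equal(case_summary(fake0, 50)$systolic_diameter, 50)
  df <- as.data.frame(rec)
  expect_identical(df$case_id, "T1-P9")
  expect_identical(df$systolic_diameter_mm, 86)
})
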