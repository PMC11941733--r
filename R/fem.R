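#' Isotropic linear elastic material
#'
#' Default parameters are the conventional aortic-wall values used for rapid
#' linear AAA wall-stress screening: Young's modulus 0.7 MPa, Poisson ratio
#' 0.45 (nearly incompressible soft tissue), density 1095 kg/m^3 (carried for
#' completeness; unused in statics).
#'
#' @param young_modulus Young's modulus, MPa (> 0).
#' @param poisson_ratio Poisson ratio in (-1, 0.5).
#' @param density kg/m^3.
#' @return an object of class `material_model`.
#' @export
material_model <- function(young_modulus = 0.7, poisson_ratio = 0.45,
                           density = 1095) {
  if (!(young_modulus > 0)) stop("young_modulus must be > 0")
  if (poisson_ratio <= -1 || poisson_ratio >= 0.5)
    stop("poisson_ratio must lie in (-1, 0.5); the incompressible limit is unsupported")
  structure(list(young_modulus = young_modulus, poisson_ratio = poisson_ratio,
                 density = density),
            class = "material_model")
}

# Lame parameters in the units of E
lame_parameters <- function(material) {
  E <- material$young_modulus; nu <- material$poisson_ratio
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))
}

#' Incremental pressure load case
#'
#' Pulse-pressure loading between a low pressure pair (systolic/diastolic
#' 130/80 mmHg) and a high pair (230/123 mmHg). The load is ramped over
#' `n_steps` increments from `delta_p_first` (50 mmHg) to `delta_p_final`
#' (77 mmHg): step k applies
#' `delta_p_first + (k-1)/(n_steps-1) * (delta_p_final - delta_p_first)`.
#' Note the final increment is the *stated* 77 mmHg convention of the
#' reference workflow (230 - 123 would be 107); it is exposed here precisely
#' so users can override it.
#'
#' @param p_dias_low,p_sys_low low diastolic/systolic pressures, mmHg.
#' @param p_dias_high,p_sys_high high diastolic/systolic pressures, mmHg.
#' @param delta_p_first,delta_p_final first/final pressure increments, mmHg.
#' @param n_steps number of incremental steps (>= 1).
#' @return an object of class `load_case`.
#' @export
load_case <- function(p_dias_low = 80, p_sys_low = 130,
                      p_dias_high = 123, p_sys_high = 230,
                      delta_p_first = 50, delta_p_final = 77, n_steps = 10) {
  if (!(delta_p_first < delta_p_final)) stop("need delta_p_first < delta_p_final")
  if (n_steps < 1) stop("n_steps must be >= 1")
  structure(list(p_dias_low = p_dias_low, p_sys_low = p_sys_low,
                 p_dias_high = p_dias_high, p_sys_high = p_sys_high,
                 delta_p_first = delta_p_first, delta_p_final = delta_p_final,
                 n_steps = as.integer(n_steps)),
            class = "load_case")
}

#' Pressure increments of a load case (mmHg)
#' @param load a [load_case()].
#' @export
load_steps <- function(load) {
  k <- seq_len(load$n_steps)
  if (load$n_steps == 1) return(load$delta_p_final)
  load$delta_p_first + (k - 1) / (load$n_steps - 1) *
    (load$delta_p_final - load$delta_p_first)
}

#' 6x6 isotropic elasticity matrix (Voigt notation)
#'
#' Rows/columns ordered (xx, yy, zz, xy, yz, zx) with engineering shear
#' strains; entries in the units of `young_modulus` (MPa).
#'
#' @param material a [material_model()].
#' @return symmetric positive-definite 6x6 matrix.
#' @export
elasticity_matrix <- function(material) {
  lp <- lame_parameters(material)
  D <- diag(c(rep(2 * lp$mu, 3), rep(lp$mu, 3)))
  D[1:3, 1:3] <- D[1:3, 1:3] + lp$lambda
  D
}

# per-element shape-function gradients (1/m) and volumes (m^3);
# nodes in mm are converted to m here, at the FEM boundary
element_gradients <- function(mesh) {
  n <- mesh$nodes * 1e-3
  t <- mesh$tets
  p0 <- n[t[, 1], , drop = FALSE]
  a <- n[t[, 2], , drop = FALSE] - p0
  b <- n[t[, 3], , drop = FALSE] - p0
  c <- n[t[, 4], , drop = FALSE] - p0
  det <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
    a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
    a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  if (any(det <= 0)) stop("inverted or degenerate tetrahedron")
  # rows of inv(M) where M = [a; b; c] (rows): grad of N2, N3, N4
  inv <- array(0, c(nrow(t), 3, 3))
  inv[, 1, 1] <- (b[, 2] * c[, 3] - b[, 3] * c[, 2]) / det
  inv[, 1, 2] <- (a[, 3] * c[, 2] - a[, 2] * c[, 3]) / det
  inv[, 1, 3] <- (a[, 2] * b[, 3] - a[, 3] * b[, 2]) / det
  inv[, 2, 1] <- (b[, 3] * c[, 1] - b[, 1] * c[, 3]) / det
  inv[, 2, 2] <- (a[, 1] * c[, 3] - a[, 3] * c[, 1]) / det
  inv[, 2, 3] <- (a[, 3] * b[, 1] - a[, 1] * b[, 3]) / det
  inv[, 3, 1] <- (b[, 1] * c[, 2] - b[, 2] * c[, 1]) / det
  inv[, 3, 2] <- (a[, 2] * c[, 1] - a[, 1] * c[, 2]) / det
  inv[, 3, 3] <- (a[, 1] * b[, 2] - a[, 2] * b[, 1]) / det
  # grads g[,a,dim]: a = node 1..4
  g <- array(0, c(nrow(t), 4, 3))
  g[, 2, ] <- inv[, , 1]
  g[, 3, ] <- inv[, , 2]
  g[, 4, ] <- inv[, , 3]
  g[, 1, ] <- -(g[, 2, ] + g[, 3, ] + g[, 4, ])
  list(grads = g, volumes = det / 6)
}

#' Element stiffness matrix of a linear (constant-strain) tetrahedron
#'
#' `K_e = V B^T D B`, evaluated through the closed-form block expression
#' `K[3a+i, 3b+j] = V (lambda g_a_i g_b_j + mu g_a_j g_b_i +
#'  mu delta_ij g_a . g_b)`. Symmetric, with exactly 6 zero eigenvalues
#' (rigid-body modes).
#'
#' @param tet_nodes 4 x 3 matrix of node coordinates, mm.
#' @param material a [material_model()].
#' @return 12 x 12 stiffness matrix, N/m (displacements in m).
#' @export
element_stiffness <- function(tet_nodes, material) {
  mesh <- wall_mesh(tet_nodes, matrix(1:4, 1, 4))
  eg <- element_gradients(mesh)
  lp <- lame_parameters(material)
  lam <- lp$lambda * 1e6; mu <- lp$mu * 1e6 # MPa -> Pa
  g <- eg$grads[1, , ] # 4 x 3
  V <- eg$volumes[1]
  K <- matrix(0, 12, 12)
  for (a in 1:4) for (b in 1:4) {
    blk <- lam * tcrossprod(g[a, ], g[b, ]) + mu * tcrossprod(g[b, ], g[a, ]) +
      mu * sum(g[a, ] * g[b, ]) * diag(3)
    K[(3 * a - 2):(3 * a), (3 * b - 2):(3 * b)] <- V * blk
  }
  K
}

#' Assemble the global sparse stiffness matrix
#'
#' Scatter-add of constant-strain-tet element matrices into a symmetric
#' sparse matrix over the 3n displacement DOFs (node-major x, y, z; SI).
#'
#' @param mesh a [wall_mesh()].
#' @param material a [material_model()].
#' @return a symmetric `Matrix::dgCMatrix` of size 3n x 3n (N/m).
#' @export
assemble <- function(mesh, material) {
  eg <- element_gradients(mesh)
  lp <- lame_parameters(material)
  lam <- lp$lambda * 1e6; mu <- lp$mu * 1e6
  g <- eg$grads; V <- eg$volumes
  nel <- nrow(mesh$tets)
  nn <- nrow(mesh$nodes)
  iL <- vector("list", 144); jL <- iL; xL <- iL
  m <- 0
  for (a in 1:4) for (b in 1:4) {
    dot_ab <- g[, a, 1] * g[, b, 1] + g[, a, 2] * g[, b, 2] + g[, a, 3] * g[, b, 3]
    for (i in 1:3) for (j in 1:3) {
      m <- m + 1
      val <- lam * g[, a, i] * g[, b, j] + mu * g[, a, j] * g[, b, i]
      if (i == j) val <- val + mu * dot_ab
      iL[[m]] <- 3 * (mesh$tets[, a] - 1) + i
      jL[[m]] <- 3 * (mesh$tets[, b] - 1) + j
      xL[[m]] <- V * val
    }
  }
  Matrix::sparseMatrix(i = unlist(iL), j = unlist(jL), x = unlist(xL),
                       dims = c(3 * nn, 3 * nn))
}

#' Nodal force vector from lumen pressure (dead load)
#'
#' Each lumen triangle contributes `p * A / 3` to each of its three nodes,
#' directed from the lumen into the wall (i.e. against the stored lumen-face
#' normals, which point out of the solid). Normals are evaluated on the
#' reference configuration, consistent with the small-deformation assumption.
#'
#' @param mesh a [wall_mesh()] with tagged `lumen_faces`.
#' @param pressure lumen pressure, Pa.
#' @return force vector of length 3n, Newtons.
#' @export
pressure_loads <- function(mesh, pressure) {
  if (nrow(mesh$lumen_faces) == 0) stop("lumen faces not tagged")
  lum <- surface_mesh(mesh$nodes * 1e-3, mesh$lumen_faces)
  tn <- triangle_normals(lum)
  f <- numeric(3 * nrow(mesh$nodes))
  if (pressure == 0) return(f)
  # load along -n (n points into the lumen): pushes the wall outward
  contrib <- -pressure * tn$areas / 3
  for (c in 1:3) {
    nd <- mesh$lumen_faces[, c]
    for (dim in 1:3) {
      acc <- rowsum(contrib * tn$normals[, dim], nd, reorder = FALSE)
      ids <- 3 * (as.integer(rownames(acc)) - 1) + dim
      f[ids] <- f[ids] + acc
    }
  }
  f
}

#' Solve a linear elastostatic problem with prescribed-zero DOFs
#'
#' Reduces the system to the free DOFs, factorises once (sparse Cholesky)
#' and solves for one or more right-hand sides; reports reactions on the
#' constrained DOFs.
#'
#' @param mesh a [wall_mesh()].
#' @param material a [material_model()].
#' @param forces numeric vector (3n) or matrix (3n x n_rhs), Newtons.
#' @param fixed_dofs integer vector of constrained DOF ids (zero value).
#' @return list with `u` (3n x n_rhs displacements, m) and `reactions`
#'   (length(fixed_dofs) x n_rhs, N).
#' @export
fem_solve <- function(mesh, material, forces, fixed_dofs) {
  K <- assemble(mesh, material)
  ndof <- nrow(K)
  forces <- as.matrix(forces)
  if (length(fixed_dofs) == 0) stop("no constraints: singular system")
  free <- setdiff(seq_len(ndof), fixed_dofs)
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  ch <- tryCatch(Matrix::Cholesky(Kff, LDL = FALSE, perm = TRUE),
                 error = function(e) stop("stiffness factorization failed: ",
                                          conditionMessage(e)))
  uf <- as.matrix(Matrix::solve(ch, forces[free, , drop = FALSE]))
  u <- matrix(0, ndof, ncol(forces))
  u[free, ] <- uf
  reactions <- as.matrix(K[fixed_dofs, , drop = FALSE] %*% u) -
    forces[fixed_dofs, , drop = FALSE]
  list(u = u, reactions = reactions, fixed_dofs = fixed_dofs)
}

# dof helper: all 3 components of the given nodes
node_dofs <- function(nodes) {
  as.integer(t(outer(3 * (as.integer(nodes) - 1), 1:3, `+`)))
}

#' Static incremental solution under lumen pressure
#'
#' Applies the pressure increments of the load case with all three
#' displacement components fixed to zero on the inlet and outlet node sets.
#' The model is linear, so the stepping is realised as one factorisation
#' with one scaled right-hand side per increment; each step is therefore an
#' exact proportional rescaling — retained to mirror incremental workflows
#' and keep the interface ready for nonlinear extension.
#'
#' @param mesh a tagged [wall_mesh()].
#' @param material a [material_model()].
#' @param load a [load_case()].
#' @return an object of class `fem_solution`: `displacements_mm` (n x 3 x
#'   n_steps), `reactions` (N, per step), `delta_p_mmhg`, `fixed_dofs`.
#' @export
solve_static <- function(mesh, material, load = load_case()) {
  if (length(mesh$inlet_nodes) == 0 || length(mesh$outlet_nodes) == 0)
    stop("inlet/outlet node sets empty: tag boundaries first")
  dp <- load_steps(load)
  f1 <- pressure_loads(mesh, 1) # unit pressure (1 Pa)
  forces <- outer(f1, convert_pressure(dp, "mmHg", "Pa"))
  fixed <- node_dofs(c(mesh$inlet_nodes, mesh$outlet_nodes))
  sol <- fem_solve(mesh, material, forces, fixed)
  nn <- nrow(mesh$nodes)
  disp <- array(0, c(nn, 3, length(dp)))
  for (k in seq_along(dp)) {
    disp[, , k] <- matrix(sol$u[, k], nn, 3, byrow = TRUE) * 1e3 # m -> mm
  }
  structure(list(displacements_mm = disp, reactions = sol$reactions,
                 delta_p_mmhg = dp, fixed_dofs = fixed),
            class = "fem_solution")
}

#' @export
print.fem_solution <- function(x, ...) {
  n <- dim(x$displacements_mm)
  umax <- max(sqrt(rowSums(x$displacements_mm[, , n[3]]^2)))
  cat(sprintf(
    "fem_solution: %d nodes, %d steps (dP %.0f..%.0f mmHg), final max |u| = %.3f mm\n",
    n[1], n[3], x$delta_p_mmhg[1], x$delta_p_mmhg[n[3]], umax))
  invisible(x)
}
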