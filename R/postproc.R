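#' Small-strain tensor of one tetrahedron
#'
#' Constant per element: `eps = (grad u + grad u^T) / 2` from the linear
#' shape functions.
#'
#' @param tet_nodes 4 x 3 node coordinates, mm.
#' @param u 4 x 3 nodal displacements, mm.
#' @return 3 x 3 symmetric strain tensor (dimensionless).
#' @export
strain_from_displacement <- function(tet_nodes, u) {
  mesh <- wall_mesh(tet_nodes, matrix(1:4, 1, 4))
  eg <- element_gradients(mesh)
  g <- eg$grads[1, , ] # 4 x 3, 1/m
  gradu <- crossprod(u * 1e-3, g) # sum_a u_a outer g_a -> (3 x 3): du_i/dx_j
  (gradu + t(gradu)) / 2
}

# per-element strain (tensor components, Voigt xx,yy,zz,xy,yz,zx with TENSOR
# shears) for all elements; u_mm is n x 3
element_strains <- function(mesh, u_mm) {
  eg <- element_gradients(mesh)
  g <- eg$grads
  t_ <- mesh$tets
  u <- u_mm * 1e-3
  comp <- function(i, j) {
    s <- 0
    for (a in 1:4) {
      ua_i <- u[t_[, a], i]; ua_j <- u[t_[, a], j]
      s <- s + 0.5 * (ua_i * g[, a, j] + ua_j * g[, a, i])
    }
    s
  }
  cbind(xx = comp(1, 1), yy = comp(2, 2), zz = comp(3, 3),
        xy = comp(1, 2), yz = comp(2, 3), zx = comp(3, 1))
}

# stress (same Voigt layout, MPa) from tensor strains
element_stresses <- function(strains, material) {
  lp <- lame_parameters(material) # MPa
  tr <- strains[, 1] + strains[, 2] + strains[, 3]
  cbind(xx = lp$lambda * tr + 2 * lp$mu * strains[, 1],
        yy = lp$lambda * tr + 2 * lp$mu * strains[, 2],
        zz = lp$lambda * tr + 2 * lp$mu * strains[, 3],
        xy = 2 * lp$mu * strains[, 4],
        yz = 2 * lp$mu * strains[, 5],
        zx = 2 * lp$mu * strains[, 6])
}

#' von Mises equivalent stress
#'
#' \deqn{\sigma_{vm} = \sqrt{\tfrac12[(\sigma_{11}-\sigma_{22})^2 +
#' (\sigma_{22}-\sigma_{33})^2 + (\sigma_{33}-\sigma_{11})^2] +
#' 3(\sigma_{12}^2+\sigma_{23}^2+\sigma_{31}^2)}}
#'
#' @param stress numeric vector of length 6 (xx, yy, zz, xy, yz, zx, tensor
#'   components) or a matrix with one such row per element.
#' @return scalar(s) in the units of the input.
#' @export
von_mises <- function(stress) {
  s <- if (is.matrix(stress)) stress else matrix(stress, 1)
  out <- sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                       (s[, 3] - s[, 1])^2) +
                3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
  if (is.matrix(stress)) out else out[1]
}

#' Equivalent (von Mises) strain
#'
#' Deviatoric scalar invariant `sqrt(2/3 * eps_dev : eps_dev)`, normalised so
#' a uniaxial deviatoric probe `diag(e, -e/2, -e/2)` returns `e`. The
#' reporting convention multiplies by 100 when quoting percentages.
#'
#' @param strain numeric vector of length 6 (xx, yy, zz, xy, yz, zx, tensor
#'   shears) or a matrix with one row per element.
#' @return dimensionless scalar(s).
#' @export
equivalent_strain <- function(strain) {
  s <- if (is.matrix(strain)) strain else matrix(strain, 1)
  tr3 <- (s[, 1] + s[, 2] + s[, 3]) / 3
  d1 <- s[, 1] - tr3; d2 <- s[, 2] - tr3; d3 <- s[, 3] - tr3
  dd <- d1^2 + d2^2 + d3^2 + 2 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2)
  out <- sqrt(2 / 3 * dd)
  if (is.matrix(strain)) out else out[1]
}

#' Derived stress/strain/displacement fields and their maxima
#'
#' Evaluates the element-constant strain and stress fields at a given load
#' step and records the field maxima that summarise a case: maximum von
#' Mises stress (MPa), maximum equivalent strain (reported as a fraction),
#' and maximum nodal displacement magnitude (mm). Maxima are taken on raw
#' element values (no nodal averaging) to avoid smoothing bias.
#'
#' @param mesh a [wall_mesh()].
#' @param material a [material_model()].
#' @param solution a `fem_solution` from [solve_static()].
#' @param step load step index (default: final).
#' @return an object of class `field_result`.
#' @export
field_result <- function(mesh, material, solution, step = NULL) {
  ns <- dim(solution$displacements_mm)[3]
  if (is.null(step)) step <- ns
  stopifnot(step >= 1, step <= ns)
  u <- solution$displacements_mm[, , step]
  eps <- element_strains(mesh, u)
  sig <- element_stresses(eps, material)
  vm <- von_mises(sig)
  eq <- equivalent_strain(eps)
  structure(list(
    element_stress = sig, element_strain = eps, node_displacement = u,
    max_von_mises = max(vm), max_equivalent_strain = max(eq),
    max_displacement = max(sqrt(rowSums(u^2))),
    step = step, delta_p_mmhg = solution$delta_p_mmhg[step]
  ), class = "field_result")
}

#' @export
print.field_result <- function(x, ...) {
  cat(sprintf(
    "field_result (dP = %.1f mmHg): max von Mises %.4f MPa, max eq. strain %.1f%%, max |u| %.2f mm\n",
    x$delta_p_mmhg, x$max_von_mises, 100 * x$max_equivalent_strain,
    x$max_displacement))
  invisible(x)
}

#' Per-case summary record
#'
#' The systolic diameter follows the dominant bookkeeping convention of the
#' reference cohort, `Dsys = Ddias + max displacement`; a cross-section-based
#' alternative (maximum diameter of the deformed lumen surface) is reported
#' side by side when the mesh and solution are supplied, since the two
#' conventions disagree for strongly asymmetric bulges.
#'
#' @param result a [field_result()].
#' @param diagnostic_diameter mm.
#' @param case_id identifier string.
#' @param mesh optional [wall_mesh()] for the sectional measurement.
#' @return an object of class `case_record` (also a one-row data.frame shape
#'   via [as.data.frame.case_record()]).
#' @export
case_summary <- function(result, diagnostic_diameter, case_id = "case",
                         mesh = NULL) {
  dsys <- diagnostic_diameter + result$max_displacement
  dsys_section <- NA_real_
  if (!is.null(mesh) && nrow(mesh$lumen_faces) > 0) {
    base <- sort(unique(as.vector(mesh$lumen_faces)))
    deformed <- mesh$nodes[base, , drop = FALSE] +
      result$node_displacement[base, , drop = FALSE]
    dsys_section <- measure_max_diameter(
      surface_mesh(deformed, matrix(1:3, 1, 3)))
  }
  structure(list(case_id = case_id,
                 diagnostic_diameter = diagnostic_diameter,
                 max_von_mises = result$max_von_mises,
                 max_equivalent_strain = result$max_equivalent_strain,
                 max_displacement = result$max_displacement,
                 systolic_diameter = dsys,
                 systolic_diameter_section = dsys_section),
            class = "case_record")
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf(
    "%s: Ddias %.1f mm | max vM %.3f MPa | max eq. strain %.1f%% | max |u| %.2f mm | Dsys %.1f mm\n",
    x$case_id, x$diagnostic_diameter, x$max_von_mises,
    100 * x$max_equivalent_strain, x$max_displacement, x$systolic_diameter))
  invisible(x)
}

#' @export
as.data.frame.case_record <- function(x, ...) {
  data.frame(case_id = x$case_id,
             diagnostic_diameter_mm = x$diagnostic_diameter,
             max_von_mises_mpa = x$max_von_mises,
             max_equivalent_strain = x$max_equivalent_strain,
             max_displacement_mm = x$max_displacement,
             systolic_diameter_mm = x$systolic_diameter,
             systolic_diameter_section_mm = x$systolic_diameter_section,
             stringsAsFactors = FALSE)
}
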