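# Shared fixtures, all generated in code at test time.

# UV (latitude/longitude) sphere with outward-oriented triangles
uv_sphere <- function(radius = 15, n_lat = 32, n_lon = 64) {
  lat <- seq(0, pi, length.out = n_lat)
  lon <- 2 * pi * (seq_len(n_lon) - 1) / n_lon
  # interior rings only; poles added as single vertices
  rings <- lat[-c(1, n_lat)]
  verts <- do.call(rbind, lapply(rings, function(th) {
    cbind(radius * sin(th) * cos(lon), radius * sin(th) * sin(lon),
          radius * cos(th))
  }))
  north <- c(0, 0, radius); south <- c(0, 0, -radius)
  verts <- rbind(verts, north, south)
  ni <- length(rings)
  idx <- function(i, j) (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  tris <- list()
  for (i in seq_len(ni - 1)) {
    j <- seq_len(n_lon)
    a <- idx(i, j); b <- idx(i, j + 1); c <- idx(i + 1, j + 1); d <- idx(i + 1, j)
    tris[[length(tris) + 1]] <- cbind(a, d, c)
    tris[[length(tris) + 1]] <- cbind(a, c, b)
  }
  np <- ni * n_lon + 1L; sp <- np + 1L
  j <- seq_len(n_lon)
  tris[[length(tris) + 1]] <- cbind(rep(np, n_lon), idx(1, j), idx(1, j + 1))
  tris[[length(tris) + 1]] <- cbind(rep(sp, n_lon), idx(ni, j + 1), idx(ni, j))
  mesh <- surface_mesh(verts, do.call(rbind, tris), "uv_sphere")
  if (mesh_volume(mesh) < 0) mesh$triangles[, c(2, 3)] <- mesh$triangles[, c(3, 2)]
  mesh
}

# voxelised ball of given radius on an isotropic grid, centred
ball_mask <- function(radius = 15, n = 40, spacing = 1) {
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  segmentation_mask(r2 <= radius^2, spacing = spacing,
                    origin = rep(ax[1], 3))
}

# small fusiform aneurysm used across modules (cheap to mesh and solve)
small_spec <- function(...) {
  anatomy_spec(neck_radius = 10, max_radius = 14, bulge_center = 20,
               bulge_width = 10, total_length = 40, wall_thickness = 2, ...)
}

small_wall_mesh <- function(n_circ = 24, n_axial = 16, n_layers = 2,
                            spec = small_spec()) {
  surf <- generate_lumen_surface(spec, n_circ, n_axial)
  tag_boundaries(extrude_wall(surf, spec$wall_thickness, n_layers), surf)
}

# straight thick-walled cylinder (a = inner radius) in plane strain:
# uz = 0 on both end planes, three in-plane pins that block the remaining
# rigid modes but are force-free by symmetry of the exact solution
lame_solution <- function(n_circ, n_axial, n_layers, nu,
                          a = 24, b = 26, p = 10e3, L = 8) {
  cspec <- anatomy_spec(neck_radius = a, max_radius = a, total_length = L,
                        bulge_center = L / 2, wall_thickness = b - a)
  surf <- generate_lumen_surface(cspec, n_circ, n_axial)
  mesh <- tag_boundaries(extrude_wall(surf, b - a, n_layers), surf)
  mat <- material_model(0.7, nu)
  f <- pressure_loads(mesh, p)
  nodes <- mesh$nodes
  zmin <- min(nodes[, 3]); zmax <- max(nodes[, 3])
  endn <- which(abs(nodes[, 3] - zmin) < 1e-9 | abs(nodes[, 3] - zmax) < 1e-9)
  fixed <- 3 * (endn - 1) + 3 # axial only: exact plane strain
  pin <- function(dx, dy) which.max(nodes[, 1] * dx + nodes[, 2] * dy)
  fixed <- unique(c(fixed, 3 * (pin(1, 0) - 1) + 2, 3 * (pin(-1, 0) - 1) + 2,
                    3 * (pin(0, 1) - 1) + 1))
  sol <- fem_solve(mesh, mat, f, fixed)
  u_mm <- matrix(sol$u, ncol = 3, byrow = TRUE) * 1e3
  eps <- aortafem:::element_strains(mesh, u_mm)
  sig <- aortafem:::element_stresses(eps, mat) # MPa
  cen <- (nodes[mesh$tets[, 1], ] + nodes[mesh$tets[, 2], ] +
            nodes[mesh$tets[, 3], ] + nodes[mesh$tets[, 4], ]) / 4
  r <- sqrt(cen[, 1]^2 + cen[, 2]^2)
  th <- atan2(cen[, 2], cen[, 1])
  hoop <- sig[, 1] * sin(th)^2 + sig[, 2] * cos(th)^2 -
    2 * sig[, 4] * sin(th) * cos(th)
  mid <- cen[, 3] > zmin + 0.25 * (zmax - zmin) &
    cen[, 3] < zmax - 0.25 * (zmax - zmin)
  inner <- abs(r - min(r)) < 0.5 * (b - a) / n_layers & mid
  lame_hoop <- function(rr) (p / 1e6) * a^2 / (b^2 - a^2) * (1 + b^2 / rr^2)
  # exact plane-strain radial displacement at the inner wall, mm
  E <- 0.7e6
  u_exact <- p * a^2 / (E * (b^2 - a^2)) *
    ((1 + nu) * (1 - 2 * nu) * a + (1 + nu) * b^2 / a)
  list(mesh = mesh, u_mm = u_mm,
       hoop_num = mean(hoop[inner]),
       hoop_ref = lame_hoop(mean(r[inner])),
       max_u = max(sqrt(rowSums(u_mm^2))),
       u_exact = u_exact)
}

# Table-7-shaped calibration pairs as fractions
calibration_pairs <- function() {
  tab <- risk_calibration_table()
  data.frame(ppsm_kpa = tab$ppsm_kpa, risk = tab$risk_percent / 100)
}
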