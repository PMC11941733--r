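#' Parametric description of a fusiform abdominal aortic aneurysm
#'
#' An `anatomy_spec` describes an idealised, unbranched abdominal aorta whose
#' lumen radius follows a Gaussian bulge superimposed on a straight neck:
#' \deqn{r(z) = r_{neck} + (r_{max} - r_{neck})
#'              \exp\left[-\left(\frac{z - z_c}{w}\right)^2\right]}
#' The diagnostic (maximum) diameter is `2 * max_radius`; the cohort of
#' interest spans diagnostic diameters of 48--68 mm. The wall is modelled as a
#' uniform-thickness shell around the lumen (thickness is an assumed unknown
#' in this problem class; 2 mm is a conventional AAA literature value).
#'
#' @param neck_radius neck (undilated) lumen radius, mm.
#' @param max_radius maximum lumen radius at the bulge apex, mm; the
#'   diagnostic diameter is `2 * max_radius`.
#' @param bulge_center axial position of the bulge apex, mm from the inlet.
#' @param bulge_width Gaussian width of the bulge, mm.
#' @param total_length axial length of the modelled segment, mm.
#' @param wall_thickness uniform wall thickness, mm.
#' @param asymmetry in `[0, 1]`; shifts the bulge centreline off-axis by
#'   `asymmetry * (r(z) - neck_radius)` along +x, emulating the anterior
#'   sagging of real fusiform aneurysms. 0 gives a surface of revolution.
#' @param seed integer; seeds phantom noise derived from this spec.
#' @return an object of class `anatomy_spec`.
#' @examples
#' spec <- anatomy_spec(neck_radius = 11, max_radius = 25.5)
#' radius_profile(spec, spec$bulge_center)
#' @export
anatomy_spec <- function(neck_radius = 11, max_radius = 25.5,
                         bulge_center = 60, bulge_width = 20,
                         total_length = 120, wall_thickness = 2,
                         asymmetry = 0, seed = 1L) {
  stopifnot(is.numeric(neck_radius), is.numeric(max_radius))
  if (!(neck_radius > 0)) stop("neck_radius must be > 0")
  if (max_radius < neck_radius) stop("max_radius must be >= neck_radius")
  if (!(bulge_center > 0 && bulge_center < total_length))
    stop("bulge_center must lie strictly inside (0, total_length)")
  if (!(bulge_width > 0)) stop("bulge_width must be > 0")
  if (!(wall_thickness > 0)) stop("wall_thickness must be > 0")
  if (asymmetry < 0 || asymmetry > 1) stop("asymmetry must be in [0, 1]")
  structure(list(
    neck_radius = as.numeric(neck_radius), max_radius = as.numeric(max_radius),
    bulge_center = as.numeric(bulge_center), bulge_width = as.numeric(bulge_width),
    total_length = as.numeric(total_length),
    wall_thickness = as.numeric(wall_thickness),
    asymmetry = as.numeric(asymmetry), seed = as.integer(seed)
  ), class = "anatomy_spec")
}

#' @export
print.anatomy_spec <- function(x, ...) {
  cat(sprintf(
    "anatomy_spec: diagnostic diameter %.1f mm (neck %.1f mm), bulge at %.1f/%.1f mm,\n  width %.1f mm, wall %.2f mm, asymmetry %.2f, seed %d\n",
    2 * x$max_radius, 2 * x$neck_radius, x$bulge_center, x$total_length,
    x$bulge_width, x$wall_thickness, x$asymmetry, x$seed))
  invisible(x)
}

#' Lumen radius at an axial position
#'
#' @param spec an [anatomy_spec()].
#' @param z axial positions in mm; must lie in `[0, total_length]`.
#' @return lumen radii in mm, bounded by `[neck_radius, max_radius]`.
#' @export
radius_profile <- function(spec, z) {
  stopifnot(inherits(spec, "anatomy_spec"))
  if (any(z < 0 | z > spec$total_length))
    stop("z outside [0, total_length]")
  spec$neck_radius + (spec$max_radius - spec$neck_radius) *
    exp(-((z - spec$bulge_center) / spec$bulge_width)^2)
}

# off-axis shift of the lumen centreline (x component; y is 0)
centerline_offset <- function(spec, z) {
  spec$asymmetry * (radius_profile(spec, z) - spec$neck_radius)
}

#' Analytic lumen volume by axial quadrature
#'
#' Integrates \eqn{\pi r(z)^2 dz} over the segment; the off-axis shift does
#' not change cross-section area, so the result is asymmetry-independent.
#'
#' @param spec an [anatomy_spec()].
#' @return lumen volume in mm^3.
#' @export
lumen_volume_analytic <- function(spec) {
  f <- function(z) pi * radius_profile(spec, z)^2
  stats::integrate(f, 0, spec$total_length, rel.tol = 1e-10)$value
}

#' Triangulated lumen surface of a synthetic aneurysm
#'
#' Builds an open-ended tube of revolution (optionally perturbed off-axis by
#' `asymmetry`) with consistently outward-oriented triangles and two boundary
#' loops, at the inlet (z = 0) and outlet (z = total_length).
#'
#' @param spec an [anatomy_spec()].
#' @param n_circumferential number of vertices per ring (>= 8).
#' @param n_axial number of rings including both ends (>= 8).
#' @return a [surface_mesh()].
#' @export
generate_lumen_surface <- function(spec, n_circumferential = 64, n_axial = 96) {
  stopifnot(inherits(spec, "anatomy_spec"))
  if (n_circumferential < 8 || n_axial < 8)
    stop("need n_circumferential >= 8 and n_axial >= 8")
  nc <- as.integer(n_circumferential); na <- as.integer(n_axial)
  z <- seq(0, spec$total_length, length.out = na)
  theta <- 2 * pi * (seq_len(nc) - 1) / nc
  r <- radius_profile(spec, z)
  cx <- centerline_offset(spec, z)
  # vertex (i, j): ring j, spoke i; id = i + (j-1)*nc
  X <- outer(cos(theta), r) + rep(cx, each = nc)
  Y <- outer(sin(theta), r)
  Z <- matrix(rep(z, each = nc), nrow = nc)
  vertices <- cbind(as.vector(X), as.vector(Y), as.vector(Z))
  # quads (i,j)-(i+1,j)-(i+1,j+1)-(i,j+1); theta CCW from +z and z increasing
  # makes (a, b, c), (a, c, d) outward-oriented
  i <- rep(seq_len(nc), na - 1)
  j <- rep(seq_len(na - 1), each = nc)
  ip <- ifelse(i == nc, 1L, i + 1L)
  a <- i + (j - 1L) * nc
  b <- ip + (j - 1L) * nc
  c <- ip + j * nc
  d <- i + j * nc
  triangles <- rbind(cbind(a, b, c), cbind(a, c, d))
  surface_mesh(vertices, triangles,
               provenance = sprintf("generate_lumen_surface(nc=%d, na=%d)", nc, na))
}

#' Voxel intensity volume
#'
#' A scalar intensity grid with per-axis spacing and physical origin: the
#' centre of voxel `[i, j, k]` sits at `origin + (c(i, j, k) - 1) * spacing`
#' (mm). Stands in for a CT series in the synthetic pathway.
#'
#' @param intensities 3D numeric array.
#' @param spacing numeric length 3, mm per axis (> 0).
#' @param origin numeric length 3, mm.
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(intensities, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 3)
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (any(!is.finite(intensities))) stop("intensities must be finite")
  structure(list(intensities = intensities, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("voxel_volume: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Noisy voxel phantom of a synthetic aneurysm
#'
#' Emulates a contrast CT of the lumen: intensity `i_in` inside the lumen,
#' `i_out` outside, plus seeded Gaussian noise (the "fluid noise" real scans
#' carry). Pure function of `(spec, voxel_size, noise_sd, seed)`.
#'
#' @param spec an [anatomy_spec()].
#' @param voxel_size isotropic voxel edge, mm; must resolve the neck.
#' @param noise_sd Gaussian noise standard deviation, intensity units.
#' @param seed integer RNG seed; defaults to `spec$seed`.
#' @param i_in,i_out lumen / background intensity (arbitrary units).
#' @param padding margin of background voxels around the lumen, mm.
#' @return a [voxel_volume()].
#' @export
generate_phantom_volume <- function(spec, voxel_size = 1, noise_sd = 0,
                                    seed = spec$seed, i_in = 1, i_out = 0,
                                    padding = 4) {
  stopifnot(inherits(spec, "anatomy_spec"))
  if (!(voxel_size > 0)) stop("voxel_size must be > 0")
  if (voxel_size > spec$neck_radius)
    stop("voxel_size exceeds neck_radius: geometry unresolvable")
  rmax <- spec$max_radius + spec$asymmetry * (spec$max_radius - spec$neck_radius)
  xr <- c(-rmax - padding, rmax + padding)
  zr <- c(-padding, spec$total_length + padding)
  xs <- seq(xr[1], xr[2], by = voxel_size)
  zs <- seq(zr[1], zr[2], by = voxel_size)
  nx <- length(xs); nz <- length(zs)
  # inside test per (x, y, z): distance to shifted centreline vs r(z)
  inside <- array(FALSE, c(nx, nx, nz))
  inz <- zs >= 0 & zs <= spec$total_length
  if (any(inz)) {
    rz <- radius_profile(spec, zs[inz])
    cz <- centerline_offset(spec, zs[inz])
    y2 <- t(matrix(xs^2, nx, nx)) # (i, j) -> y_j^2
    kk <- which(inz)
    for (m in seq_along(kk)) {
      dx2 <- matrix((xs - cz[m])^2, nx, nx) # (i, j) -> (x_i - cx)^2
      inside[, , kk[m]] <- (dx2 + y2) <= rz[m]^2
    }
  }
  vol <- array(i_out, c(nx, nx, nz))
  vol[inside] <- i_in
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    vol <- vol + array(stats::rnorm(length(vol), 0, noise_sd), dim(vol))
  }
  voxel_volume(vol, spacing = rep(voxel_size, 3),
               origin = c(xr[1], xr[1], zr[1]))
}

#' Sample a synthetic aneurysm cohort
#'
#' Diagnostic diameters are drawn uniformly on \[48, 68\] mm, the span of the
#' reference cohort; the remaining shape parameters vary over ranges a
#' vascular modeller would call plausible for fusiform AAA (neck diameter
#' 20--24 mm, bulge width 18--25 mm, segment length 110--130 mm, mild
#' asymmetry) and the wall is a uniform 2 mm.
#'
#' @param n number of cases (>= 1).
#' @param seed integer RNG seed.
#' @return list of [anatomy_spec()] objects, named `case_01`, ...
#' @export
sample_cohort <- function(n, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  set.seed(as.integer(seed))
  diam <- stats::runif(n, 48, 68)
  neck <- stats::runif(n, 10, 12)
  width <- stats::runif(n, 18, 25)
  len <- stats::runif(n, 110, 130)
  asym <- stats::runif(n, 0, 0.3)
  out <- lapply(seq_len(n), function(i) {
    anatomy_spec(neck_radius = neck[i], max_radius = diam[i] / 2,
                 bulge_center = len[i] / 2, bulge_width = width[i],
                 total_length = len[i], wall_thickness = 2,
                 asymmetry = asym[i], seed = as.integer(seed) + i)
  })
  names(out) <- sprintf("case_%02d", seq_len(n))
  out
}
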