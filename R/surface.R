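#' Triangulated surface mesh
#'
#' Vertices in physical millimetres, 1-based triangle vertex indices,
#' consistent winding. Used for both synthetic lumen surfaces and surfaces
#' reconstructed from voxel masks.
#'
#' @param vertices numeric matrix n x 3 (mm).
#' @param triangles integer matrix m x 3 of vertex indices.
#' @param provenance free-text record of how the surface was produced.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, provenance = "") {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles); storage.mode(triangles) <- "integer"
  dimnames(vertices) <- NULL; dimnames(triangles) <- NULL
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3)
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles,
                 provenance = provenance),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles%s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  invisible(x)
}

tri_cross <- function(mesh) {
  v <- mesh$vertices; t <- mesh$triangles
  e1 <- v[t[, 2], , drop = FALSE] - v[t[, 1], , drop = FALSE]
  e2 <- v[t[, 3], , drop = FALSE] - v[t[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Total surface area (mm^2)
#' @param mesh a [surface_mesh()].
#' @export
surface_area <- function(mesh) {
  cr <- tri_cross(mesh)
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Per-triangle areas and unit normals
#' @param mesh a [surface_mesh()].
#' @return list with `areas` (mm^2) and `normals` (m x 3 unit vectors).
#' @export
triangle_normals <- function(mesh) {
  cr <- tri_cross(mesh)
  a2 <- sqrt(rowSums(cr^2))
  if (any(a2 <= 0)) stop("degenerate (zero-area) triangle present")
  list(areas = a2 / 2, normals = cr / a2)
}

#' Enclosed volume by the divergence theorem (mm^3)
#'
#' Signed: positive when triangles are consistently outward-oriented.
#' Meaningful only for closed surfaces (see [cap_ends()]).
#' @param mesh a [surface_mesh()].
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; t <- mesh$triangles
  p1 <- v[t[, 1], , drop = FALSE]
  p2 <- v[t[, 2], , drop = FALSE]
  p3 <- v[t[, 3], , drop = FALSE]
  cr <- cbind(p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2],
              p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3],
              p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  sum(rowSums(p1 * cr)) / 6
}

# undirected edge table: one row per edge occurrence, key = lo * nv + hi
edge_keys <- function(mesh) {
  t <- mesh$triangles
  a <- c(t[, 1], t[, 2], t[, 3])
  b <- c(t[, 2], t[, 3], t[, 1])
  lo <- pmin(a, b); hi <- pmax(a, b)
  list(lo = lo, hi = hi,
       key = as.numeric(lo) * (nrow(mesh$vertices) + 1) + hi)
}

#' Euler characteristic V - E + F
#' @param mesh a [surface_mesh()].
#' @export
euler_characteristic <- function(mesh) {
  ek <- edge_keys(mesh)
  nrow(mesh$vertices) - length(unique(ek$key)) + nrow(mesh$triangles)
}

#' Boundary edges and loops of an open surface
#'
#' Boundary edges are those used by exactly one triangle; they are chained
#' into closed loops of vertex indices.
#' @param mesh a [surface_mesh()].
#' @return list of integer vectors, one per loop (empty for closed surfaces).
#' @export
boundary_loops <- function(mesh) {
  ek <- edge_keys(mesh)
  tab <- table(ek$key)
  bkey <- as.numeric(names(tab)[tab == 1])
  if (length(bkey) == 0) return(list())
  sel <- match(bkey, ek$key)
  lo <- ek$lo[sel]; hi <- ek$hi[sel]
  # adjacency among boundary vertices (each has exactly 2 boundary edges)
  verts <- sort(unique(c(lo, hi)))
  nb <- vector("list", length(verts))
  idx <- function(v) match(v, verts)
  for (m in seq_along(lo)) {
    i <- idx(lo[m]); j <- idx(hi[m])
    nb[[i]] <- c(nb[[i]], hi[m]); nb[[j]] <- c(nb[[j]], lo[m])
  }
  visited <- rep(FALSE, length(verts))
  loops <- list()
  for (s in seq_along(verts)) {
    if (visited[s]) next
    loop <- integer(0)
    cur <- verts[s]; prev <- NA_integer_
    repeat {
      ci <- idx(cur)
      visited[ci] <- TRUE
      loop <- c(loop, cur)
      nxt <- setdiff(nb[[ci]], prev)
      if (length(nxt) == 0) break
      nxt <- nxt[1]
      if (nxt == verts[s]) break
      prev <- cur; cur <- nxt
    }
    loops[[length(loops) + 1]] <- loop
  }
  loops
}

#' Close an open tube by fan-capping its boundary loops
#'
#' Adds one centroid vertex per boundary loop and a triangle fan oriented
#' consistently with the existing surface, producing a watertight mesh whose
#' [mesh_volume()] is the enclosed lumen volume.
#' @param mesh a [surface_mesh()].
#' @return a watertight [surface_mesh()].
#' @export
cap_ends <- function(mesh) {
  loops <- boundary_loops(mesh)
  if (length(loops) == 0) return(mesh)
  v <- mesh$vertices; tri <- mesh$triangles
  for (loop in loops) {
    cen <- colMeans(v[loop, , drop = FALSE])
    v <- rbind(v, cen)
    ci <- nrow(v)
    nxt <- c(loop[-1], loop[1])
    tri <- rbind(tri, cbind(loop, nxt, ci))
  }
  out <- surface_mesh(v, tri, provenance = paste0(mesh$provenance, " +caps"))
  # orient caps (and everything) consistently outward: flip all if volume < 0,
  # then flip individual caps that disagree with the tube via volume gradient
  fix_cap <- function(m, rows) {
    vol0 <- mesh_volume(m)
    m2 <- m
    m2$triangles[rows, c(2, 3)] <- m2$triangles[rows, c(3, 2)]
    if (abs(mesh_volume(m2)) > abs(vol0)) m2 else m
  }
  ncap_rows <- (nrow(mesh$triangles) + 1):nrow(tri)
  # caps were added loop by loop; fix each loop's fan separately
  start <- nrow(mesh$triangles)
  for (loop in loops) {
    rows <- start + seq_along(loop)
    out <- fix_cap(out, rows)
    start <- start + length(loop)
  }
  if (mesh_volume(out) < 0)
    out$triangles[, c(2, 3)] <- out$triangles[, c(3, 2)]
  out
}

#' Maximum cross-sectional diameter along an axis
#'
#' Vertices are binned along `axis`; within each bin the diameter is the
#' maximum in-plane chord (computed exactly on the 2D convex hull of the
#' bin's vertices, so it is insensitive to non-uniform vertex density and to
#' off-axis sections).
#'
#' @param mesh a [surface_mesh()].
#' @param axis 1, 2 or 3 (default 3 = z).
#' @param bin_width_mm axial bin width, mm.
#' @return maximum diameter in mm.
#' @export
measure_max_diameter <- function(mesh, axis = 3, bin_width_mm = 2) {
  v <- mesh$vertices
  w <- v[, axis]
  pl <- v[, setdiff(1:3, axis), drop = FALSE]
  bins <- floor((w - min(w)) / bin_width_mm)
  best <- 0
  for (b in unique(bins)) {
    p <- pl[bins == b, , drop = FALSE]
    if (nrow(p) < 3) next
    h <- p[grDevices::chull(p), , drop = FALSE]
    d2 <- max(outer(h[, 1], h[, 1], `-`)^2 + outer(h[, 2], h[, 2], `-`)^2)
    d <- sqrt(d2)
    if (d > best) best <- d
  }
  best
}
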