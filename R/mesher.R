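#' Tetrahedral wall-volume mesh
#'
#' Nodes in mm; tets as 1-based node index quadruples with positive signed
#' volume; `inlet_nodes` / `outlet_nodes` are the fully fixed boundary node
#' sets; `lumen_faces` are the inner-surface triangles (base-layer node ids)
#' carrying the pressure load, wound so their normals point into the lumen,
#' i.e. outward from the solid wall.
#'
#' @param nodes numeric n x 3 (mm).
#' @param tets integer m x 4.
#' @param inlet_nodes,outlet_nodes integer node-id vectors.
#' @param lumen_faces integer t x 3.
#' @param element_size_target mm, informational.
#' @param n_base number of base-surface vertices (layer stride).
#' @return an object of class `wall_mesh`.
#' @export
wall_mesh <- function(nodes, tets, inlet_nodes = integer(0),
                      outlet_nodes = integer(0),
                      lumen_faces = matrix(0L, 0, 3),
                      element_size_target = NA_real_, n_base = nrow(nodes)) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  tets <- as.matrix(tets); storage.mode(tets) <- "integer"
  dimnames(nodes) <- NULL; dimnames(tets) <- NULL
  stopifnot(ncol(nodes) == 3, ncol(tets) == 4)
  structure(list(nodes = nodes, tets = tets,
                 inlet_nodes = as.integer(inlet_nodes),
                 outlet_nodes = as.integer(outlet_nodes),
                 lumen_faces = matrix(as.integer(lumen_faces), ncol = 3),
                 element_size_target = element_size_target,
                 n_base = as.integer(n_base)),
            class = "wall_mesh")
}

#' @export
print.wall_mesh <- function(x, ...) {
  cat(sprintf(
    "wall_mesh: %d nodes, %d tets, %d inlet / %d outlet nodes, %d lumen faces\n",
    nrow(x$nodes), nrow(x$tets), length(x$inlet_nodes), length(x$outlet_nodes),
    nrow(x$lumen_faces)))
  invisible(x)
}

#' Signed tetrahedron volumes (mm^3)
#' @param mesh a [wall_mesh()].
#' @export
tet_volumes <- function(mesh) {
  n <- mesh$nodes; t <- mesh$tets
  a <- n[t[, 2], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  b <- n[t[, 3], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  c <- n[t[, 4], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Area-weighted vertex normals of a surface
#'
#' The unnormalised per-triangle cross product is area-weighted already, so
#' accumulating raw cross products at the vertices and normalising gives the
#' area-weighted average normal.
#'
#' @param surface a consistently oriented [surface_mesh()].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(surface) {
  v <- surface$vertices; t <- surface$triangles
  cr <- tri_cross(surface)
  n <- matrix(0, nrow(v), 3)
  for (c in 1:3) {
    for (dim in 1:3) {
      acc <- rowsum(cr[, dim], t[, c], reorder = FALSE)
      n[as.integer(rownames(acc)), dim] <- n[as.integer(rownames(acc)), dim] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  if (any(len == 0)) stop("isolated vertex (no incident triangle)")
  n / len
}

# Dompierre-style prism -> 3 tets split keyed on global base-vertex indices.
# Prism columns: bottom (b1, b2, b3), top = bottom + stride. Rotating so the
# smallest base index leads makes every quad-face diagonal start at its
# smallest bottom vertex, so neighbouring prisms agree edge-for-edge.
split_prism <- function(b, stride) {
  r <- which.min(b) - 1L
  if (r > 0) b <- c(b[-seq_len(r)], b[seq_len(r)])
  t_ <- b + stride
  if (b[2] < b[3]) {
    rbind(c(b[1], b[2], b[3], t_[3]),
          c(b[1], b[2], t_[3], t_[2]),
          c(b[1], t_[2], t_[3], t_[1]))
  } else {
    rbind(c(b[1], b[2], b[3], t_[2]),
          c(b[1], t_[2], b[3], t_[3]),
          c(b[1], t_[2], t_[3], t_[1]))
  }
}

#' Extrude a lumen surface into a tetrahedral wall mesh
#'
#' Offsets the surface outward along area-weighted vertex normals in
#' `n_layers` equal shells and splits each prism into 3 tets with a
#' globally consistent diagonal rule, so faces conform across neighbours.
#'
#' @param surface a manifold, outward-oriented [surface_mesh()] (the lumen).
#' @param thickness wall thickness, mm (> 0).
#' @param n_layers number of element layers through the wall (>= 1).
#' @return a [wall_mesh()] (boundary sets untagged; see [tag_boundaries()]).
#' @export
extrude_wall <- function(surface, thickness, n_layers = 2) {
  stopifnot(inherits(surface, "surface_mesh"))
  if (!(thickness > 0)) stop("thickness must be > 0")
  if (n_layers < 1) stop("n_layers must be >= 1")
  nv <- nrow(surface$vertices)
  nrm <- vertex_normals(surface)
  layers <- lapply(0:n_layers, function(l) {
    surface$vertices + nrm * (thickness * l / n_layers)
  })
  nodes <- do.call(rbind, layers)
  tri <- surface$triangles
  tets_by_tri <- lapply(seq_len(nrow(tri)), function(m) {
    base <- tri[m, ]
    do.call(rbind, lapply(seq_len(n_layers), function(l) {
      split_prism(base + (l - 1L) * nv, nv)
    }))
  })
  tets <- do.call(rbind, tets_by_tri)
  mesh <- wall_mesh(nodes, tets, n_base = nv)
  vol <- tet_volumes(mesh)
  neg <- vol < 0
  if (any(neg)) {
    # prism orientation depends on surface winding; flip uniformly if needed
    if (all(neg)) {
      mesh$tets[, c(3, 4)] <- mesh$tets[, c(4, 3)]
      vol <- -vol
    } else {
      bad <- unique(as.vector(mesh$tets[neg, ])) %% nv
      bad[bad == 0] <- nv
      stop("self-intersecting offset near surface vertices ",
           paste(utils::head(sort(unique(bad)), 10), collapse = ", "),
           " (wall thickness too large for local curvature)")
    }
  }
  if (any(vol <= 0)) stop("degenerate tetrahedra in extrusion")
  mesh$element_size_target <- thickness / n_layers
  mesh
}

#' Tag inlet/outlet node sets and lumen faces of an extruded tube
#'
#' Inlet nodes are all through-thickness copies of the z-min boundary loop of
#' the generating surface, likewise outlet at z-max. Lumen faces are the
#' original inner-surface triangles, rewound so normals point into the lumen
#' (outward from the solid).
#'
#' @param mesh a [wall_mesh()] produced by [extrude_wall()].
#' @param surface the generating open [surface_mesh()].
#' @return the mesh with `inlet_nodes`, `outlet_nodes`, `lumen_faces` set.
#' @export
tag_boundaries <- function(mesh, surface) {
  loops <- boundary_loops(surface)
  if (length(loops) < 2)
    stop("surface has no two boundary loops (closed surface?)")
  zm <- vapply(loops, function(l) mean(surface$vertices[l, 3]), 0)
  inlet_base <- loops[[which.min(zm)]]
  outlet_base <- loops[[which.max(zm)]]
  n_layers <- nrow(mesh$nodes) / mesh$n_base - 1L
  expand <- function(base) {
    as.integer(outer(base, (0:n_layers) * mesh$n_base, `+`))
  }
  mesh$inlet_nodes <- expand(inlet_base)
  mesh$outlet_nodes <- expand(outlet_base)
  # inner surface triangles; outward tube winding -> flip so normals point
  # into the lumen (outward from the wall solid)
  mesh$lumen_faces <- surface$triangles[, c(1, 3, 2), drop = FALSE]
  mesh
}

#' Conformity check: every interior face shared by exactly 2 tets
#'
#' @param mesh a [wall_mesh()].
#' @return list with `conforming` (logical) and the face-multiplicity table.
#' @export
check_conformity <- function(mesh) {
  t <- mesh$tets
  faces <- rbind(t[, c(1, 2, 3)], t[, c(1, 2, 4)], t[, c(1, 3, 4)], t[, c(2, 3, 4)])
  lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
  nv <- nrow(mesh$nodes) + 1
  key <- (as.numeric(lo) * nv + mid) * nv + hi
  tab <- tabulate(match(key, unique(key)))
  list(conforming = all(tab %in% c(1L, 2L)), multiplicity = table(tab))
}
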