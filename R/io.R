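#' Write a surface mesh to STL
#'
#' @param mesh a [surface_mesh()].
#' @param path output file.
#' @param ascii write ASCII STL (default) or binary STL.
#' @param name solid name for the ASCII header.
#' @export
write_stl <- function(mesh, path, ascii = TRUE, name = "aortafem") {
  tn <- triangle_normals(mesh)
  v <- mesh$vertices; t <- mesh$triangles
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", name), con)
    for (m in seq_len(nrow(t))) {
      writeLines(c(
        sprintf("  facet normal %.9e %.9e %.9e",
                tn$normals[m, 1], tn$normals[m, 2], tn$normals[m, 3]),
        "    outer loop",
        sprintf("      vertex %.9e %.9e %.9e",
                v[t[m, ], 1], v[t[m, ], 2], v[t[m, ], 3]),
        "    endloop", "  endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", name), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "aortafem binary STL"))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nrow(t)), con, size = 4, endian = "little")
    for (m in seq_len(nrow(t))) {
      writeBin(c(tn$normals[m, ], t(v[t[m, ], ])), con, size = 4,
               endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an STL file (ASCII or binary)
#'
#' Vertices are welded by exact coordinate match, so watertight solids
#' round-trip with their connectivity restored.
#'
#' @param path STL file.
#' @return a [surface_mesh()].
#' @export
read_stl <- function(path) {
  head5 <- readBin(path, "raw", 5)
  is_ascii <- identical(rawToChar(head5), "solid") && {
    # binary STLs may also start with "solid": check plausible triangle count
    txt <- tryCatch(readLines(path, n = 2, warn = FALSE), error = function(e) "")
    any(grepl("facet", txt))
  }
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
      as.numeric(p[2:4])
    }))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    nt <- readBin(con, "integer", 1, size = 4, endian = "little")
    xyz <- matrix(0, 3 * nt, 3)
    for (m in seq_len(nt)) {
      rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
      xyz[(3 * m - 2):(3 * m), ] <- matrix(rec[4:12], 3, byrow = TRUE)
      readBin(con, "integer", 1, size = 2, endian = "little")
    }
  }
  key <- paste(xyz[, 1], xyz[, 2], xyz[, 3])
  uk <- unique(key)
  vid <- match(key, uk)
  verts <- xyz[match(uk, key), , drop = FALSE]
  tri <- matrix(vid, ncol = 3, byrow = TRUE)
  surface_mesh(verts, tri, provenance = paste0("read_stl(", basename(path), ")"))
}

#' Export a wall mesh (and optional point/cell fields) to ASCII VTU
#'
#' Minimal VTK unstructured-grid writer (tet cells, type 10) understood by
#' ParaView; point data arrays must have one row per node, cell data one
#' value per tet.
#'
#' @param mesh a [wall_mesh()].
#' @param path output `.vtu` file.
#' @param point_data named list of per-node vectors/matrices.
#' @param cell_data named list of per-element vectors.
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  num <- function(x) paste(format(x, digits = 9, trim = TRUE), collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m)
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w('          %s', num(t(mesh$nodes)))
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  w('          %s', num(t(mesh$tets) - 1L))
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  w('          %s', num(4L * seq_len(m)))
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  w('          %s', num(rep(10L, m)))
  w('        </DataArray>')
  w('      </Cells>')
  emit_fields <- function(fields, where) {
    if (length(fields) == 0) return()
    w('      <%s>', where)
    for (nm in names(fields)) {
      x <- fields[[nm]]
      nc <- if (is.matrix(x)) ncol(x) else 1L
      w('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
        nm, nc)
      w('          %s', num(if (is.matrix(x)) t(x) else x))
      w('        </DataArray>')
    }
    w('      </%s>', where)
  }
  emit_fields(point_data, "PointData")
  emit_fields(cell_data, "CellData")
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Write / read a wall mesh in a documented plain-text format
#'
#' Header line `aortafem-mesh 1`, then counts, then blocks: `nodes` (x y z in
#' mm), `tets` (4 node ids), `inlet`, `outlet` (node ids), `lumen_faces`
#' (3 node ids). Whitespace-separated, 1-based ids.
#'
#' @param mesh a [wall_mesh()].
#' @param path output file.
#' @export
write_mesh_text <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("aortafem-mesh 1", con)
  writeLines(sprintf("counts %d %d %d %d %d %d",
                     nrow(mesh$nodes), nrow(mesh$tets),
                     length(mesh$inlet_nodes), length(mesh$outlet_nodes),
                     nrow(mesh$lumen_faces), mesh$n_base), con)
  writeLines(apply(format(mesh$nodes, digits = 17, trim = TRUE), 1, paste,
                   collapse = " "), con)
  writeLines(apply(mesh$tets, 1, paste, collapse = " "), con)
  writeLines(paste(mesh$inlet_nodes, collapse = " "), con)
  writeLines(paste(mesh$outlet_nodes, collapse = " "), con)
  if (nrow(mesh$lumen_faces) > 0)
    writeLines(apply(mesh$lumen_faces, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_mesh_text
#' @export
read_mesh_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1], "aortafem-mesh")) stop("not an aortafem mesh file")
  cnt <- as.integer(strsplit(lines[2], " ")[[1]][-1])
  pos <- 2
  take <- function(k) {
    block <- lines[(pos + 1):(pos + k)]
    pos <<- pos + k
    block
  }
  parse_mat <- function(block, nc) {
    matrix(as.numeric(unlist(strsplit(trimws(block), "\\s+"))), ncol = nc,
           byrow = TRUE)
  }
  nodes <- parse_mat(take(cnt[1]), 3)
  tets <- parse_mat(take(cnt[2]), 4)
  inlet <- as.integer(strsplit(trimws(take(1)), "\\s+")[[1]])
  outlet <- as.integer(strsplit(trimws(take(1)), "\\s+")[[1]])
  lum <- if (cnt[5] > 0) parse_mat(take(cnt[5]), 3) else matrix(0L, 0, 3)
  wall_mesh(nodes, tets, inlet, outlet, lum, n_base = cnt[6])
}

#' Export / import a voxel volume as raw doubles plus a JSON header
#'
#' The header (`<path>.json`) records dimensions, spacing, origin and the
#' on-disk value type; the payload is little-endian float64 in R's native
#' column-major order.
#'
#' @param volume a [voxel_volume()].
#' @param path payload path (header written next to it).
#' @export
write_volume_raw <- function(volume, path) {
  hdr <- list(format = "aortafem-raw-volume", version = 1L,
              dim = dim(volume$intensities), spacing = volume$spacing,
              origin = volume$origin, dtype = "float64-little")
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(volume$intensities), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_volume_raw
#' @export
read_volume_raw <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(hdr$format, "aortafem-raw-volume")) stop("unknown volume format")
  n <- prod(hdr$dim)
  x <- readBin(path, "numeric", n, size = 8, endian = "little")
  voxel_volume(array(x, hdr$dim), hdr$spacing, hdr$origin)
}

#' Serialize / restore an anatomy spec (or list of specs) as JSON
#'
#' @param specs an [anatomy_spec()] or list thereof.
#' @param path JSON file.
#' @export
write_cohort_json <- function(specs, path) {
  if (inherits(specs, "anatomy_spec")) specs <- list(specs)
  if (is.null(names(specs)) || any(!nzchar(names(specs))))
    names(specs) <- sprintf("case_%02d", seq_along(specs))
  df <- do.call(rbind, lapply(names(specs), function(nm) {
    cbind(data.frame(case_id = nm, stringsAsFactors = FALSE),
          as.data.frame(unclass(specs[[nm]])))
  }))
  jsonlite::write_json(df, path, digits = I(17))
  invisible(path)
}

#' @rdname write_cohort_json
#' @export
read_cohort_json <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    do.call(anatomy_spec, as.list(df[i, setdiff(names(df), "case_id")]))
  })
  names(out) <- df$case_id
  out
}
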