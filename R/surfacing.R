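#' Construct a validated triangle surface mesh
#'
#' @param vertices V x 3 numeric matrix of positions (Angstrom).
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @param normals optional V x 3 matrix of unit vertex normals; computed from
#'   the faces via [compute_vertex_normals()] when absent.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3 || ncol(faces) != 3) stop("vertices and faces must have 3 columns")
  if (any(!is.finite(vertices))) stop("mesh vertices contain non-finite values")
  if (nrow(faces) > 0) {
    if (min(faces) < 1 || max(faces) > nrow(vertices)) stop("face index out of range")
    degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] | faces[, 2] == faces[, 3]
    if (any(degen)) stop("faces with repeated vertices are not allowed")
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  mesh <- structure(list(vertices = vertices, faces = faces, normals = NULL),
                    class = "surface_mesh")
  if (is.null(normals)) {
    mesh <- compute_vertex_normals(mesh)
  } else {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    if (!all(dim(normals) == dim(vertices))) stop("normals must match vertices in shape")
    len <- sqrt(rowSums(normals^2))
    if (any(abs(len - 1) > 1e-6)) stop("normals must have unit length")
    dimnames(normals) <- NULL
    mesh$normals <- normals
  }
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> V=%d F=%d (chi=%d)\n", nrow(x$vertices),
              nrow(x$faces), euler_characteristic(x)))
  invisible(x)
}

#' Euler characteristic V - E + F of a mesh
#' @param mesh a `surface_mesh`.
#' @export
euler_characteristic <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  n_edges <- nrow(unique(e))
  nrow(mesh$vertices) - n_edges + nrow(f)
}

#' Signed Euclidean distance field of an atom cloud
#'
#' Evaluates, on a regular grid, the probe-inflated distance to the van der
#' Waals surface: `f(g) = min_i (|g - p_i| - r_vdw(i)) - probe`. Negative
#' inside the inflated envelope, positive outside; its zero level set is the
#' molecular surface used throughout the pipeline.
#'
#' @param cloud an [atom_cloud()].
#' @param spacing grid spacing in Angstrom (default 0.7).
#' @param probe_radius solvent probe radius in Angstrom (default 1.4).
#' @param padding extra margin around the atom bounding box; defaults to
#'   `probe_radius + max(r_vdw) + 2 * spacing`, the minimum that keeps the
#'   zero level set away from the grid boundary.
#' @param max_cells guard against accidental huge grids.
#' @param band optional evaluation band in Angstrom: when finite, values are
#'   exact wherever `|f| < band` and clamped to `+band` elsewhere. Because the
#'   distance field is 1-Lipschitz this leaves every level-set cell with
#'   `|level| < band - spacing * sqrt(3)` untouched while evaluation cost
#'   drops from grid x atoms to a local sweep per atom. Default `Inf` (exact
#'   everywhere).
#' @return a `scalar_field`: list with `origin`, `spacing`, `dims`, and a
#'   3D `values` array (Angstrom).
#' @export
build_distance_field <- function(cloud, spacing = 0.7, probe_radius = 1.4,
                                 padding = NULL, max_cells = 4e7, band = Inf) {
  stopifnot(inherits(cloud, "atom_cloud"))
  if (spacing <= 0) stop("spacing must be positive")
  if (probe_radius < 0) stop("probe_radius must be non-negative")
  radii <- atom_radii(cloud)
  pad_min <- probe_radius + max(radii) + 2 * spacing
  padding <- padding %||% pad_min
  if (padding < pad_min) padding <- pad_min
  lo <- apply(cloud$xyz, 2, min) - padding
  hi <- apply(cloud$xyz, 2, max) + padding
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  if (prod(as.numeric(dims)) > max_cells) {
    stop(sprintf("grid of %d x %d x %d cells exceeds the cell budget; use a coarser spacing",
                 dims[1], dims[2], dims[3]))
  }
  vals <- if (is.finite(band)) {
    if (band < 3 * spacing) stop("band must be at least 3 * spacing")
    cpp_distance_field_banded(cloud$xyz, radii, lo, spacing, dims,
                              probe_radius, band)
  } else {
    cpp_distance_field(cloud$xyz, radii, lo, spacing, dims, probe_radius)
  }
  structure(list(origin = unname(lo), spacing = spacing, dims = dims,
                 values = array(vals, dim = dims)),
            class = "scalar_field")
}

#' Evaluate a scalar field's defining formula directly at arbitrary points
#'
#' Convenience for checking grid values against the analytic definition.
#' @param cloud an [atom_cloud()].
#' @param points m x 3 matrix.
#' @param probe_radius probe radius in Angstrom.
#' @export
distance_field_at <- function(cloud, points, probe_radius = 1.4) {
  points <- rbind(points)
  unname(apply(points, 1, function(p) {
    d <- sqrt(colSums((t(cloud$xyz) - p)^2))
    min(d - atom_radii(cloud)) - probe_radius
  }))
}

#' Extract the triangulated isosurface of a scalar field
#'
#' Marching-tetrahedra triangulation of the requested level set, with face
#' winding such that computed normals point toward increasing field values
#' (outward for a distance field).
#'
#' @param field a `scalar_field` from [build_distance_field()].
#' @param level iso level in Angstrom (default 0, the molecular surface).
#' @return a [surface_mesh()] with vertex normals attached.
#' @export
extract_isosurface <- function(field, level = 0) {
  stopifnot(inherits(field, "scalar_field"))
  rng <- range(field$values)
  if (level <= rng[1] || level >= rng[2]) {
    stop(sprintf("level %.3f outside field range [%.3f, %.3f]: empty surface",
                 level, rng[1], rng[2]))
  }
  res <- cpp_marching_tets(as.numeric(field$values), field$dims, field$origin,
                           field$spacing, level)
  surface_mesh(res$vertices, res$faces)
}

#' Compute outward vertex normals from face geometry
#'
#' Face normals are the normalised cross products of the face edge vectors;
#' each vertex normal is the normalised sum of its incident face normals.
#' Vertices with no incident face are dropped with a warning.
#'
#' @param mesh a `surface_mesh` with consistently wound faces.
#' @return the mesh with unit `normals` attached.
#' @export
compute_vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0) stop("mesh has no faces")
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(fn^2))
  len[len == 0] <- 1
  fn <- fn / len
  idx <- as.vector(f)
  acc <- rowsum(rbind(fn, fn, fn), idx)           # sum over incident faces
  touched <- as.integer(rownames(acc))
  nrm <- matrix(0, nrow(v), 3)
  nrm[touched, ] <- acc
  nlen <- sqrt(rowSums(nrm^2))
  isolated <- nlen == 0
  if (any(isolated)) {
    warning(sprintf("dropping %d isolated vertices", sum(isolated)))
    keep <- which(!isolated)
    remap <- match(seq_len(nrow(v)), keep)
    v <- v[keep, , drop = FALSE]
    f <- matrix(remap[f], ncol = 3)
    return(compute_vertex_normals(structure(
      list(vertices = v, faces = f, normals = NULL), class = "surface_mesh")))
  }
  mesh$normals <- nrm / nlen
  mesh
}

#' Surface a protein in one call
#'
#' Distance field plus isosurface extraction with the module defaults; the
#' field is evaluated in a band around the surface (exact there), which does
#' not change the extracted zero level set.
#' @param cloud an [atom_cloud()].
#' @inheritParams build_distance_field
#' @export
surface_protein <- function(cloud, spacing = 0.7, probe_radius = 1.4) {
  extract_isosurface(
    build_distance_field(cloud, spacing, probe_radius, band = 4 * spacing), 0)
}

# ---- mesh file I/O (ascii PLY and OFF) --------------------------------------

#' Read a triangle mesh from an ascii PLY or OFF file
#'
#' @param path file path; format chosen by extension (`.ply` / `.off`).
#' @return a [surface_mesh()]; normals are recomputed when the file has none.
#' @export
load_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  res <- switch(ext, ply = read_ply(path), off = read_off(path),
                stop("unsupported mesh format: .", ext))
  if (any(!is.finite(res$vertices))) stop("mesh file contains non-finite vertices")
  surface_mesh(res$vertices, res$faces, res$normals)
}

#' Write a triangle mesh to an ascii PLY or OFF file
#' @param mesh a `surface_mesh`.
#' @param path output path; format chosen by extension.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  f <- mesh$faces
  if (ext == "ply") {
    nrm <- mesh$normals
    header <- c("ply", "format ascii 1.0",
                sprintf("element vertex %d", nrow(v)),
                "property float x", "property float y", "property float z",
                if (!is.null(nrm)) c("property float nx", "property float ny",
                                     "property float nz"),
                sprintf("element face %d", nrow(f)),
                "property list uchar int vertex_indices", "end_header")
    vl <- if (is.null(nrm)) {
      sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3])
    } else {
      sprintf("%.6f %.6f %.6f %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3],
              nrm[, 1], nrm[, 2], nrm[, 3])
    }
    fl <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
    writeLines(c(header, vl, fl), path)
  } else if (ext == "off") {
    writeLines(c("OFF", sprintf("%d %d 0", nrow(v), nrow(f)),
                 sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]),
                 sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)),
               path)
  } else {
    stop("unsupported mesh format: .", ext)
  }
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || trimws(lines[1]) != "ply") stop("not a PLY file")
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop("PLY header has no end_header")
  header <- trimws(lines[seq_len(hdr_end)])
  if (!any(grepl("^format\\s+ascii", header))) stop("only ascii PLY is supported")
  elem_lines <- grep("^element\\s", header)
  elems <- do.call(rbind, lapply(strsplit(header[elem_lines], "\\s+"), function(x) x[2:3]))
  nv <- as.integer(elems[elems[, 1] == "vertex", 2])
  nf <- as.integer(elems[elems[, 1] == "face", 2])
  # vertex property names, in order, to locate x/y/z and optional normals
  vstart <- elem_lines[which(elems[, 1] == "vertex")]
  vstop <- min(c(elem_lines[elem_lines > vstart], hdr_end)) - 1
  vprops <- vapply(strsplit(header[(vstart + 1):vstop], "\\s+"),
                   function(x) x[length(x)], "")
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vtab <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"), as.numeric))
  xyz_cols <- match(c("x", "y", "z"), vprops)
  if (any(is.na(xyz_cols))) stop("PLY vertex element lacks x/y/z properties")
  vertices <- vtab[, xyz_cols, drop = FALSE]
  normals <- NULL
  n_cols <- match(c("nx", "ny", "nz"), vprops)
  if (!any(is.na(n_cols))) normals <- vtab[, n_cols, drop = FALSE]
  ftab <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  counts <- vapply(ftab, function(x) as.integer(x[1]), 1L)
  if (any(counts != 3)) stop("non-triangular face in PLY file (only triangles supported)")
  faces <- do.call(rbind, lapply(ftab, function(x) as.integer(x[2:4]) + 1L))
  list(vertices = vertices, faces = faces, normals = normals)
}

read_off <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (lines[1] != "OFF") stop("not an OFF file")
  counts <- as.integer(strsplit(lines[2], "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vertices <- do.call(rbind, lapply(strsplit(lines[2 + seq_len(nv)], "\\s+"), as.numeric))
  ftab <- strsplit(lines[2 + nv + seq_len(nf)], "\\s+")
  fc <- vapply(ftab, function(x) as.integer(x[1]), 1L)
  if (any(fc != 3)) stop("non-triangular face in OFF file (only triangles supported)")
  faces <- do.call(rbind, lapply(ftab, function(x) as.integer(x[2:4]) + 1L))
  list(vertices = vertices[, 1:3, drop = FALSE], faces = faces, normals = NULL)
}
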