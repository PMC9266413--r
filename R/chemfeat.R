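#' Fourier distance features
#'
#' Multi-scale encoding of a non-negative distance:
#' `gamma(d) = (d, cos(d/2^0), sin(d/2^0), ..., cos(d/2^F), sin(d/2^F))`,
#' of length `1 + 2 * (F + 1)`.
#'
#' @param d numeric vector of distances (Angstrom, >= 0).
#' @param F non-negative integer order (default 4).
#' @return a matrix with `length(d)` rows and `1 + 2 * (F + 1)` columns.
#' @export
fourier_distance_features <- function(d, F = 4) {
  d <- as.numeric(d)
  if (any(!is.finite(d)) || any(d < 0)) stop("distances must be finite and non-negative")
  if (F < 0) stop("F must be non-negative")
  scales <- 2^(0:F)
  out <- matrix(0, length(d), 1 + 2 * (F + 1))
  out[, 1] <- d
  for (s in seq_along(scales)) {
    out[, 2 * s] <- cos(d / scales[s])
    out[, 2 * s + 1] <- sin(d / scales[s])
  }
  colnames(out) <- c("d", as.vector(rbind(paste0("cos", 0:F), paste0("sin", 0:F))))
  out
}

# Kyte-Doolittle hydropathy scale
kyte_doolittle <- c(
  ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5, MET = 1.9, ALA = 1.8,
  GLY = -0.4, THR = -0.7, SER = -0.8, TRP = -0.9, TYR = -1.3, PRO = -1.6,
  HIS = -3.2, GLU = -3.5, GLN = -3.5, ASP = -3.5, ASN = -3.5, LYS = -3.9,
  ARG = -4.5
)

#' Residue hydrophobicity on the Kyte-Doolittle scale, rescaled to [-1, 1]
#'
#' Scale values are divided by 4.5 so isoleucine maps to +1 and arginine
#' to -1. Unknown residue codes return 0 with a warning.
#'
#' @param residue_name character vector of 3-letter residue codes.
#' @return numeric vector in `[-1, 1]`.
#' @export
residue_hydrophobicity <- function(residue_name) {
  v <- unname(kyte_doolittle[toupper(residue_name)] / 4.5)
  if (anyNA(v)) {
    warning("unknown residue code(s): ",
            paste(unique(toupper(residue_name)[is.na(v)]), collapse = ", "),
            "; using 0")
    v[is.na(v)] <- 0
  }
  v
}

#' Distance-weighted hydrogen-bond potential at surface points
#'
#' A deliberately simple donor/acceptor surrogate without angular terms:
#' nitrogen atoms act as donors (+), oxygens as acceptors (-). Each class
#' contributes `w = max(0, 1 - d/cutoff)` via its nearest atom of that class;
#' the two contributions are summed and clamped to `[-1, 1]`.
#'
#' @param points m x 3 matrix of surface positions (vertex normals are not
#'   used by this surrogate and may be omitted).
#' @param cloud an [atom_cloud()].
#' @param cutoff interaction cutoff in Angstrom (default 3.0).
#' @return numeric vector in `[-1, 1]`, 0 where no N/O lies within cutoff.
#' @export
hbond_potential <- function(points, cloud, cutoff = 3.0) {
  stopifnot(inherits(cloud, "atom_cloud"))
  if (cutoff <= 0) stop("cutoff must be positive")
  points <- rbind(points)
  contrib <- function(class_idx, sign) {
    if (length(class_idx) == 0) return(numeric(nrow(points)))
    nn <- knn(points, cloud$xyz[class_idx, , drop = FALSE], 1)
    sign * pmax(0, 1 - nn$dist[, 1] / cutoff)
  }
  codes <- cloud$element_codes
  val <- contrib(which(codes == 2L), +1) + contrib(which(codes == 3L), -1)
  pmin(1, pmax(-1, val))
}

#' Gather per-vertex chemical inputs from the k nearest atoms
#'
#' For each surface point this collects its `k` nearest atoms (directed
#' vertex <- atom structure, entries sorted by ascending distance) and builds
#' one record per atom: element one-hot (6), Fourier distance features
#' (`1 + 2(F+1)`), the hydrophobicity of the atom's residue (1), the point's
#' hydrogen-bond potential replicated per entry (1), plus the relative atom
#' position.
#'
#' @param points m x 3 matrix of surface positions (e.g. mesh vertices).
#' @param cloud an [atom_cloud()].
#' @param k number of atoms aggregated per point (default 16).
#' @param F Fourier order (default 4).
#' @param hbond_cutoff cutoff for [hbond_potential()].
#' @return list with `k`, `F`, `atom_idx` (m x k), `dist` (m x k),
#'   `features` ((m*k) x (8 + 2F + 3) matrix, rows grouped by point), and
#'   `rel_pos` ((m*k) x 3).
#' @export
gather_vertex_chem_inputs <- function(points, cloud, k = 16, F = 4,
                                      hbond_cutoff = 3.0) {
  stopifnot(inherits(cloud, "atom_cloud"))
  points <- rbind(points)
  m <- nrow(points)
  if (k > n_atoms(cloud)) stop("k exceeds the number of atoms")
  nn <- knn(points, cloud$xyz, k)
  flat <- as.vector(t(nn$idx))                      # m*k atom indices, point-major
  onehot <- encode_elements(cloud)[flat, , drop = FALSE]
  gam <- fourier_distance_features(as.vector(t(nn$dist)), F)
  hyd <- suppressWarnings(residue_hydrophobicity(cloud$residue_names))[flat]
  hb <- hbond_potential(points, cloud, hbond_cutoff)
  features <- cbind(onehot, gam, hydro = hyd, hbond = rep(hb, each = k))
  rel <- cloud$xyz[flat, , drop = FALSE] -
    points[rep(seq_len(m), each = k), , drop = FALSE]
  list(k = k, F = F, atom_idx = nn$idx, dist = nn$dist,
       features = unname(features), rel_pos = unname(rel),
       point_of_row = rep(seq_len(m), each = k))
}
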