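#' Fixed element palette used for one-hot atom typing
#'
#' Atom elements are categorised into carbon, nitrogen, oxygen, sulfur,
#' hydrogen, and a catch-all class for everything else (metals, selenium,
#' halogens, ...).
#'
#' @export
element_palette <- c("C", "N", "O", "S", "H", "other")

# Bondi van-der-Waals radii (Angstrom) for the palette
vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.10, other = 1.80)

#' Construct a validated atom cloud
#'
#' An `atom_cloud` is the container for the atomic point cloud of one protein
#' (or chain selection): ordered atom records with element symbols, residue
#' metadata, and coordinates in Angstrom.
#'
#' @param elements character vector of element symbols (e.g. `"C"`, `"SE"`).
#' @param xyz numeric matrix (n x 3) of coordinates in Angstrom.
#' @param atom_names atom name per record (e.g. `"CA"`); defaults to elements.
#' @param residue_names 3-letter residue codes; default `"UNK"`.
#' @param residue_seq integer residue sequence numbers; default `1:n`.
#' @param chain_ids chain identifier per atom; default `"A"`.
#' @return an object of class `atom_cloud`.
#' @export
atom_cloud <- function(elements, xyz, atom_names = NULL, residue_names = NULL,
                       residue_seq = NULL, chain_ids = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("xyz must have three columns")
  n <- nrow(xyz)
  if (n < 1) stop("an atom cloud needs at least one atom")
  elements <- toupper(as.character(elements))
  if (length(elements) != n) stop("elements and xyz disagree in length")
  if (any(!is.finite(xyz))) stop("atom coordinates must be finite")
  if (any(!nzchar(elements))) stop("element symbols must be non-empty")
  storage.mode(xyz) <- "double"
  dimnames(xyz) <- NULL
  cloud <- structure(list(
    elements = elements,
    atom_names = as.character(atom_names %||% elements),
    residue_names = toupper(as.character(residue_names %||% rep("UNK", n))),
    residue_seq = as.integer(residue_seq %||% seq_len(n)),
    chain_ids = as.character(chain_ids %||% rep("A", n)),
    xyz = xyz
  ), class = "atom_cloud")
  cloud$element_codes <- element_codes(cloud)
  cloud
}

#' @export
print.atom_cloud <- function(x, ...) {
  cat(sprintf("<atom_cloud> %d atoms, chains: %s\n", n_atoms(x),
              paste(sort(unique(x$chain_ids)), collapse = ", ")))
  tab <- table(factor(element_palette[x$element_codes], levels = element_palette))
  cat("  elements:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Number of atoms in a cloud
#' @param cloud an `atom_cloud`.
#' @export
n_atoms <- function(cloud) nrow(cloud$xyz)

# palette index per atom; anything outside {C,N,O,S,H} maps to "other"
element_codes <- function(cloud) {
  idx <- match(cloud$elements, element_palette[-6])
  idx[is.na(idx)] <- 6L
  idx
}

#' One-hot encode atom elements over the fixed palette
#'
#' @param cloud an `atom_cloud`.
#' @return an n x 6 matrix; each row has exactly one 1, columns follow
#'   [element_palette] (unknown elements land in `"other"`).
#' @export
encode_elements <- function(cloud) {
  stopifnot(inherits(cloud, "atom_cloud"))
  codes <- cloud$element_codes
  onehot <- matrix(0, n_atoms(cloud), length(element_palette),
                   dimnames = list(NULL, element_palette))
  onehot[cbind(seq_along(codes), codes)] <- 1
  onehot
}

#' Van-der-Waals radius per atom
#' @param cloud an `atom_cloud`.
#' @return numeric vector of radii in Angstrom (Bondi values per palette class).
#' @export
atom_radii <- function(cloud) {
  unname(vdw_radii[cloud$element_codes])
}

# element inference when the PDB element column is blank: strip digits, map
# unambiguous two-letter names (selenium, halogens, ...), else first letter.
# "CA"/"NA"/"CO" are left to the one-letter rule: in ATOM records those are
# protein atom names (alpha carbon etc.), not metals.
infer_element <- function(atom_name) {
  nm <- gsub("[^A-Z]", "", toupper(atom_name))
  known2 <- c("SE", "CL", "BR", "FE", "ZN", "MG", "MN", "CU")
  out <- substr(nm, 1, 1)
  hit2 <- nm %in% known2
  out[hit2] <- nm[hit2]
  out[!nzchar(out)] <- "C"
  out
}

#' Read a PDB file into an atom cloud
#'
#' Parses fixed-column ATOM records (HETATM and waters excluded by default),
#' restricts to the requested chains, and resolves alternate locations to the
#' highest-occupancy copy (first listed on ties). Elements come from the PDB
#' element column, with an atom-name heuristic as fallback.
#'
#' @param path path to a PDB file.
#' @param chains optional character vector of chain IDs to keep (all if NULL).
#' @param include_het if TRUE, non-water HETATM records are kept (typed from
#'   their element column, unknowns as `"other"`).
#' @return an [atom_cloud()].
#' @export
read_pdb <- function(path, chains = NULL, include_het = FALSE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  keep <- at$type == "ATOM"
  if (include_het) keep <- keep | (at$type == "HETATM" & at$resid != "HOH")
  at <- at[keep & at$resid != "HOH", , drop = FALSE]
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (nrow(at) == 0) {
    stop("no atoms left after filtering",
         if (!is.null(chains)) paste0(" (requested chains: ",
                                      paste(chains, collapse = ","), ")") else "")
  }
  # resolve altlocs: keep the highest-occupancy copy of each atom site,
  # first-listed on equal occupancy
  occ <- at$o
  occ[is.na(occ)] <- 1
  site <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(site, -occ, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE][!duplicated(site[ord]), , drop = FALSE]
  at <- at[order(as.integer(rownames(at))), , drop = FALSE]

  elem <- toupper(trimws(at$elesy %||% ""))
  miss <- is.na(elem) | !nzchar(elem)
  if (any(miss)) elem[miss] <- infer_element(at$elety[miss])
  atom_cloud(
    elements = elem,
    xyz = cbind(at$x, at$y, at$z),
    atom_names = at$elety,
    residue_names = at$resid,
    residue_seq = at$resno,
    chain_ids = at$chain
  )
}

#' Select chains from an atom cloud
#' @param cloud an `atom_cloud`.
#' @param chains character vector of chain IDs to keep.
#' @export
select_chains <- function(cloud, chains) {
  keep <- cloud$chain_ids %in% chains
  if (!any(keep)) stop("no atoms on chains: ", paste(chains, collapse = ","))
  atom_cloud(cloud$elements[keep], cloud$xyz[keep, , drop = FALSE],
             cloud$atom_names[keep], cloud$residue_names[keep],
             cloud$residue_seq[keep], cloud$chain_ids[keep])
}

#' Write an atom cloud as PDB ATOM records
#'
#' Fixed-width serialisation; coordinates at the format's 1e-3 Angstrom
#' precision. Used by the synthetic generator so fixtures travel through the
#' same parser as real structures.
#'
#' @param cloud an `atom_cloud`.
#' @param path output path.
#' @export
write_pdb <- function(cloud, path) {
  n <- n_atoms(cloud)
  el <- cloud$elements
  # fixed columns: name 13-16, altLoc 17, resName 18-20, chain 22, seq 23-26
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(n) %% 100000L,
    substr(cloud$atom_names, 1, 4),
    substr(cloud$residue_names, 1, 3),
    substr(cloud$chain_ids, 1, 1),
    cloud$residue_seq %% 10000L,
    cloud$xyz[, 1], cloud$xyz[, 2], cloud$xyz[, 3],
    1, 0, substr(el, 1, 2)
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' A pair of proteins to score for interaction
#' @param a,b `atom_cloud` objects.
#' @param id_a,id_b free-text identifiers.
#' @export
protein_pair <- function(a, b, id_a = "A", id_b = "B") {
  stopifnot(inherits(a, "atom_cloud"), inherits(b, "atom_cloud"))
  structure(list(a = a, b = b, id_a = id_a, id_b = id_b),
            class = "protein_pair")
}
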