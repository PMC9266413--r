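#' Configuration of the synthetic pseudo-protein generator
#'
#' The generator builds pairs of blob-like atom clouds whose interfaces are
#' complementary both geometrically (a bump on the "lock" matching a
#' depression on the "key") and chemically (hydrophobic residues concentrated
#' in the interface cap), with ground-truth interface atom sets.
#'
#' @param n_atoms atoms per protein (>= 20; default 300).
#' @param blob_radius nominal sphere radius in Angstrom (default 12).
#' @param cap_angle angular radius of the interface cap in radians (default
#'   0.9, about 52 degrees; must not exceed pi/2).
#' @param bump_height height of the lock's bump / depth of the key's
#'   depression in Angstrom (default 2.5).
#' @param hydro_correlation probability boost for hydrophobic residues inside
#'   the cap, in `[0, 1]` (default 0.7; 1 makes every cap residue
#'   hydrophobic).
#' @param noise_sd positional jitter in Angstrom (default 0.1, the coordinate
#'   uncertainty scale of high-resolution structures; it also keeps the posed
#'   interface gap within the labeling cutoff across the facet).
#' @param gap target surface-to-surface separation at the posed interface in
#'   Angstrom (default 1.0).
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_atoms = 300, blob_radius = 12, cap_angle = 0.9,
                         bump_height = 2.5, hydro_correlation = 0.7,
                         noise_sd = 0.1, gap = 1.0) {
  if (n_atoms < 20) stop("n_atoms must be at least 20")
  if (blob_radius <= 0) stop("blob_radius must be positive")
  if (cap_angle <= 0 || cap_angle > pi / 2) {
    stop("cap_angle must lie in (0, pi/2]: the cap cannot exceed a hemisphere")
  }
  if (hydro_correlation < 0 || hydro_correlation > 1) {
    stop("hydro_correlation must lie in [0, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (gap < 0) stop("gap must be non-negative")
  structure(list(n_atoms = n_atoms, blob_radius = blob_radius,
                 cap_angle = cap_angle, bump_height = bump_height,
                 hydro_correlation = hydro_correlation, noise_sd = noise_sd,
                 gap = gap), class = "synth_config")
}

hydrophobic_residues <- c("ILE", "VAL", "LEU", "PHE", "ALA", "MET")
polar_residues <- c("ARG", "LYS", "ASP", "GLU", "ASN", "GLN", "SER", "THR",
                    "HIS", "GLY")
synth_element_freq <- c(C = 0.62, N = 0.17, O = 0.20, S = 0.01)

# smooth radial bump profile: 1 at the cap centre, 0 at the rim
cap_profile <- function(angle, cap_angle) {
  ifelse(angle <= cap_angle, 0.5 * (1 + cos(pi * angle / cap_angle)), 0)
}

#' Generate one pseudo-protein blob
#'
#' Atoms are sampled on a jittered sphere, except inside the interface cap
#' (around +z), which is flattened to a planar facet at the cap-rim height;
#' on the facet, offsets along the facet normal create a central bump
#' (`role = "lock"`) or a matching depression (`role = "key"`). Two such
#' facets mate with a near-constant surface gap, so the planted interface is
#' an extended patch rather than a point tangency (real protein interfaces
#' are likewise locally flat). Each atom is its own pseudo-residue; cap
#' residues are drawn from the hydrophobic set with probability raised by
#' `hydro_correlation`, and elements follow a fixed C/N/O/S composition.
#' A deterministic interior carbon lattice (pseudo-glycine scaffold) fills
#' the blob so its molecular surface is a single outer sheet; `n_atoms`
#' counts the chemically meaningful surface atoms only.
#'
#' @param config a [synth_config()].
#' @param role `"lock"` or `"key"`.
#' @param seed RNG seed (identical seeds give identical clouds).
#' @param chain_id chain identifier written on the atoms.
#' @return list with the [atom_cloud()] (`cloud`), the ground-truth
#'   `interface` atom indices, and the cap axis (`c(0, 0, 1)` before posing).
#' @export
make_blob <- function(config = synth_config(), role = c("lock", "key"),
                      seed = 1, chain_id = "A") {
  stopifnot(inherits(config, "synth_config"))
  role <- match.arg(role)
  set.seed(seed)
  n <- config$n_atoms
  R <- config$blob_radius
  # uniform directions on the sphere
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  angle <- acos(pmin(pmax(u[, 3], -1), 1))
  sgn <- if (role == "lock") +1 else -1
  in_cap <- angle <= config$cap_angle
  eps <- rnorm(n, sd = config$noise_sd)
  radius <- R + eps
  xyz <- u * radius
  # facet: cap atoms at transverse distance R*sin(a) on the plane
  # z = R*cos(cap_angle), plus the bump/depression profile and jitter along z
  if (any(in_cap)) {
    t_ <- R * sin(angle[in_cap])
    phi <- atan2(u[in_cap, 2], u[in_cap, 1])
    zc <- R * cos(config$cap_angle) +
      sgn * config$bump_height * cap_profile(angle[in_cap], config$cap_angle) +
      eps[in_cap]
    xyz[in_cap, ] <- cbind(t_ * cos(phi), t_ * sin(phi), zc)
  }

  # deterministic interior scaffold: a carbon lattice fills the blob so the
  # isosurface has a single outer sheet (no artifact interior surface); the
  # scaffold stays clear of the facet/bump profile
  lat <- 2.6
  g <- seq(-R + lat, R - lat, by = lat)
  sc <- as.matrix(expand.grid(x = g, y = g, z = g))
  keep <- sqrt(rowSums(sc^2)) <= R - lat
  t_sc <- sqrt(sc[, 1]^2 + sc[, 2]^2)
  under_cap <- t_sc < R * sin(config$cap_angle)
  a_sc <- asin(pmin(t_sc / R, 1))
  facet_z <- R * cos(config$cap_angle) +
    sgn * config$bump_height * cap_profile(a_sc, config$cap_angle)
  keep <- keep & (!under_cap | sc[, 3] <= facet_z - 2.0)
  sc <- sc[keep, , drop = FALSE]
  n_sc <- nrow(sc)
  bg <- 0.35   # background hydrophobic fraction
  p_hydro <- ifelse(in_cap, bg + config$hydro_correlation * (1 - bg), bg)
  hydro <- runif(n) < p_hydro
  res <- character(n)
  res[hydro] <- sample(hydrophobic_residues, sum(hydro), replace = TRUE)
  res[!hydro] <- sample(polar_residues, sum(!hydro), replace = TRUE)
  elem <- sample(names(synth_element_freq), n, replace = TRUE,
                 prob = synth_element_freq)
  cloud <- atom_cloud(elements = c(elem, rep("C", n_sc)),
                      xyz = rbind(xyz, sc),
                      atom_names = c(elem, rep("C", n_sc)),
                      residue_names = c(res, rep("GLY", n_sc)),
                      residue_seq = seq_len(n + n_sc),
                      chain_ids = rep(chain_id, n + n_sc))
  list(cloud = cloud, interface = which(in_cap), n_surface = n,
       cap_axis = c(0, 0, 1), role = role, config = config)
}

rotation_x <- function(theta) {
  rbind(c(1, 0, 0), c(0, cos(theta), -sin(theta)), c(0, sin(theta), cos(theta)))
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

transform_cloud <- function(cloud, R, t) {
  atom_cloud(cloud$elements, cloud$xyz %*% t(R) +
               matrix(t, nrow(cloud$xyz), 3, byrow = TRUE),
             cloud$atom_names, cloud$residue_names, cloud$residue_seq,
             cloud$chain_ids)
}

#' Pose a lock/key blob pair into an interacting complex
#'
#' The key is flipped so its depression faces the lock's bump and placed so
#' the probe-inflated surfaces are separated by roughly `gap` across the cap;
#' a random global rigid motion is then applied to the posed pair. Poses with
#' atomic collisions (interatomic distance < 1.5 Angstrom) are re-drawn up to
#' 10 times.
#'
#' @param lock,key outputs of [make_blob()] with matching config.
#' @param gap target surface gap in Angstrom (defaults to the lock config's).
#' @param seed RNG seed for the azimuthal spin and the global motion.
#' @param probe_radius probe radius used to convert atom separation into the
#'   expected surface separation (default 1.4).
#' @return a `synth_pair`: `pair` ([protein_pair()]), ground-truth interface
#'   atom indices `interface_a` / `interface_b`, posed cap axes and blob
#'   centres, and the generation parameters.
#' @export
pose_pair <- function(lock, key, gap = NULL, seed = 1, probe_radius = 1.4) {
  cfg <- lock$config
  gap <- gap %||% cfg$gap
  # facets mate plane-to-plane: centre distance = both facet heights plus the
  # inflated atomic surfaces plus the target gap (carbon-dominated r_eff)
  r_eff <- 1.7
  D <- 2 * cfg$blob_radius * cos(cfg$cap_angle) + 2 * (r_eff + probe_radius) + gap
  for (attempt in seq_len(10)) {
    set.seed(derive_seed(seed, paste0("pose", attempt)))
    spin <- runif(1, 0, 2 * pi)
    Rz <- rbind(c(cos(spin), -sin(spin), 0), c(sin(spin), cos(spin), 0),
                c(0, 0, 1))
    Rkey <- rotation_x(pi) %*% Rz     # cap now faces -z, towards the lock
    key_posed <- transform_cloud(key$cloud, Rkey, c(0, 0, D))
    clash <- any(cpp_within_dist(lock$cloud$xyz, key_posed$xyz, 1.5))
    if (!clash) {
      Rg <- random_rotation()
      tg <- runif(3, -20, 20)
      a <- transform_cloud(lock$cloud, Rg, tg)
      b <- transform_cloud(key_posed, Rg, tg)
      sp <- structure(list(
        pair = protein_pair(a, b, "synthA", "synthB"),
        interface_a = lock$interface, interface_b = key$interface,
        cap_axis_a = as.vector(Rg %*% c(0, 0, 1)),
        cap_axis_b = as.vector(Rg %*% Rkey %*% c(0, 0, 1)),
        center_a = as.vector(Rg %*% c(0, 0, 0) + tg),
        center_b = as.vector(Rg %*% c(0, 0, D) + tg),
        gap = gap, config = cfg), class = "synth_pair")
      validate_synth_pair(sp, probe_radius)
      return(sp)
    }
  }
  stop("failed to pose the pair without atomic collisions after 10 attempts")
}

# ground-truth interface atoms must come close once posed: atomic surfaces
# (centre distance minus both vdW radii) within 2*probe + gap, plus jitter
validate_synth_pair <- function(sp, probe_radius = 1.4) {
  a <- sp$pair$a; b <- sp$pair$b
  ia <- sp$interface_a; ib <- sp$interface_b
  da <- a$xyz[ia, , drop = FALSE]
  db <- b$xyz[ib, , drop = FALSE]
  d2 <- outer(rowSums(da^2), rowSums(db^2), "+") - 2 * da %*% t(db)
  dmin <- sqrt(max(min(d2), 0))
  ra <- max(atom_radii(a)[ia]); rb <- max(atom_radii(b)[ib])
  slack <- 4 * sp$config$noise_sd + 0.5
  if (dmin - ra - rb > 2 * probe_radius + sp$gap + slack) {
    stop("posed interface atoms are too far apart; posing failed")
  }
  invisible(sp)
}

#' Generate a full synthetic pair in one call
#' @param config a [synth_config()].
#' @param seed RNG seed.
#' @export
make_synth_pair <- function(config = synth_config(), seed = 1) {
  lock <- make_blob(config, "lock", derive_seed(seed, "lock"), chain_id = "A")
  key <- make_blob(config, "key", derive_seed(seed, "key"), chain_id = "B")
  pose_pair(lock, key, config$gap, derive_seed(seed, "pose"))
}

#' Generate a synthetic dataset with a train/test split
#'
#' Independent pairs with an 80/20 split, deterministic under the seed. When
#' `dir` is given, each protein is serialised as a PDB file and a manifest
#' CSV (`pdb_path_a`, `chains_a`, `pdb_path_b`, `chains_b`, `split`) plus
#' ground-truth interface-atom sidecars are written.
#'
#' @param n_pairs number of pairs (>= 2).
#' @param config a [synth_config()].
#' @param seed RNG seed.
#' @param dir optional output directory.
#' @return list with `pairs` (list of `synth_pair`), `manifest` (data.frame),
#'   and the split indices `train` / `test`.
#' @export
make_dataset <- function(n_pairs, config = synth_config(), seed = 1,
                         dir = NULL) {
  if (n_pairs < 2) stop("n_pairs must be at least 2")
  pairs <- lapply(seq_len(n_pairs),
                  function(q) make_synth_pair(config, derive_seed(seed, paste0("dspair", q))))
  n_train <- floor(0.8 * n_pairs)
  split <- rep(c("train", "test"), c(n_train, n_pairs - n_train))
  manifest <- data.frame(
    pdb_path_a = sprintf("pair%03d_A.pdb", seq_len(n_pairs)),
    chains_a = "A",
    pdb_path_b = sprintf("pair%03d_B.pdb", seq_len(n_pairs)),
    chains_b = "B",
    split = split, stringsAsFactors = FALSE
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (q in seq_len(n_pairs)) {
      write_pdb(pairs[[q]]$pair$a, file.path(dir, manifest$pdb_path_a[q]))
      write_pdb(pairs[[q]]$pair$b, file.path(dir, manifest$pdb_path_b[q]))
      writeLines(c(paste(pairs[[q]]$interface_a, collapse = ","),
                   paste(pairs[[q]]$interface_b, collapse = ",")),
                 file.path(dir, sprintf("pair%03d_interface.txt", q)))
    }
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(pairs = pairs, manifest = manifest,
       train = which(split == "train"), test = which(split == "test"))
}

#' Analytic geometry fixtures
#'
#' Exact parametric meshes with analytic unit normals attached, used to test
#' normal and curvature estimation against closed forms.
#'
#' @param kind `"sphere"` (icosphere, `resolution` = subdivision rounds),
#'   `"plane"` (square grid of side `size` at z = 0), `"cylinder"` (radius
#'   `size`, height `2 * size`, open ends), or `"saddle"`
#'   (`z = (x^2 - y^2) / 2` over a square of side `size`).
#' @param size characteristic size in Angstrom (sphere/cylinder radius,
#'   plane/saddle side length).
#' @param resolution mesh resolution (>= 3); grid points per side for
#'   plane/saddle, subdivision rounds for the sphere, circumferential
#'   half-segments for the cylinder.
#' @return a [surface_mesh()] with analytic normals.
#' @export
analytic_fixture <- function(kind = c("sphere", "plane", "cylinder", "saddle"),
                             size = 1, resolution = 10) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("unknown fixture kind: ", kind[1]))
  if (resolution < 3) stop("resolution must be at least 3")
  switch(kind,
    sphere = icosphere(size, min(resolution, 6)),
    plane = grid_fixture(size, resolution, function(x, y) 0,
                         function(x, y) c(0, 0, 1)),
    saddle = grid_fixture(size, resolution, function(x, y) (x^2 - y^2) / 2,
                          function(x, y) c(-x, y, 1) / sqrt(1 + x^2 + y^2)),
    cylinder = cylinder_fixture(size, resolution)
  )
}

grid_fixture <- function(size, resolution, zfun, nfun) {
  xs <- seq(-size / 2, size / 2, length.out = resolution)
  g <- expand.grid(x = xs, y = xs)
  v <- cbind(g$x, g$y, mapply(zfun, g$x, g$y))
  nrm <- t(mapply(function(x, y) nfun(x, y), g$x, g$y))
  idx <- function(i, j) (j - 1L) * resolution + i
  f <- list()
  for (j in seq_len(resolution - 1)) {
    for (i in seq_len(resolution - 1)) {
      f[[length(f) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
      f[[length(f) + 1]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
    }
  }
  surface_mesh(v, do.call(rbind, f), nrm)
}

cylinder_fixture <- function(radius, resolution) {
  n_theta <- 2L * resolution
  n_z <- resolution
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  zs <- seq(-radius, radius, length.out = n_z)
  v <- NULL; nrm <- NULL
  for (z in zs) {
    v <- rbind(v, cbind(radius * cos(theta), radius * sin(theta), z))
    nrm <- rbind(nrm, cbind(cos(theta), sin(theta), 0))
  }
  idx <- function(i, j) (j - 1L) * n_theta + i   # i around, j along z
  f <- list()
  for (j in seq_len(n_z - 1)) {
    for (i in seq_len(n_theta)) {
      i2 <- if (i == n_theta) 1L else i + 1L
      f[[length(f) + 1]] <- c(idx(i, j), idx(i2, j), idx(i2, j + 1))
      f[[length(f) + 1]] <- c(idx(i, j), idx(i2, j + 1), idx(i, j + 1))
    }
  }
  surface_mesh(v, do.call(rbind, f), nrm)
}

icosphere <- function(radius, subdivisions) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- midcache[[key]]
      if (!is.null(hit)) return(hit)
      m <- vlist[[a]] + vlist[[b]]
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1]] <<- m
      id <- length(vlist)
      midcache[[key]] <- id
      id
    }
    nf <- matrix(0L, 0, 3)
    for (q in seq_len(nrow(f))) {
      a <- f[q, 1]; b <- f[q, 2]; c_ <- f[q, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  surface_mesh(v * radius, f, v)
}
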