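#' Full run configuration
#'
#' One declarative bundle of every tunable of the pipeline: surfacing,
#' featurisation, model dimensions, and training settings. Values are
#' validated against the module preconditions before any compute.
#'
#' @param ... named overrides of the defaults listed below.
#' @return a `run_config` list with fields: `spacing`, `probe_radius` (surface
#'   construction, Angstrom); `n_points` (surface points sampled per protein
#'   for the network stage); `k_atoms`, `F`, `hbond_cutoff` (chemical
#'   features); `k_geom` (curvature); `k_graph`, `chem_embed_dim`,
#'   `geom_embed_dim`, `conv_radius`, `n_conv_layers`, `hidden_dim`,
#'   `out_dim`, `frame` (network); `interface_cutoff`, `n_train_pairs`,
#'   `n_eval_pairs`, `lr`, `max_epochs`, `patience`, `val_fraction`
#'   (training and evaluation); `seed`.
#' @export
run_config <- function(...) {
  cfg <- list(
    spacing = 0.7, probe_radius = 1.4,
    n_points = 256,
    k_atoms = 16, F = 4, hbond_cutoff = 3.0,
    k_geom = 16,
    k_graph = 8, chem_embed_dim = 8, geom_embed_dim = 8,
    conv_radius = 12, n_conv_layers = 3, hidden_dim = 16, out_dim = 8,
    frame = "global",
    interface_cutoff = 1.4,
    n_train_pairs = 32, n_eval_pairs = 64,
    lr = 1e-3, max_epochs = 300, patience = 10, val_fraction = 0.1,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, over)
  with(cfg, {
    if (spacing <= 0) stop("config field 'spacing' must be positive")
    if (probe_radius < 0) stop("config field 'probe_radius' must be non-negative")
    if (n_points < 16) stop("config field 'n_points' must be at least 16")
    if (k_geom < 4) stop("config field 'k_geom' must be at least 4")
    if (interface_cutoff <= 0) stop("config field 'interface_cutoff' must be positive")
    if (lr <= 0) stop("config field 'lr' must be positive")
    if (max_epochs < 1 || patience < 1) stop("config fields 'max_epochs' and 'patience' must be >= 1")
    if (val_fraction <= 0 || val_fraction >= 1) stop("config field 'val_fraction' must be in (0,1)")
  })
  structure(cfg, class = "run_config")
}

#' Extract the model configuration from a run configuration
#' @param cfg a [run_config()].
#' @export
as_model_config <- function(cfg) {
  model_config(chem_embed_dim = cfg$chem_embed_dim,
               geom_embed_dim = cfg$geom_embed_dim,
               conv_radius = cfg$conv_radius,
               n_conv_layers = cfg$n_conv_layers,
               hidden_dim = cfg$hidden_dim, out_dim = cfg$out_dim,
               k_atoms = cfg$k_atoms, k_geom = cfg$k_geom,
               k_graph = cfg$k_graph, F = cfg$F, frame = cfg$frame)
}

#' Featurise a protein for the network stage
#'
#' Surfaces the atom cloud (unless a mesh is supplied), samples `n_points`
#' surface points, and assembles everything the network consumes: chemical
#' neighbour records, principal curvatures, the point-graph edges of the
#' chemical stream, and the radius-convolution edge list with kernel inputs.
#'
#' @param cloud an [atom_cloud()].
#' @param config a [run_config()].
#' @param seed seed for the surface-point subsample.
#' @param mesh optional precomputed [surface_mesh()].
#' @param indices optional explicit vertex indices to featurise (overrides
#'   the seeded subsample).
#' @return a featurised protein (`protein_features`): `points`, `normals`,
#'   `chem`, `curv`, `graph`, `edges_i`/`edges_j`, `K`, `mesh_indices`.
#' @export
featurize_protein <- function(cloud, config = run_config(), seed = 1,
                              mesh = NULL, indices = NULL) {
  stopifnot(inherits(cloud, "atom_cloud"))
  mesh <- mesh %||% surface_protein(cloud, config$spacing, config$probe_radius)
  nv <- nrow(mesh$vertices)
  if (is.null(indices)) {
    n_points <- min(config$n_points, nv)
    set.seed(derive_seed(seed, "subsample"))
    idx <- sort(sample.int(nv, n_points))
  } else {
    idx <- sort(as.integer(indices))
    if (min(idx) < 1 || max(idx) > nv) stop("indices out of range")
    n_points <- length(idx)
  }
  P <- mesh$vertices[idx, , drop = FALSE]
  N <- mesh$normals[idx, , drop = FALSE]
  chem <- gather_vertex_chem_inputs(P, cloud, min(config$k_atoms, n_atoms(cloud)),
                                    config$F, config$hbond_cutoff)
  # curvature on the subsampled point cloud: its k-NN scale tracks the
  # sampling density (a few Angstrom), the scale at which binding-relevant
  # shape lives; full-mesh k-NN at dense meshes would sit below the grid
  # resolution and measure discretisation noise instead
  curv <- point_cloud_curvatures(P, N, k_geom = min(config$k_geom,
                                                    n_points - 1L))
  graph <- knn(P, P, min(config$k_graph + 1L, n_points))$idx[, -1, drop = FALSE]
  e <- radius_edges(P, P, config$conv_radius)
  K <- conv_edge_features(P, N, e$i, e$j, config$conv_radius, config$frame)
  structure(list(points = P, normals = N, chem = chem,
                 curv = unclass(curv)[, 1:2, drop = FALSE], graph = graph,
                 edges_i = e$i, edges_j = e$j, K = K, mesh_indices = idx),
            class = "protein_features")
}

#' Prepare a protein pair for training and evaluation
#'
#' Surfaces both proteins, labels interface vertices on the full meshes at
#' the configured cutoff, featurises both sides, carries the labels to the
#' sampled points, and draws a balanced training item set.
#'
#' @param pair a [protein_pair()] (or a synthetic pair's `$pair`).
#' @param config a [run_config()].
#' @param seed base seed; sub-seeds are derived per stage.
#' @return a `prepared_pair`: `pf_a`, `pf_b`, `labels_a`, `labels_b`, `items`,
#'   plus the interface positive counts on the full meshes.
#' @export
prepare_pair <- function(pair, config = run_config(), seed = 1) {
  stopifnot(inherits(pair, "protein_pair"))
  mesh_a <- surface_protein(pair$a, config$spacing, config$probe_radius)
  mesh_b <- surface_protein(pair$b, config$spacing, config$probe_radius)
  lab <- label_interface(mesh_a, mesh_b, config$interface_cutoff)
  # seeded subsample with a guaranteed handful of interface vertices, so
  # sparse subsamples cannot lose the interface entirely
  pick_indices <- function(mesh, labels, tag) {
    nv <- nrow(mesh$vertices)
    n_points <- min(config$n_points, nv)
    set.seed(derive_seed(seed, tag))
    idx <- sort(sample.int(nv, n_points))
    pos <- which(labels == 1)
    want <- min(4L, length(pos))
    have <- sum(labels[idx] == 1)
    if (have < want) {
      resample <- function(x, n) x[sample.int(length(x), n)]
      add <- resample(setdiff(pos, idx), want - have)
      drop_from <- which(labels[idx] == 0)
      idx <- sort(c(idx[-resample(drop_from, length(add))], add))
    }
    idx
  }
  idx_a <- pick_indices(mesh_a, lab$a, "feat_a")
  idx_b <- pick_indices(mesh_b, lab$b, "feat_b")
  pf_a <- featurize_protein(pair$a, config, mesh = mesh_a, indices = idx_a)
  pf_b <- featurize_protein(pair$b, config, mesh = mesh_b, indices = idx_b)
  labels_a <- lab$a[pf_a$mesh_indices]
  labels_b <- lab$b[pf_b$mesh_indices]
  items <- sample_pairs(pf_a$points, pf_b$points, labels_a, labels_b,
                        config$n_train_pairs, derive_seed(seed, "items"))
  structure(list(pf_a = pf_a, pf_b = pf_b, labels_a = labels_a,
                 labels_b = labels_b, items = items,
                 n_pos_mesh = c(a = sum(lab$a), b = sum(lab$b)),
                 id_a = pair$id_a, id_b = pair$id_b),
            class = "prepared_pair")
}

#' Prepare a list of pairs
#' @param pairs list of [protein_pair()] objects.
#' @param config a [run_config()].
#' @param seed base seed.
#' @param verbose print progress.
#' @export
prepare_pairs <- function(pairs, config = run_config(), seed = 1,
                          verbose = FALSE) {
  lapply(seq_along(pairs), function(q) {
    if (verbose && q %% 20 == 1) message("preparing pair ", q, "/", length(pairs))
    prepare_pair(pairs[[q]], config, derive_seed(seed, paste0("pair", q)))
  })
}

#' Site-task items from prepared pairs
#'
#' Each prepared pair contributes its two proteins as independent site items
#' (featurised points plus interface labels).
#' @param prepared list of `prepared_pair` objects.
#' @export
site_items <- function(prepared) {
  out <- list()
  for (pp in prepared) {
    out <- c(out, list(list(pf = pp$pf_a, labels = pp$labels_a, id = pp$id_a),
                       list(pf = pp$pf_b, labels = pp$labels_b, id = pp$id_b)))
  }
  out
}

#' Score interface sites on a protein
#'
#' End-to-end path: surface, featurise, run the network, return per-point
#' site scores with the sampled point coordinates.
#'
#' @param state a trained `model_state`.
#' @param cloud an [atom_cloud()].
#' @param config a [run_config()].
#' @param seed subsampling seed.
#' @return data.frame with point coordinates and `score`.
#' @export
predict_sites <- function(state, cloud, config = run_config(), seed = 1) {
  pf <- featurize_protein(cloud, config, seed)
  sc <- site_head(forward_protein(state, pf)$out, state)
  data.frame(x = pf$points[, 1], y = pf$points[, 2], z = pf$points[, 3],
             score = sc)
}

#' Score the interaction of two proteins
#'
#' Featurises both proteins and reports the maximum and mean patch-pair
#' interaction score over the top-scoring site patches of each side, plus the
#' per-side site scores.
#'
#' @param state a trained `model_state`.
#' @param pair a [protein_pair()].
#' @param config a [run_config()].
#' @param seed subsampling seed.
#' @param n_top number of top site patches considered per protein.
#' @return list with `score` (max over patch pairings), `mean_top_score`, and
#'   the per-side site score data.frames.
#' @export
predict_interaction <- function(state, pair, config = run_config(), seed = 1,
                                n_top = 16) {
  pf_a <- featurize_protein(pair$a, config, derive_seed(seed, "feat_a"))
  pf_b <- featurize_protein(pair$b, config, derive_seed(seed, "feat_b"))
  ea <- forward_protein(state, pf_a)$out
  eb <- forward_protein(state, pf_b)$out
  sa <- site_head(ea, state)
  sb <- site_head(eb, state)
  ta <- order(sa, decreasing = TRUE)[seq_len(min(n_top, length(sa)))]
  tb <- order(sb, decreasing = TRUE)[seq_len(min(n_top, length(sb)))]
  grid <- expand.grid(ia = ta, ib = tb)
  ps <- interaction_head(ea[grid$ia, , drop = FALSE],
                         eb[grid$ib, , drop = FALSE], state)
  list(score = max(ps), mean_top_score = mean(ps),
       sites_a = data.frame(pf_a$points, score = sa),
       sites_b = data.frame(pf_b$points, score = sb))
}
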