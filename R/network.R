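#' Model configuration
#'
#' Dimensions and neighbourhood settings of the trainable pipeline. The
#' per-point output is fixed at 8 dimensions.
#'
#' @param chem_embed_dim width of the chemical embedding (default 8).
#' @param geom_embed_dim width of the curvature embedding (default 8).
#' @param conv_radius radius of the spatial convolution in Angstrom
#'   (default 12).
#' @param n_conv_layers number of radius-convolution layers (default 3).
#' @param hidden_dim width of hidden layers (default 16).
#' @param out_dim per-point output width; fixed at 8.
#' @param k_atoms atoms aggregated per surface point (default 16).
#' @param k_geom mesh neighbours for curvature estimation (default 16).
#' @param k_graph mesh k-NN edges of the vertex graph used by the chemical
#'   stream's graph-convolution layer (default 8).
#' @param F Fourier order of the distance features (default 4).
#' @param frame `"global"` feeds the kernel raw position/normal differences
#'   (translation- but not rotation-invariant); `"tangent"` resolves both in
#'   the receiving point's tangent plane with an edge-adapted in-plane axis,
#'   making every kernel input a rigid-motion invariant.
#' @return a `model_config` list.
#' @export
model_config <- function(chem_embed_dim = 8, geom_embed_dim = 8,
                         conv_radius = 12, n_conv_layers = 3, hidden_dim = 16,
                         out_dim = 8, k_atoms = 16, k_geom = 16, k_graph = 8,
                         F = 4, frame = c("global", "tangent")) {
  frame <- match.arg(frame)
  cfg <- list(chem_embed_dim = chem_embed_dim, geom_embed_dim = geom_embed_dim,
              conv_radius = conv_radius, n_conv_layers = n_conv_layers,
              hidden_dim = hidden_dim, out_dim = out_dim, k_atoms = k_atoms,
              k_geom = k_geom, k_graph = k_graph, F = F, frame = frame)
  dims <- unlist(cfg[1:10])
  if (any(dims < 1)) stop("all model dimensions must be >= 1")
  if (conv_radius <= 0) stop("conv_radius must be positive")
  if (out_dim != 8) stop("the per-point output dimension is fixed at 8")
  structure(cfg, class = "model_config")
}

chem_input_dim <- function(config) {
  6L + (1L + 2L * (config$F + 1L)) + 2L  # one-hot + gamma(d) + hydro + hbond
}

dense_init <- function(nin, nout, gain = sqrt(2)) {
  list(W = matrix(rnorm(nin * nout, sd = gain / sqrt(nin)), nin, nout),
       b = numeric(nout))
}

#' Initialise all trainable parameter blocks
#'
#' @param config a [model_config()].
#' @param seed RNG seed for the parameter draw.
#' @return a `model_state`: `config` plus the nested parameter tree (`params`)
#'   covering the atomic-input MLP, the chemical graph-convolution layer, the
#'   curvature MLP, the per-layer kernel/feature networks of the radius
#'   convolution, the final per-point MLP, and both prediction heads.
#' @export
init_model <- function(config = model_config(), seed = 1) {
  stopifnot(inherits(config, "model_config"))
  set.seed(seed)
  h <- config$hidden_dim
  ce <- config$chem_embed_dim
  ge <- config$geom_embed_dim
  fused <- ce + ge
  params <- list(
    chem = list(
      mlp1 = dense_init(chem_input_dim(config), h),
      mlp2 = dense_init(h, ce),
      gcn_self = dense_init(ce, ce),
      gcn_nb = dense_init(ce, ce)
    ),
    geom = list(
      mlp1 = dense_init(2, h),
      mlp2 = dense_init(h, ge, gain = 1)
    ),
    conv = lapply(seq_len(config$n_conv_layers), function(l) {
      din <- if (l == 1) fused else h
      list(kernel1 = dense_init(6, h, gain = 1),
           kernel2 = dense_init(h, 1, gain = 0.5),
           pre = dense_init(din, h),
           post = dense_init(h, h))
    }),
    final = list(mlp1 = dense_init(h, h),
                 mlp2 = dense_init(h, config$out_dim, gain = 1)),
    site = list(mlp1 = dense_init(config$out_dim, config$out_dim),
                mlp2 = dense_init(config$out_dim, 1, gain = 1)),
    inter = list(mlp1 = dense_init(2 * config$out_dim, h),
                 mlp2 = dense_init(h, 1, gain = 1))
  )
  structure(list(config = config, params = params, schema = "surfppi-model-1"),
            class = "model_state")
}

#' @export
print.model_state <- function(x, ...) {
  n <- sum(vapply(flatten_params(x$params), length, 1L))
  cat(sprintf("<model_state> %d parameters, %d conv layers, frame=%s\n",
              n, x$config$n_conv_layers, x$config$frame))
  invisible(x)
}

flatten_params <- function(tree, prefix = "") {
  if (is.numeric(tree)) return(setNames(list(tree), prefix))
  out <- list()
  for (nm in names(tree)) {
    out <- c(out, flatten_params(tree[[nm]],
                                 if (nzchar(prefix)) paste0(prefix, ".", nm) else nm))
  }
  out
}

# elementwise binary map over two identically shaped parameter trees
tree_map2 <- function(a, b, f) {
  if (is.numeric(a)) return(f(a, b))
  setNames(lapply(names(a), function(nm) tree_map2(a[[nm]], b[[nm]], f)), names(a))
}

tree_zero <- function(a) {
  if (is.numeric(a)) return(a * 0)
  lapply(a, tree_zero)
}

relu <- function(x) x * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-pmin(pmax(x, -30), 30)))

# rowsum over groups 1..n, returning a dense n-row matrix (zero rows for
# groups absent from `g`)
scatter_rowsum <- function(x, g, n) {
  acc <- rowsum(x, g)
  out <- matrix(0, n, ncol(x))
  out[as.integer(rownames(acc)), ] <- acc
  out
}

dense_fwd <- function(X, p) sweep(X %*% p$W, 2, p$b, "+")

dense_bwd <- function(X, p, dZ) {
  list(dX = dZ %*% t(p$W), g = list(W = crossprod(X, dZ), b = colSums(dZ)))
}

# ---- kernel edge features ---------------------------------------------------

# kernel input per directed edge (i <- j). Global mode: raw position and
# normal differences (positions pre-scaled by 1/radius for conditioning) —
# translation- but not rotation-invariant. Tangent mode: differences are
# expressed in the receiving point's tangent plane with the in-plane axis
# aligned to the edge direction (an edge-adapted gauge), so every component
# is a rigid-motion invariant: in-plane and normal parts of the position
# difference, and the normal difference resolved in that frame.
conv_edge_features <- function(points, normals, i, j, radius,
                               frame = "global") {
  dp <- points[j, , drop = FALSE] - points[i, , drop = FALSE]
  dn <- normals[j, , drop = FALSE] - normals[i, , drop = FALSE]
  if (frame == "global") return(cbind(dp / radius, dn))
  ni <- normals[i, , drop = FALSE]
  dpn <- rowSums(dp * ni)
  dp_plane <- dp - dpn * ni
  lp <- sqrt(rowSums(dp_plane^2))
  u <- dp_plane / ifelse(lp > 1e-9, lp, 1)
  # degenerate in-plane direction (self edges): deterministic axis-rule frame
  deg <- lp <= 1e-9
  if (any(deg)) {
    for (q in which(deg)) {
      nn <- ni[q, ] / sqrt(sum(ni[q, ]^2))
      u[q, ] <- build_tangent_frame(nn)$u
    }
  }
  v <- cbind(ni[, 2] * u[, 3] - ni[, 3] * u[, 2],
             ni[, 3] * u[, 1] - ni[, 1] * u[, 3],
             ni[, 1] * u[, 2] - ni[, 2] * u[, 1])
  cbind(lp / radius, dpn / radius,
        rowSums(dn * u), rowSums(dn * v), rowSums(dn * ni),
        sqrt(rowSums(dp^2)) / radius)
}

# ---- forward / backward -----------------------------------------------------

conv_stack_fwd <- function(params_conv, K, i, j, F0, n) {
  caches <- vector("list", length(params_conv))
  Fl <- F0
  for (l in seq_along(params_conv)) {
    p <- params_conv[[l]]
    A1 <- dense_fwd(K, p$kernel1); T1 <- tanh(A1)
    w <- dense_fwd(T1, p$kernel2)
    Zp <- dense_fwd(Fl, p$pre); P <- relu(Zp)
    S <- scatter_rowsum(P[j, , drop = FALSE] * as.vector(w), i, n)
    Zo <- dense_fwd(S, p$post); Fo <- relu(Zo)
    caches[[l]] <- list(Fin = Fl, A1 = A1, T1 = T1, w = w, Zp = Zp, P = P,
                        S = S, Zo = Zo)
    Fl <- Fo
  }
  list(out = Fl, caches = caches)
}

conv_stack_bwd <- function(params_conv, K, i, j, caches, dOut, n) {
  grads <- vector("list", length(params_conv))
  dFl <- dOut
  for (l in rev(seq_along(params_conv))) {
    p <- params_conv[[l]]
    ch <- caches[[l]]
    dZo <- dFl * (ch$Zo > 0)
    bpost <- dense_bwd(ch$S, p$post, dZo)
    dS <- bpost$dX
    dSi <- dS[i, , drop = FALSE]
    dw <- rowSums(ch$P[j, , drop = FALSE] * dSi)
    dPj <- dSi * as.vector(ch$w)
    dP <- scatter_rowsum(dPj, j, n)
    dZp <- dP * (ch$Zp > 0)
    bpre <- dense_bwd(ch$Fin, p$pre, dZp)
    bk2 <- dense_bwd(ch$T1, p$kernel2, matrix(dw, ncol = 1))
    dA1 <- bk2$dX * (1 - ch$T1^2)
    bk1 <- dense_bwd(K, p$kernel1, dA1)
    grads[[l]] <- list(kernel1 = bk1$g, kernel2 = bk2$g, pre = bpre$g,
                       post = bpost$g)
    dFl <- bpre$dX
  }
  list(grads = grads, dF0 = dFl)
}

#' Embed per-point chemistry from aggregated atomic records
#'
#' Each neighbour record is transformed by a two-layer MLP, mean-aggregated
#' over the k atoms of its point, and passed through one graph-convolution
#' layer over the point graph (learned linear maps of the self and
#' neighbour-mean terms, shared across points).
#'
#' @param chem output of [gather_vertex_chem_inputs()].
#' @param graph n x k_graph matrix of point-graph neighbour indices.
#' @param state a `model_state`.
#' @return n x chem_embed_dim matrix.
#' @export
embed_chemistry <- function(chem, graph, state) {
  chem_fwd(state$params$chem, chem, graph, nrow(graph))$out
}

chem_fwd <- function(pc, chem, graph, n) {
  k <- chem$k
  X <- chem$features
  Z1 <- dense_fwd(X, pc$mlp1); H1 <- relu(Z1)
  Z2 <- dense_fwd(H1, pc$mlp2); H2 <- relu(Z2)
  M <- rowsum(H2, chem$point_of_row) / k
  kg <- ncol(graph)
  gi <- as.vector(t(graph))
  NM <- scatter_rowsum(M[gi, , drop = FALSE], rep(seq_len(n), each = kg), n) / kg
  # one bias for the layer (carried by gcn_self; gcn_nb's stays zero)
  Zg <- sweep(M %*% pc$gcn_self$W + NM %*% pc$gcn_nb$W, 2, pc$gcn_self$b, "+")
  C <- relu(Zg)
  list(out = C, cache = list(X = X, Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2,
                             M = M, NM = NM, Zg = Zg, gi = gi, kg = kg, k = k))
}

chem_bwd <- function(pc, ch, dC, pof, n) {
  dZg <- dC * (ch$Zg > 0)
  bself <- dense_bwd(ch$M, pc$gcn_self, dZg)
  bnb <- dense_bwd(ch$NM, pc$gcn_nb, dZg)
  bnb$g$b <- bnb$g$b * 0  # the shared bias is carried by gcn_self only
  dM <- bself$dX +
    scatter_rowsum((bnb$dX / ch$kg)[rep(seq_len(n), each = ch$kg), , drop = FALSE],
                   ch$gi, n)
  dH2 <- dM[pof, , drop = FALSE] / ch$k
  dZ2 <- dH2 * (ch$Z2 > 0)
  b2 <- dense_bwd(ch$H1, pc$mlp2, dZ2)
  dZ1 <- b2$dX * (ch$Z1 > 0)
  b1 <- dense_bwd(ch$X, pc$mlp1, dZ1)
  list(mlp1 = b1$g, mlp2 = b2$g, gcn_self = bself$g, gcn_nb = bnb$g)
}

#' Embed principal curvatures
#'
#' Two-layer feed-forward map of `(k1, k2)` to the geometric embedding.
#'
#' @param curv n x 2 matrix of principal curvatures (1/Angstrom).
#' @param state a `model_state`.
#' @return n x geom_embed_dim matrix.
#' @export
embed_geometry <- function(curv, state) {
  if (any(!is.finite(curv))) stop("curvatures must be finite")
  geom_fwd(state$params$geom, curv)$out
}

geom_fwd <- function(pg, curv) {
  Z1 <- dense_fwd(curv, pg$mlp1); H1 <- relu(Z1)
  G <- dense_fwd(H1, pg$mlp2)
  list(out = G, cache = list(Q = curv, Z1 = Z1, H1 = H1))
}

geom_bwd <- function(pg, ch, dG) {
  b2 <- dense_bwd(ch$H1, pg$mlp2, dG)
  dZ1 <- b2$dX * (ch$Z1 > 0)
  b1 <- dense_bwd(ch$Q, pg$mlp1, dZ1)
  list(mlp1 = b1$g, mlp2 = b2$g)
}

#' Run a protein's features through the full per-point pipeline
#'
#' Chemical and geometric embeddings are fused by concatenation, passed
#' through the radius-convolution stack, and mapped by the final MLP to the
#' 8-dimensional per-point output.
#'
#' @param state a `model_state`.
#' @param pf a featurised protein from [featurize_protein()].
#' @param ablate `"none"`, `"chem"`, or `"geom"`: zero out one input stream
#'   (used for ablation studies).
#' @param with_cache keep intermediate activations for backpropagation.
#' @return list with `out` (n x 8 matrix) and, if requested, `cache`.
#' @export
forward_protein <- function(state, pf, ablate = "none", with_cache = FALSE) {
  p <- state$params
  n <- nrow(pf$points)
  if (ablate == "chem") {
    C <- matrix(0, n, state$config$chem_embed_dim)
    chem_cache <- NULL
  } else {
    cf <- chem_fwd(p$chem, pf$chem, pf$graph, n)
    C <- cf$out; chem_cache <- cf$cache
  }
  if (ablate == "geom") {
    G <- matrix(0, n, state$config$geom_embed_dim)
    geom_cache <- NULL
  } else {
    gf <- geom_fwd(p$geom, pf$curv)
    G <- gf$out; geom_cache <- gf$cache
  }
  F0 <- cbind(C, G)
  cs <- conv_stack_fwd(p$conv, pf$K, pf$edges_i, pf$edges_j, F0, n)
  Zf <- dense_fwd(cs$out, p$final$mlp1); Hf <- relu(Zf)
  E8 <- dense_fwd(Hf, p$final$mlp2)
  if (!with_cache) return(list(out = E8))
  list(out = E8,
       cache = list(chem = chem_cache, geom = geom_cache, conv = cs$caches,
                    conv_out = cs$out, Zf = Zf, Hf = Hf, ablate = ablate, n = n))
}

backward_protein <- function(state, pf, cache, dE8) {
  p <- state$params
  n <- cache$n
  ce <- state$config$chem_embed_dim
  bf2 <- dense_bwd(cache$Hf, p$final$mlp2, dE8)
  dZf <- bf2$dX * (cache$Zf > 0)
  bf1 <- dense_bwd(cache$conv_out, p$final$mlp1, dZf)
  cb <- conv_stack_bwd(p$conv, pf$K, pf$edges_i, pf$edges_j, cache$conv,
                       bf1$dX, n)
  dC <- cb$dF0[, seq_len(ce), drop = FALSE]
  dG <- cb$dF0[, -seq_len(ce), drop = FALSE]
  g_chem <- if (is.null(cache$chem)) tree_zero(p$chem) else
    chem_bwd(p$chem, cache$chem, dC, pf$chem$point_of_row, n)
  g_geom <- if (is.null(cache$geom)) tree_zero(p$geom) else
    geom_bwd(p$geom, cache$geom, dG)
  list(chem = g_chem, geom = g_geom, conv = cb$grads,
       final = list(mlp1 = bf1$g, mlp2 = bf2$g))
}

#' Spatial radius convolution over a point cloud
#'
#' For every point i, neighbours j within `radius` (self included) contribute
#' `w_ij * pre(f_j)`, where the scalar weight `w_ij` is a learned kernel
#' network applied to the position and normal differences of the pair; the
#' weighted sum is transformed by a per-layer post network. The stack is
#' applied `n_conv_layers` times with independent parameters.
#'
#' @param points V x 3 positions (Angstrom).
#' @param normals V x 3 unit normals.
#' @param feats V x d input features (d must match the first layer's width).
#' @param radius neighbourhood radius in Angstrom.
#' @param state a `model_state` (its `conv` blocks are used).
#' @return V x hidden_dim output features.
#' @export
radius_convolution <- function(points, normals, feats, radius, state) {
  points <- rbind(points); normals <- rbind(normals); feats <- rbind(feats)
  e <- radius_edges(points, points, radius)
  K <- conv_edge_features(points, normals, e$i, e$j, radius,
                          state$config$frame)
  conv_stack_fwd(state$params$conv, K, e$i, e$j, feats, nrow(points))$out
}

#' Per-point interface-site scores
#'
#' Feed-forward map of the 8-dimensional per-point vectors to one logit,
#' followed by the logistic function.
#'
#' @param embeddings n x 8 matrix of per-point outputs.
#' @param state a `model_state`.
#' @return numeric vector of scores strictly inside (0, 1).
#' @export
site_head <- function(embeddings, state) {
  site_fwd(state$params$site, rbind(embeddings))$p
}

site_fwd <- function(ps, E) {
  Z1 <- dense_fwd(E, ps$mlp1); H1 <- relu(Z1)
  logit <- dense_fwd(H1, ps$mlp2)
  list(p = as.vector(sigmoid(logit)), logit = as.vector(logit),
       cache = list(E = E, Z1 = Z1, H1 = H1))
}

site_bwd <- function(ps, ch, dlogit) {
  dlogit <- matrix(dlogit, ncol = 1)
  b2 <- dense_bwd(ch$H1, ps$mlp2, dlogit)
  dZ1 <- b2$dX * (ch$Z1 > 0)
  b1 <- dense_bwd(ch$E, ps$mlp1, dZ1)
  list(g = list(mlp1 = b1$g, mlp2 = b2$g), dE = b1$dX)
}

#' Interaction score of two surface patches
#'
#' Symmetric combination `[e_a + e_b, |e_a - e_b|]` fed to a feed-forward
#' block with logistic output, so the score is exactly invariant under
#' swapping the two proteins.
#'
#' @param embed_a,embed_b 8-vectors (or m x 8 matrices) of patch embeddings.
#' @param state a `model_state`.
#' @return score(s) in (0, 1).
#' @export
interaction_head <- function(embed_a, embed_b, state) {
  inter_fwd(state$params$inter, rbind(embed_a), rbind(embed_b))$p
}

inter_fwd <- function(pi_, EA, EB) {
  D <- EA - EB
  Z <- cbind(EA + EB, abs(D))
  Z1 <- dense_fwd(Z, pi_$mlp1); H1 <- relu(Z1)
  logit <- dense_fwd(H1, pi_$mlp2)
  list(p = as.vector(sigmoid(logit)), logit = as.vector(logit),
       cache = list(Z = Z, D = D, Z1 = Z1, H1 = H1))
}

inter_bwd <- function(pi_, ch, dlogit) {
  dlogit <- matrix(dlogit, ncol = 1)
  b2 <- dense_bwd(ch$H1, pi_$mlp2, dlogit)
  dZ1 <- b2$dX * (ch$Z1 > 0)
  b1 <- dense_bwd(ch$Z, pi_$mlp1, dZ1)
  d <- ncol(ch$D)
  dSum <- b1$dX[, seq_len(d), drop = FALSE]
  dAbs <- b1$dX[, d + seq_len(d), drop = FALSE]
  sg <- sign(ch$D)
  list(g = list(mlp1 = b1$g, mlp2 = b2$g),
       dEA = dSum + dAbs * sg, dEB = dSum - dAbs * sg)
}

#' Save / load a model state
#'
#' Single-archive serialisation with the configuration embedded and a schema
#' tag checked on load.
#'
#' @param state a `model_state`.
#' @param path file path (`.rds`).
#' @export
save_model <- function(state, path) {
  stopifnot(inherits(state, "model_state"))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  state <- readRDS(path)
  if (!inherits(state, "model_state") ||
      !identical(state$schema, "surfppi-model-1")) {
    stop("not a surfppi model archive (schema mismatch)")
  }
  state
}
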