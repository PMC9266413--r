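zero_params <- function(state) {
  state$params <- surfppi:::tree_zero(state$params)
  state
}

test_that("zero parameters give zero embeddings and 0.5 scores", {
  pp <- tiny_prepared_pair()
  st <- zero_params(tiny_model())
  C <- embed_chemistry(pp$pf_a$chem, pp$pf_a$graph, st)
  expect_true(all(C == 0))
  G <- embed_geometry(pp$pf_a$curv, st)
  expect_true(all(G == 0))
  fw <- forward_protein(st, pp$pf_a)
  expect_true(all(fw$out == 0))
  expect_equal(site_head(fw$out, st), rep(0.5, nrow(fw$out)))
})

test_that("chemical embedding is invariant to neighbour order and duplication", {
  pp <- tiny_prepared_pair()
  st <- tiny_model()
  pf <- pp$pf_a
  base <- embed_chemistry(pf$chem, pf$graph, st)
  # permute the k records of every vertex
  k <- pf$chem$k
  n <- nrow(pf$points)
  set.seed(2)
  perm_rows <- unlist(lapply(seq_len(n), function(v) (v - 1) * k + sample(k)))
  chem_p <- pf$chem
  chem_p$features <- chem_p$features[perm_rows, ]
  expect_lt(max(abs(embed_chemistry(chem_p, pf$graph, st) - base)), 1e-6)
  # duplicate every record (k -> 2k): mean aggregation unchanged
  chem_d <- pf$chem
  dup_rows <- unlist(lapply(seq_len(n), function(v) {
    rep((v - 1) * k + seq_len(k), 2)
  }))
  chem_d$features <- chem_d$features[dup_rows, ]
  chem_d$k <- 2L * k
  chem_d$point_of_row <- rep(seq_len(n), each = 2L * k)
  expect_lt(max(abs(embed_chemistry(chem_d, pf$graph, st) - base)), 1e-6)
})

test_that("the curvature embedding is a pure finite function of (k1, k2)", {
  st <- tiny_model()
  curv <- rbind(c(0.1, 0.4), c(-0.3, 0.2), c(0.1, 0.4))
  G <- embed_geometry(curv, st)
  expect_equal(G[1, ], G[3, ])
  extreme <- embed_geometry(rbind(c(-10, 10), c(10, 10)), st)
  expect_true(all(is.finite(extreme)))
  expect_error(embed_geometry(rbind(c(NaN, 0)), st), "finite")
})

test_that("radius convolution matches a dense masked-sum reference", {
  set.seed(14)
  n <- 50
  pts <- matrix(runif(3 * n, 0, 6), n, 3)
  nrm <- matrix(rnorm(3 * n), n, 3)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  st <- tiny_model()
  feats <- matrix(rnorm(n * 16), n, 16)
  out <- radius_convolution(pts, nrm, feats, 3.5, st)
  ref <- dense_conv_reference(st, pts, nrm, feats, 3.5)
  expect_lt(max(abs(out - ref)), 1e-5)
})

test_that("radius convolution is translation invariant and handles isolation", {
  set.seed(15)
  n <- 30
  pts <- matrix(runif(3 * n, 0, 8), n, 3)
  nrm <- matrix(rnorm(3 * n), n, 3)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  st <- tiny_model()
  feats <- matrix(rnorm(n * 16), n, 16)
  a <- radius_convolution(pts, nrm, feats, 4, st)
  b <- radius_convolution(sweep(pts, 2, c(100, -50, 3), "+"), nrm, feats, 4, st)
  expect_lt(max(abs(a - b)), 1e-5)
  # a single isolated point reduces to its self term
  one <- radius_convolution(matrix(0, 1, 3), matrix(c(0, 0, 1), 1, 3),
                            feats[1, , drop = FALSE], 4, st)
  ref <- dense_conv_reference(st, matrix(0, 1, 3), matrix(c(0, 0, 1), 1, 3),
                              feats[1, , drop = FALSE], 4)
  expect_lt(max(abs(one - ref)), 1e-10)
})

test_that("site head scores are monotone logistic outputs in (0,1)", {
  st <- tiny_model()
  E <- matrix(rnorm(200 * 8), 200, 8)
  p <- site_head(E, st)
  expect_true(all(p > 0 & p < 1))
  hd <- surfppi:::site_fwd(st$params$site, E)
  expect_equal(order(hd$logit), order(hd$p))
  expect_equal(p[order(hd$logit)], sort(p))
})

test_that("the interaction head is exactly symmetric in its arguments", {
  st <- tiny_model()
  set.seed(4)
  EA <- matrix(rnorm(40 * 8), 40, 8)
  EB <- matrix(rnorm(40 * 8), 40, 8)
  expect_equal(interaction_head(EA, EB, st), interaction_head(EB, EA, st),
               tolerance = 1e-12)
  p <- interaction_head(EA, EB, st)
  expect_true(all(p > 0 & p < 1))
  # equal embeddings zero the |difference| block
  hd <- surfppi:::inter_fwd(st$params$inter, EA, EA)
  expect_true(all(hd$cache$Z[, 9:16] == 0))
})

test_that("vertex reindexing permutes outputs without value changes", {
  pp <- tiny_prepared_pair()
  st <- tiny_model()
  pf <- pp$pf_a
  base <- forward_protein(st, pf)$out
  n <- nrow(pf$points)
  set.seed(8)
  perm <- sample(n)            # new index of old vertex i is inv[i]
  inv <- integer(n); inv[perm] <- seq_len(n)
  k <- pf$chem$k
  rows <- unlist(lapply(perm, function(v) (v - 1) * k + seq_len(k)))
  pf2 <- pf
  pf2$points <- pf$points[perm, ]
  pf2$normals <- pf$normals[perm, ]
  pf2$curv <- pf$curv[perm, ]
  pf2$chem$features <- pf$chem$features[rows, ]
  pf2$chem$point_of_row <- rep(seq_len(n), each = k)
  pf2$graph <- matrix(inv[pf$graph[perm, ]], n)
  ord <- order(inv[pf$edges_i], inv[pf$edges_j])
  pf2$edges_i <- inv[pf$edges_i][ord]
  pf2$edges_j <- inv[pf$edges_j][ord]
  pf2$K <- pf$K[ord, ]
  out2 <- forward_protein(st, pf2)$out
  expect_lt(max(abs(out2[inv, ] - base)), 1e-6)
})

test_that("forward passes are bit-stable across repeated evaluation", {
  pp <- tiny_prepared_pair()
  st <- tiny_model()
  a <- forward_protein(st, pp$pf_a)$out
  b <- forward_protein(st, pp$pf_a)$out
  expect_identical(a, b)
})

test_that("model states serialise with a checked schema", {
  st <- tiny_model()
  path <- tempfile(fileext = ".rds")
  save_model(st, path)
  back <- load_model(path)
  expect_equal(back$params, st$params)
  saveRDS(list(1), path)
  expect_error(load_model(path), "schema")
})

test_that("tangent-frame kernels make the pipeline rotation invariant", {
  cfg <- tiny_run_config()
  cfg$frame <- "tangent"
  sp <- make_synth_pair(tiny_synth_config(), seed = 31)
  mesh <- surface_protein(sp$pair$a, cfg$spacing, cfg$probe_radius)
  pf <- featurize_protein(sp$pair$a, cfg, seed = 2, mesh = mesh)
  st <- init_model(as_model_config(cfg), seed = 9)
  base <- forward_protein(st, pf)$out
  set.seed(21)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  pf2 <- pf
  pf2$points <- pf$points %*% t(R)
  pf2$normals <- pf$normals %*% t(R)
  pf2$K <- surfppi:::conv_edge_features(pf2$points, pf2$normals, pf$edges_i,
                                        pf$edges_j, cfg$conv_radius, "tangent")
  out2 <- forward_protein(st, pf2)$out
  expect_lt(max(abs(out2 - base)), 1e-6)
})
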