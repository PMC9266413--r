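# shared fixtures, built once per test run and memoised here
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# a small but fully functional synthetic complex + run config, shared by the
# network / training unit tests
tiny_synth_config <- function() synth_config(n_atoms = 120, blob_radius = 8)

tiny_run_config <- function() {
  run_config(n_points = 48, k_atoms = 8, k_geom = 8, conv_radius = 6,
             k_graph = 4)
}

tiny_prepared_pair <- function() {
  fixture("tiny_pair", function() {
    sp <- make_synth_pair(tiny_synth_config(), seed = 3)
    prepare_pair(sp$pair, tiny_run_config(), seed = 5)
  })
}

tiny_model <- function(seed = 9) {
  init_model(as_model_config(tiny_run_config()), seed = seed)
}

# small list of prepared pairs for training smoke tests
tiny_dataset <- function() {
  fixture("tiny_dataset", function() {
    cfg <- tiny_run_config()
    lapply(1:8, function(q) {
      sp <- make_synth_pair(tiny_synth_config(), seed = 100 + q)
      prepare_pair(sp$pair, cfg, seed = 200 + q)
    })
  })
}

# fixed-width PDB ATOM line
pdb_line <- function(serial, name, alt = " ", res = "ALA", chain = "A",
                     resno = 1, x = 0, y = 0, z = 0, occ = 1, elem = "C") {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, res, chain, resno, x, y, z, occ, 0, elem)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# connected components of a mesh from its face edges (union-find)
mesh_n_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  f <- mesh$faces
  for (e in list(f[, 1:2], f[, 2:3])) {
    for (q in seq_len(nrow(e))) {
      a <- find(e[q, 1]); b <- find(e[q, 2])
      if (a != b) parent[a] <- b
    }
  }
  length(unique(vapply(seq_len(n), find, 1L)))
}

# dense O(V^2) reference for the radius-convolution stack: same parameters,
# explicit masked weight matrix, plain summation
dense_conv_reference <- function(state, points, normals, feats, radius) {
  n <- nrow(points)
  Fl <- feats
  for (p in state$params$conv) {
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        d <- points[j, ] - points[i, ]
        if (sqrt(sum(d^2)) <= radius) {
          k_in <- c(d / radius, normals[j, ] - normals[i, ])
          h <- tanh(k_in %*% p$kernel1$W + p$kernel1$b)
          W[i, j] <- h %*% p$kernel2$W + p$kernel2$b
        }
      }
    }
    P <- pmax(sweep(Fl %*% p$pre$W, 2, p$pre$b, "+"), 0)
    S <- W %*% P
    Fl <- pmax(sweep(S %*% p$post$W, 2, p$post$b, "+"), 0)
  }
  Fl
}

# brute-force AUROC by counting ordered positive-negative pairs
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}
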