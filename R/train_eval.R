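#' Label interface vertices of two surfaces
#'
#' A vertex of one surface is an interface vertex (label 1) when its distance
#' to the nearest vertex of the partner surface is at most `cutoff`.
#'
#' @param mesh_a,mesh_b [surface_mesh()] objects, or plain V x 3 vertex
#'   matrices.
#' @param cutoff interface distance cutoff in Angstrom (default 1.4).
#' @return list with integer 0/1 vectors `a` and `b`.
#' @export
label_interface <- function(mesh_a, mesh_b, cutoff = 1.4) {
  va <- if (inherits(mesh_a, "surface_mesh")) mesh_a$vertices else rbind(mesh_a)
  vb <- if (inherits(mesh_b, "surface_mesh")) mesh_b$vertices else rbind(mesh_b)
  list(a = as.integer(cpp_within_dist(va, vb, cutoff)),
       b = as.integer(cpp_within_dist(vb, va, cutoff)))
}

#' Sample a balanced set of patch pairs from two labelled point sets
#'
#' Positive items pair an interface point of A with its nearest interface
#' point of B; negative items are uniform point pairs constrained to contain
#' at least one non-interface member. Exactly `n_pairs / 2` of each are drawn.
#'
#' @param points_a,points_b point coordinate matrices.
#' @param labels_a,labels_b 0/1 interface labels per point.
#' @param n_pairs even total number of items.
#' @param seed RNG seed; identical seeds yield identical item lists.
#' @return data.frame with columns `ia`, `ib`, `label`.
#' @export
sample_pairs <- function(points_a, points_b, labels_a, labels_b, n_pairs,
                         seed = 1) {
  if (n_pairs %% 2 != 0 || n_pairs < 2) stop("n_pairs must be a positive even number")
  pos_a <- which(labels_a == 1)
  pos_b <- which(labels_b == 1)
  if (length(pos_a) == 0 || length(pos_b) == 0) {
    stop("cannot sample positive patch pairs: a protein has no interface vertices")
  }
  set.seed(seed)
  half <- n_pairs / 2L
  ia <- sample(pos_a, half, replace = length(pos_a) < half)
  nn <- knn(rbind(points_a)[ia, , drop = FALSE],
            rbind(points_b)[pos_b, , drop = FALSE], 1)
  ib <- pos_b[nn$idx[, 1]]
  pos <- data.frame(ia = ia, ib = ib, label = 1L)
  na <- nrow(rbind(points_a)); nb <- nrow(rbind(points_b))
  neg <- data.frame(ia = integer(0), ib = integer(0), label = integer(0))
  while (nrow(neg) < half) {
    m <- 2L * (half - nrow(neg)) + 4L
    ca <- sample.int(na, m, replace = TRUE)
    cb <- sample.int(nb, m, replace = TRUE)
    ok <- !(labels_a[ca] == 1 & labels_b[cb] == 1)
    neg <- rbind(neg, data.frame(ia = ca[ok], ib = cb[ok], label = 0L))
  }
  rbind(pos, utils::head(neg, half))
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation: the probability that a random positive outscores
#' a random negative, with ties credited 1/2.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (at least one of each class).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUROC undefined: need at least one positive and one negative label")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion matrix at a score threshold
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @param threshold classification threshold (default 0.5).
#' @return named vector `c(TP, FP, TN, FN)`.
#' @export
confusion_matrix <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  labels <- as.integer(labels)
  c(TP = sum(pred == 1 & labels == 1), FP = sum(pred == 1 & labels == 0),
    TN = sum(pred == 0 & labels == 0), FN = sum(pred == 0 & labels == 1))
}

# ---- losses -----------------------------------------------------------------

bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

# d(loss)/d(logit) for mean BCE through a logistic output
bce_dlogit <- function(p, y) (p - y) / length(y)

site_item_pass <- function(state, item, ablate, with_grad) {
  fw <- forward_protein(state, item$pf, ablate, with_cache = with_grad)
  hd <- site_fwd(state$params$site, fw$out)
  y <- item$labels
  loss <- bce_loss(hd$p, y)
  if (!with_grad) return(list(loss = loss, scores = hd$p))
  sb <- site_bwd(state$params$site, hd$cache, bce_dlogit(hd$p, y))
  gb <- backward_protein(state, item$pf, fw$cache, sb$dE)
  grads <- list(chem = gb$chem, geom = gb$geom, conv = gb$conv,
                final = gb$final, site = sb$g,
                inter = tree_zero(state$params$inter))
  list(loss = loss, scores = hd$p, grads = grads)
}

inter_pair_pass <- function(state, pair, ablate, with_grad, items = NULL) {
  items <- items %||% pair$items
  fa <- forward_protein(state, pair$pf_a, ablate, with_cache = with_grad)
  fb <- forward_protein(state, pair$pf_b, ablate, with_cache = with_grad)
  EA <- fa$out[items$ia, , drop = FALSE]
  EB <- fb$out[items$ib, , drop = FALSE]
  hd <- inter_fwd(state$params$inter, EA, EB)
  y <- items$label
  loss <- bce_loss(hd$p, y)
  if (!with_grad) return(list(loss = loss, scores = hd$p))
  ib <- inter_bwd(state$params$inter, hd$cache, bce_dlogit(hd$p, y))
  dE8a <- scatter_rowsum(ib$dEA, items$ia, nrow(fa$out))
  dE8b <- scatter_rowsum(ib$dEB, items$ib, nrow(fb$out))
  ga <- backward_protein(state, pair$pf_a, fa$cache, dE8a)
  gb <- backward_protein(state, pair$pf_b, fb$cache, dE8b)
  shared <- tree_map2(list(chem = ga$chem, geom = ga$geom, conv = ga$conv,
                           final = ga$final),
                      list(chem = gb$chem, geom = gb$geom, conv = gb$conv,
                           final = gb$final), `+`)
  grads <- c(shared, list(site = tree_zero(state$params$site), inter = ib$g))
  list(loss = loss, scores = hd$p, grads = grads)
}

# ---- AMSGrad ----------------------------------------------------------------

amsgrad_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), vhat = tree_zero(params),
       t = 0L)
}

amsgrad_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- tree_map2(opt$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  opt$v <- tree_map2(opt$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  opt$vhat <- tree_map2(opt$vhat, opt$v, pmax)
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  step <- tree_map2(opt$m, opt$vhat, function(m, vh) {
    lr * (m / bc1) / (sqrt(vh / bc2) + eps)
  })
  list(params = tree_map2(params, step, `-`), opt = opt)
}

# ---- training loop ----------------------------------------------------------

#' Train the site or interaction model
#'
#' Minimises mean binary cross-entropy with the AMSGrad variant of Adam,
#' one gradient step per item (protein for the site task, protein pair for
#' the interaction task). A seeded 10% split of the items is held out for
#' validation; training stops when the validation loss has not improved for
#' `patience` consecutive epochs, and the parameters of the best-validation
#' epoch are returned.
#'
#' @param dataset for `task = "site"`: a list of items, each with `pf`
#'   (featurised protein) and `labels`; for `task = "interaction"`: a list of
#'   prepared pairs with `pf_a`, `pf_b`, and an `items` data.frame from
#'   [sample_pairs()].
#' @param task `"site"` or `"interaction"`.
#' @param config a [model_config()].
#' @param seed RNG seed controlling initialisation, the validation split, and
#'   item order.
#' @param lr learning rate (default 1e-3).
#' @param max_epochs epoch cap (default 300).
#' @param patience early-stopping patience in epochs (default 10).
#' @param val_fraction validation fraction of the items (default 0.1).
#' @param ablate `"none"`, `"chem"`, or `"geom"` (zero one input stream).
#' @param shuffle_labels permute the training labels (negative-control runs).
#' @param state optional warm-start `model_state`.
#' @param verbose print per-epoch progress.
#' @return list with the trained `state`, the per-epoch `log` (data.frame with
#'   training loss, validation loss, validation AUROC), `best_epoch`,
#'   `stopped_epoch`, and `seed`.
#' @export
train_model <- function(dataset, task = c("site", "interaction"),
                        config = model_config(), seed = 1, lr = 1e-3,
                        max_epochs = 300, patience = 10, val_fraction = 0.1,
                        ablate = "none", shuffle_labels = FALSE, state = NULL,
                        verbose = FALSE) {
  task <- match.arg(task)
  if (length(dataset) < 2) stop("dataset must contain at least two items")
  state <- state %||% init_model(config, derive_seed(seed, "init"))
  pass <- if (task == "site") site_item_pass else inter_pair_pass

  if (shuffle_labels) {
    set.seed(derive_seed(seed, "shuffle"))
    dataset <- lapply(dataset, function(it) {
      if (task == "site") it$labels <- sample(it$labels)
      else it$items$label <- sample(it$items$label)
      it
    })
  }

  set.seed(derive_seed(seed, "split"))
  n <- length(dataset)
  n_val <- max(1L, round(val_fraction * n))
  val_idx <- sort(sample.int(n, n_val))
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(train_idx) == 0) stop("validation split consumed all items")

  eval_items <- function(st, idx) {
    scores <- c(); labels <- c(); losses <- numeric(0)
    for (i in idx) {
      r <- pass(st, dataset[[i]], ablate, with_grad = FALSE)
      losses <- c(losses, r$loss)
      scores <- c(scores, r$scores)
      labels <- c(labels, if (task == "site") dataset[[i]]$labels
                  else dataset[[i]]$items$label)
    }
    au <- if (length(unique(labels)) == 2) auroc(scores, labels) else NA_real_
    list(loss = mean(losses), auroc = au)
  }

  opt <- amsgrad_init(state$params)
  best <- list(loss = Inf, epoch = 0L, params = state$params)
  bad_epochs <- 0L
  log <- data.frame()
  stopped_epoch <- max_epochs
  for (epoch in seq_len(max_epochs)) {
    set.seed(derive_seed(seed, paste0("epoch", epoch)))
    order_idx <- sample(train_idx)
    train_losses <- numeric(length(order_idx))
    for (q in seq_along(order_idx)) {
      r <- pass(state, dataset[[order_idx[q]]], ablate, with_grad = TRUE)
      if (!is.finite(r$loss)) {
        stop(sprintf("training diverged (non-finite loss at epoch %d)", epoch))
      }
      train_losses[q] <- r$loss
      upd <- amsgrad_step(state$params, r$grads, opt, lr)
      state$params <- upd$params
      opt <- upd$opt
    }
    vl <- eval_items(state, val_idx)
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_loss = mean(train_losses),
                                 val_loss = vl$loss, val_auroc = vl$auroc))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  val-AUROC %s", epoch,
                      mean(train_losses), vl$loss,
                      ifelse(is.na(vl$auroc), "NA", sprintf("%.3f", vl$auroc))))
    }
    if (vl$loss < best$loss) {
      best <- list(loss = vl$loss, epoch = epoch, params = state$params)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= patience) { stopped_epoch <- epoch; break }
    }
    stopped_epoch <- epoch
  }
  state$params <- best$params
  list(state = state, log = log, best_epoch = best$epoch,
       stopped_epoch = stopped_epoch, seed = seed)
}

#' Evaluate the interaction model on one prepared pair
#'
#' Draws a balanced item sample with [sample_pairs()], scores it with the
#' interaction head, and reports AUROC plus the confusion matrix at
#' threshold 0.5.
#'
#' @param state a trained `model_state`.
#' @param pair a prepared pair (see [prepare_pair()]).
#' @param n_eval_pairs number of items to draw (default 64).
#' @param seed sampling seed.
#' @param ablate stream ablation flag passed to the forward pass.
#' @return one-row data.frame with `auroc`, `TP`, `FP`, `TN`, `FN`, `n_items`.
#' @export
evaluate_pair <- function(state, pair, n_eval_pairs = 64, seed = 1,
                          ablate = "none") {
  items <- sample_pairs(pair$pf_a$points, pair$pf_b$points, pair$labels_a,
                        pair$labels_b, n_eval_pairs, seed)
  r <- inter_pair_pass(state, pair, ablate, with_grad = FALSE, items = items)
  cm <- confusion_matrix(r$scores, items$label)
  data.frame(auroc = auroc(r$scores, items$label), TP = cm["TP"], FP = cm["FP"],
             TN = cm["TN"], FN = cm["FN"], n_items = nrow(items),
             row.names = NULL)
}

#' Evaluate the interaction model over a list of prepared pairs
#'
#' @param state a trained `model_state`.
#' @param pairs list of prepared pairs.
#' @param n_eval_pairs items per pair.
#' @param seed base seed (per-pair seeds are derived from it).
#' @param ablate stream ablation flag.
#' @return list with `per_pair` (data.frame, one row per pair) and
#'   `mean_auroc`.
#' @export
evaluate_dataset <- function(state, pairs, n_eval_pairs = 64, seed = 1,
                             ablate = "none") {
  rows <- lapply(seq_along(pairs), function(q) {
    evaluate_pair(state, pairs[[q]], n_eval_pairs,
                  derive_seed(seed, paste0("eval", q)), ablate)
  })
  per_pair <- do.call(rbind, rows)
  per_pair$pair <- seq_along(pairs)
  list(per_pair = per_pair, mean_auroc = mean(per_pair$auroc))
}

#' Evaluate site predictions over featurised proteins
#'
#' Scores every sampled surface point of each protein and reports the
#' per-protein AUROC of the interface labels plus their mean.
#'
#' @param state a trained `model_state`.
#' @param items list of site items (`pf` + `labels`).
#' @param ablate stream ablation flag.
#' @return list with `per_protein` AUROC vector and `mean_auroc`.
#' @export
evaluate_sites <- function(state, items, ablate = "none") {
  per <- vapply(items, function(it) {
    r <- site_item_pass(state, it, ablate, with_grad = FALSE)
    if (length(unique(it$labels)) < 2) return(NA_real_)
    auroc(r$scores, it$labels)
  }, 1.0)
  list(per_protein = per, mean_auroc = mean(per, na.rm = TRUE))
}
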