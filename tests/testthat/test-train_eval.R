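test_that("interface labels follow the distance cutoff", {
  g <- as.matrix(expand.grid(x = 0:3, y = 0:3))
  a <- cbind(g, 0)
  b_near <- cbind(g, 1.0)
  lab <- label_interface(a, b_near)
  expect_true(all(lab$a == 1))
  expect_true(all(lab$b == 1))
  b_far <- cbind(g, 2.0)
  lab2 <- label_interface(a, b_far)
  expect_true(all(lab2$a == 0))
  # symmetric in its arguments
  expect_equal(label_interface(b_near, a)$a, lab$b)
})

test_that("a hand-built staircase fixture labels exactly the close vertices", {
  # A: ten vertices along x at increasing height above the plane z = 0;
  # hand-computed: vertices with z in {0.4, 0.8, 1.2} are within 1.4 of B
  a <- cbind(seq(0, 9), 0, seq(0.4, 4.0, by = 0.4))
  b <- as.matrix(expand.grid(x = seq(-1, 10, by = 0.25),
                             y = seq(-1, 1, by = 0.25)))
  b <- cbind(b, 0)
  lab <- label_interface(a, b)
  expect_equal(lab$a, c(1L, 1L, 1L, rep(0L, 7)))
})

test_that("sampled pair items are balanced, seeded, and negative-correct", {
  set.seed(1)
  pa <- matrix(runif(60), 20, 3)
  pb <- matrix(runif(60), 20, 3)
  la <- rep(c(1L, 0L), c(5, 15))
  lb <- rep(c(0L, 1L), c(15, 5))
  items <- sample_pairs(pa, pb, la, lb, n_pairs = 8, seed = 42)
  expect_equal(sum(items$label == 1), 4)
  expect_equal(sum(items$label == 0), 4)
  expect_identical(items, sample_pairs(pa, pb, la, lb, 8, seed = 42))
  # every negative contains at least one non-interface vertex
  neg <- items[items$label == 0, ]
  expect_true(all(la[neg$ia] == 0 | lb[neg$ib] == 0))
  # positives pair interface vertices across the two sides
  pos <- items[items$label == 1, ]
  expect_true(all(la[pos$ia] == 1 & lb[pos$ib] == 1))
  expect_error(sample_pairs(pa, pb, rep(0L, 20), lb, 8, 1), "no interface")
  expect_error(sample_pairs(pa, pb, la, lb, 7, 1), "even")
})

test_that("auroc equals the Mann-Whitney pair-counting statistic", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.9, 0.4, 0.6, 0.1), c(1, 0, 0, 1)), 0.5)
  expect_equal(auroc(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_error(auroc(c(1, 2), c(1, 1)), "undefined")
  set.seed(9)
  for (trial in 1:20) {
    n <- sample(5:60, 1)
    scores <- round(runif(n), 2)   # ties likely
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), brute_auroc(scores, labels),
                 tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(auroc(exp(scores), labels), auroc(scores, labels),
                 tolerance = 1e-12)
    expect_equal(auroc(3 * scores - 7, labels), auroc(scores, labels),
                 tolerance = 1e-12)
    # complement identity on tie-free scores
    sc2 <- scores + seq_len(n) * 1e-9
    expect_equal(auroc(sc2, labels) + auroc(sc2, 1 - labels), 1,
                 tolerance = 1e-12)
  }
})

test_that("confusion matrices count all items at the threshold", {
  cm <- confusion_matrix(c(0.9, 0.6, 0.4, 0.1), c(1, 0, 1, 0))
  expect_equal(unname(cm), c(1, 1, 1, 1))
  expect_equal(sum(cm), 4)
  cm2 <- confusion_matrix(c(0.9, 0.6, 0.4, 0.1), c(1, 1, 0, 0))
  expect_equal(unname(cm2), c(2, 0, 2, 0))
})

test_that("training reduces the loss and is seed-reproducible", {
  ds <- tiny_dataset()
  mc <- as_model_config(tiny_run_config())
  fit <- train_model(ds, "interaction", mc, seed = 5, max_epochs = 6,
                     patience = 6)
  expect_lt(tail(fit$log$train_loss, 1), fit$log$train_loss[1])
  expect_true(all(is.finite(fit$log$val_loss)))
  expect_lte(fit$stopped_epoch, 6)
  expect_equal(fit$best_epoch, which.min(fit$log$val_loss))
  fit2 <- train_model(ds, "interaction", mc, seed = 5, max_epochs = 6,
                      patience = 6)
  expect_identical(fit$log, fit2$log)
  expect_equal(fit$state$params, fit2$state$params)
})

test_that("early stopping halts after `patience` non-improving epochs", {
  ds <- tiny_dataset()
  mc <- as_model_config(tiny_run_config())
  # shuffled labels leave nothing to learn, so validation stalls quickly
  fit <- train_model(ds, "interaction", mc, seed = 7, max_epochs = 40,
                     patience = 2, shuffle_labels = TRUE)
  if (fit$stopped_epoch < 40) {
    expect_equal(fit$stopped_epoch, nrow(fit$log))
    tail_losses <- fit$log$val_loss
    best <- min(tail_losses)
    # the two epochs after the last improvement failed to beat the best
    expect_true(all(tail_losses[(fit$stopped_epoch - 1):fit$stopped_epoch] >= best))
    expect_equal(fit$best_epoch, which.min(tail_losses))
  }
  succeed()
})

test_that("site training on a small toy task improves the loss", {
  ds <- site_items(tiny_dataset())
  mc <- as_model_config(tiny_run_config())
  fit <- train_model(ds, "site", mc, seed = 3, max_epochs = 5, patience = 5)
  expect_lt(tail(fit$log$train_loss, 1), fit$log$train_loss[1])
})

test_that("pair evaluation reports AUROC and a consistent confusion matrix", {
  pp <- tiny_prepared_pair()
  aurocs <- vapply(1:3, function(s) {
    st <- init_model(as_model_config(tiny_run_config()), seed = 30 + s)
    ev <- evaluate_pair(st, pp, n_eval_pairs = 32, seed = s)
    expect_equal(ev$TP + ev$FP + ev$TN + ev$FN, ev$n_items)
    ev$auroc
  }, 1.0)
  # untrained random models hover around chance
  expect_true(all(aurocs > 0.2 & aurocs < 0.8))
})
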