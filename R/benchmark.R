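#' End-to-end parameter-recovery benchmark on synthetic pairs
#'
#' Generates a seeded synthetic dataset, prepares every pair through the full
#' real-data path (PDB-style atom clouds, surfacing, labeling,
#' featurisation), trains the interaction and site models, and evaluates
#' held-out AUROCs. Optionally repeats the interaction training with shuffled
#' labels (negative control) and with either input stream ablated.
#'
#' @param n_train,n_test number of training / held-out pairs.
#' @param seed global seed; all stage seeds are derived from it.
#' @param config a [run_config()].
#' @param synth a [synth_config()].
#' @param max_epochs_inter,max_epochs_site epoch caps of the two training
#'   runs (early stopping usually ends them sooner).
#' @param patience early-stopping patience.
#' @param control run the shuffled-label negative control.
#' @param ablations run the chem- and geom-ablated interaction trainings.
#' @param verbose print progress.
#' @return list with held-out `interaction_auroc` and `site_auroc`,
#'   `control_auroc` (shuffled-label), `interaction_auroc_chem_ablated`,
#'   `interaction_auroc_geom_ablated` (each NA when not run), the fitted
#'   states, train logs, and the evaluation reports.
#' @export
synthetic_benchmark <- function(n_train = 200, n_test = 50, seed = 1,
                                config = run_config(),
                                synth = synth_config(),
                                max_epochs_inter = 30, max_epochs_site = 40,
                                patience = 6, control = TRUE,
                                ablations = TRUE, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  n_pairs <- n_train + n_test
  say("generating %d synthetic pairs", n_pairs)
  pairs <- lapply(seq_len(n_pairs), function(q) {
    make_synth_pair(synth, derive_seed(seed, paste0("bench", q)))$pair
  })
  say("preparing pairs (surface, label, featurise)")
  prep <- prepare_pairs(pairs, config, derive_seed(seed, "prep"),
                        verbose = verbose)
  train_p <- prep[seq_len(n_train)]
  test_p <- prep[n_train + seq_len(n_test)]
  mc <- as_model_config(config)

  say("training interaction model")
  fit_i <- train_model(train_p, "interaction", mc,
                       seed = derive_seed(seed, "inter"), lr = config$lr,
                       max_epochs = max_epochs_inter, patience = patience,
                       val_fraction = config$val_fraction, verbose = verbose)
  ev_i <- evaluate_dataset(fit_i$state, test_p, config$n_eval_pairs,
                           derive_seed(seed, "evali"))

  say("training site model")
  site_train <- site_items(train_p)
  site_test <- site_items(test_p)
  fit_s <- train_model(site_train, "site", mc,
                       seed = derive_seed(seed, "site"), lr = config$lr,
                       max_epochs = max_epochs_site, patience = patience,
                       val_fraction = config$val_fraction, verbose = verbose)
  ev_s <- evaluate_sites(fit_s$state, site_test)

  control_auroc <- NA_real_
  if (control) {
    say("shuffled-label control")
    fit_c <- train_model(train_p, "interaction", mc,
                         seed = derive_seed(seed, "control"), lr = config$lr,
                         max_epochs = max_epochs_inter, patience = patience,
                         val_fraction = config$val_fraction,
                         shuffle_labels = TRUE, verbose = verbose)
    control_auroc <- evaluate_dataset(fit_c$state, test_p,
                                      config$n_eval_pairs,
                                      derive_seed(seed, "evalc"))$mean_auroc
  }

  ab_chem <- ab_geom <- NA_real_
  if (ablations) {
    say("chem-ablated interaction model")
    fit_ac <- train_model(train_p, "interaction", mc,
                          seed = derive_seed(seed, "abchem"), lr = config$lr,
                          max_epochs = max_epochs_inter, patience = patience,
                          val_fraction = config$val_fraction,
                          ablate = "chem", verbose = verbose)
    ab_chem <- evaluate_dataset(fit_ac$state, test_p, config$n_eval_pairs,
                                derive_seed(seed, "evalac"),
                                ablate = "chem")$mean_auroc
    say("geom-ablated interaction model")
    fit_ag <- train_model(train_p, "interaction", mc,
                          seed = derive_seed(seed, "abgeom"), lr = config$lr,
                          max_epochs = max_epochs_inter, patience = patience,
                          val_fraction = config$val_fraction,
                          ablate = "geom", verbose = verbose)
    ab_geom <- evaluate_dataset(fit_ag$state, test_p, config$n_eval_pairs,
                                derive_seed(seed, "evalag"),
                                ablate = "geom")$mean_auroc
  }

  list(interaction_auroc = ev_i$mean_auroc,
       site_auroc = ev_s$mean_auroc,
       control_auroc = control_auroc,
       interaction_auroc_chem_ablated = ab_chem,
       interaction_auroc_geom_ablated = ab_geom,
       interaction_report = ev_i, site_report = ev_s,
       fit_interaction = fit_i, fit_site = fit_s,
       n_train = n_train, n_test = n_test, seed = seed)
}
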