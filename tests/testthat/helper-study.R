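# Compact rational-vs-random sampling comparison used by the acceptance
# checks: one synthetic universe per seed, a 2:1 -> 3:1 -> 4:1 rational
# arm against a size-matched random 4:1 reference, both externally
# validated on the untouched test set.

mini_compare <- function(seed, n_active = 56, n_inactive = 700) {
  cfg <- fixture_config(n_active = n_active, n_inactive = n_inactive,
                        decoy_rate = 0.12, seed = seed)
  tbl <- generate_fixture(cfg)
  cd <- curate(tbl)
  rec <- kept_records(cd, modelling = TRUE)
  fs <- featurize(rec$canonical_smiles, rec$id)
  labels <- stats::setNames(as.integer(rec$label == "ACTIVE"), rec$id)
  act <- rec$id[rec$label == "ACTIVE"]
  inact <- rec$id[rec$label == "INACTIVE"]
  sp <- make_split(act, inact, 0.10, floor(0.8 * length(inact)),
                   seed = seed)
  mc <- model_config(seed = seed_substream(seed, "mini-model"))
  n_act <- length(sp$train_actives)

  # rational arm: iterative expansion
  tr_inact <- initial_inactive_draw(sp$selection_pool, n_act, 2,
                                    seed = seed)
  n_add <- 4 * floor(n_act / 4)
  model <- NULL
  for (k in 1:2) {
    rows <- c(sp$train_actives, tr_inact)
    model <- fit_cocktail(fs[rows], labels[rows], config = mc)
    cand <- setdiff(sp$selection_pool, tr_inact)
    ex <- rational_expand(model, fs[cand], n_add,
                          seed = seed_substream(seed, paste0("mini-ex", k)))
    tr_inact <- c(tr_inact, ex$ids)
  }
  rows <- c(sp$train_actives, tr_inact)
  rational <- fit_cocktail(fs[rows], labels[rows], config = mc)

  # random reference arm, size-matched to the rational training set
  rand_inact <- with_seed(seed_substream(seed, "mini-rand"),
                          sample_ids(sp$selection_pool, length(tr_inact)))
  rows_r <- c(sp$train_actives, rand_inact)
  random <- fit_cocktail(fs[rows_r], labels[rows_r], config = mc)

  test_ids <- c(sp$test_actives, sp$test_inactives)
  ev_rat <- external_validate(rational, fs[test_ids], labels[test_ids])
  ev_ran <- external_validate(random, fs[test_ids], labels[test_ids])
  list(rational = ev_rat, random = ev_ran, features = fs,
       labels = labels, rows_rational = rows, split = sp)
}
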