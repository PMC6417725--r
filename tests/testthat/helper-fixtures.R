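# Shared fixtures, built once per test run and memoized.

.fx_cache <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fx_cache)) {
    assign(name, builder(), envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

# small mixed molecule set for feature/domain tests
tiny_features <- function() {
  memo("tiny", function() {
    smis <- c("CCO", "CC(=O)O", "c1ccccc1", "c1ccc2[nH]ccc2c1CC",
              "CS(=O)(=O)NCC", "CCCCCCO", "c1ccncc1CCN", "C1CCCCC1CCO",
              "CCc1cc[nH]c1", "CCOC(=O)CC")
    ids <- sprintf("tiny%02d", seq_along(smis))
    list(smiles = smis, ids = ids, features = featurize(smis, ids))
  })
}

# planted-alert modelling fixture: 60 actives / 240 inactives
model_fixture <- function() {
  memo("model", function() {
    cfg <- fixture_config(n_active = 60, n_inactive = 240,
                          alert_penetrance = 1, decoy_rate = 0.03,
                          seed = 11)
    tbl <- generate_fixture(cfg)
    list(tbl = tbl, labels = as.integer(tbl$true_class == "active"),
         features = featurize(tbl$smiles, tbl$id))
  })
}

# the 200/800 near-separable fixture used by the heavier properties
big_fixture <- function() {
  memo("big", function() {
    cfg <- fixture_config(n_active = 200, n_inactive = 800,
                          alert_penetrance = 0.9, decoy_rate = 0.05,
                          seed = 23)
    tbl <- generate_fixture(cfg)
    list(tbl = tbl, labels = as.integer(tbl$true_class == "active"),
         features = featurize(tbl$smiles, tbl$id))
  })
}

# minimal hand-built single model for structural-domain unit tests
fake_member <- function(train_fp, key_columns) {
  structure(list(train_fp = train_fp, key_columns = key_columns,
                 type = "intercept", base_rate = 0.5,
                 train_ids = rownames(train_fp),
                 n_active = 1, n_inactive = 1),
            class = "qsar_single_model")
}
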