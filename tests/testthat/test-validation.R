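# Cooper statistics, predictive values, MCC, cross-validation,
# Y-randomization and external validation.

test_that("cooper statistics match printed worked examples and the oracle", {
  # cross-validated ensemble confusion
  cp <- cooper(list(tp = 544, tn = 1264, fp = 104, fn = 68))
  expect_equal(round_half_up(cp$sensitivity, 1), 88.9)
  expect_equal(round_half_up(cp$specificity, 1), 92.4)
  # external validation of the third-iteration model
  cp2 <- cooper(list(tp = 40, tn = 114977, fp = 3475, fn = 7))
  expect_equal(round_half_up(cp2$sensitivity, 1), 85.1)
  expect_equal(round_half_up(cp2$specificity, 1), 97.1)
  expect_equal(round_half_up(cp2$balanced_accuracy, 1), 91.1)
  # perfect classifier
  cp3 <- cooper(list(tp = 10, tn = 20, fp = 0, fn = 0))
  expect_equal(unlist(cp3), c(sensitivity = 100, specificity = 100,
                              balanced_accuracy = 100))
  # empty experimental class leaves statistics undefined
  cp4 <- cooper(list(tp = 0, tn = 5, fp = 2, fn = 0))
  expect_true(is.na(cp4$sensitivity))
  expect_true(is.na(cp4$balanced_accuracy))
  # independent oracle on random tables: caret's class statistics
  set.seed(19)
  for (i in 1:200) {
    cc <- rpois(4, 20) + c(1, 1, 0, 1)  # tp tn fp fn, margins nonzero
    truth <- factor(rep(c("act", "inact"), c(cc[1] + cc[4], cc[2] + cc[3])),
                    levels = c("act", "inact"))
    call <- factor(c(rep("act", cc[1]), rep("inact", cc[4]),
                     rep("inact", cc[2]), rep("act", cc[3])),
                   levels = c("act", "inact"))
    cp <- cooper(list(tp = cc[1], tn = cc[2], fp = cc[3], fn = cc[4]))
    expect_equal(cp$sensitivity / 100,
                 unname(caret::sensitivity(call, truth, positive = "act")),
                 tolerance = 1e-9)
    expect_equal(cp$specificity / 100,
                 unname(caret::specificity(call, truth, negative = "inact")),
                 tolerance = 1e-9)
    expect_equal(cp$balanced_accuracy,
                 (cp$sensitivity + cp$specificity) / 2)
  }
})

test_that("prevalence-adjusted predictive values match population arithmetic", {
  # printed worked example at 1% prevalence
  pv <- predictive_values(0.851, 0.971, 0.01)
  expect_equal(round_half_up(pv$ppv, 1), 22.9)
  # perfect model
  pv1 <- predictive_values(1, 1, 0.3)
  expect_equal(pv1$ppv, 100); expect_equal(pv1$npv, 100)
  # oracle: counts in a large synthetic population
  set.seed(4)
  for (i in 1:100) {
    s <- runif(1, 0.5, 0.99); cc <- runif(1, 0.5, 0.99)
    pi <- runif(1, 0.01, 0.5)
    pop <- 1e7
    tp <- s * pi * pop;        fn <- (1 - s) * pi * pop
    tn <- cc * (1 - pi) * pop; fp <- (1 - cc) * (1 - pi) * pop
    pv <- predictive_values(s, cc, pi)
    expect_equal(pv$ppv, 100 * tp / (tp + fp), tolerance = 1e-9)
    expect_equal(pv$npv, 100 * tn / (tn + fn), tolerance = 1e-9)
  }
  # PPV strictly increases in prevalence for s, c in (0,1)
  ppvs <- sapply(c(0.01, 0.05, 0.10, 0.2),
                 function(pi) predictive_values(0.9, 0.9, pi)$ppv)
  expect_true(all(diff(ppvs) > 0))
  expect_warning(predictive_values(0.9, 0.9, 0), "degenerate")
})

test_that("agreement MCC matches the correlation oracle and is symmetric", {
  # printed agreement counts of the two final models
  expect_equal(round_half_up(mcc_from_agreement(1135, 38305, 4, 34), 3),
               0.983)
  expect_equal(mcc_from_agreement(10, 20, 0, 0), 1)
  # symmetric in the disagreement directions
  expect_equal(mcc_from_agreement(7, 11, 3, 5),
               mcc_from_agreement(7, 11, 5, 3))
  # oracle: MCC is the Pearson correlation of the two binary call vectors
  set.seed(8)
  for (i in 1:100) {
    cc <- rpois(4, 10) + 1
    a <- rep(c(1, 0, 1, 0), cc)
    b <- rep(c(1, 0, 0, 1), cc)
    expect_equal(mcc_from_agreement(cc[1], cc[2], cc[3], cc[4]),
                 cor(a, b), tolerance = 1e-9)
  }
  expect_warning(mcc_from_agreement(5, 0, 0, 0), "margin")
})

test_that("cross-validation learns the separable fixture and not its permutation", {
  fx <- big_fixture()
  mc <- model_config(seed = 6)
  cv <- crossvalidate(fx$features, fx$labels, repeats = 2, folds = 5,
                      seed = 14, config = mc)
  ba <- cv$summary$balanced_accuracy["mean"]
  expect_gte(ba, 85); expect_lte(ba, 100)
  expect_equal(nrow(cv$per_fold), 10)
  # fold membership partitions the set per repeat (10 held-out fifths)
  expect_equal(sum(cv$confusion$tp, cv$confusion$tn, cv$confusion$fp,
                   cv$confusion$fn) <= 2 * length(fx$labels), TRUE)
  # label-permuted control sits at chance: over all called predictions the
  # balanced accuracy is pinned near 50; the in-AD value rests on a handful
  # of confident calls and is only loosely bounded
  y_perm <- with(list(), {set.seed(99); sample(fx$labels)})
  cv_null <- crossvalidate(fx$features, y_perm, repeats = 2, folds = 5,
                           seed = 14, config = mc)
  ba_null_all <- cv_null$summary$balanced_accuracy_all["mean"]
  expect_gte(ba_null_all, 45); expect_lte(ba_null_all, 55)
  ba_null_ad <- cv_null$summary$balanced_accuracy["mean"]
  expect_true(is.na(ba_null_ad) ||
                (ba_null_ad >= 35 && ba_null_ad <= 65))
})

test_that("y-randomization assigns half/half labels and scores at chance", {
  fx <- big_fixture()
  yr <- y_randomize(fx$features, fx$labels, repeats = 2, folds = 5,
                    seed = 14, config = model_config(seed = 6))
  n <- length(fx$labels)
  expect_equal(yr$n_assigned_active, ceiling(n / 2))
  expect_equal(sum(yr$randomized_labels), ceiling(n / 2))
  # chance-level discrimination, judged over all called predictions: at
  # desk scale the in-AD subset of a randomized model is near-empty
  ba_all <- yr$summary$balanced_accuracy_all["mean"]
  expect_gte(ba_all, 40); expect_lte(ba_all, 60)
  # no discrimination: active calls land on randomized actives and
  # inactives at the same rate, so sensitivity + (100 - specificity)
  # cancel even when the call threshold sits off-centre in p space
  s_all <- yr$summary$sensitivity_all["mean"]
  c_all <- yr$summary$specificity_all["mean"]
  expect_gte(s_all + c_all, 90); expect_lte(s_all + c_all, 110)
  # the randomized model either abstains (near-empty AD) or scores at
  # chance inside it
  ba_ad <- yr$summary$balanced_accuracy["mean"]
  expect_true(yr$summary$ad_pct["mean"] < 10 || is.na(ba_ad) ||
                (ba_ad >= 35 && ba_ad <= 65))
})

test_that("external validation guards leakage and reports coverage by class", {
  fx <- model_fixture()
  mc <- model_config(seed = 3)
  train <- seq(1, 240)
  test <- seq(241, 300)
  ck <- fit_cocktail(fx$features[train], fx$labels[train], config = mc)
  ev <- external_validate(ck, fx$features[test], fx$labels[test])
  # coverage identities
  y <- fx$labels[test]
  pred <- ev$predictions
  expect_equal(ev$ad_pct, 100 * mean(pred$in_ad))
  expect_equal(ev$coverage_inactives, 100 * mean(pred$in_ad[y == 0]))
  # confusion restricted to in-AD predictions
  expect_equal(ev$confusion$tp + ev$confusion$tn + ev$confusion$fp +
                 ev$confusion$fn, sum(pred$in_ad))
  # any train/test overlap is a hard error
  expect_error(external_validate(ck, fx$features[c(1, 250:260)],
                                 fx$labels[c(1, 250:260)]), "leakage")
})

test_that("external validation handles the trivial all-in / all-out cases", {
  # training structures under fresh ids: similarity 1, in-AD, correct
  act <- sprintf("Cc1ccc2[nH]ccc2c1%s", c("C", "CC", "CCC", "CCO", "CN",
                                          "CCN"))
  inact <- sprintf("CCCC%s", c("C", "CC", "CCC", "CCO", "CN", "CCN"))
  smis <- c(act, inact)
  fs <- featurize(smis, sprintf("tr%02d", 1:12))
  y <- rep(c(1L, 0L), each = 6)
  m <- fit_single(fs, y, config = model_config(seed = 2, press_folds = 3))
  fs_test <- featurize(smis, sprintf("te%02d", 1:12))
  ev <- external_validate(m, fs_test, y)
  expect_equal(ev$ad_pct, 100)
  expect_equal(ev$cooper$balanced_accuracy, 100)
  # structures sharing nothing with training: out of structural domain
  far <- featurize(c("ICI", "C(Br)(Br)Br"), c("far1", "far2"))
  ev2 <- external_validate(m, far, c(0L, 0L))
  expect_equal(ev2$ad_pct, 0)
  expect_true(is.na(ev2$cooper$specificity))
})

test_that("external balanced accuracy rises with alert penetrance", {
  mc <- model_config(seed = 6)
  ba <- sapply(c(0.2, 0.6, 1.0), function(pen) {
    cfg <- fixture_config(n_active = 40, n_inactive = 160,
                          alert_penetrance = pen, decoy_rate = 0,
                          seed = 29)
    tbl <- generate_fixture(cfg)
    fs <- featurize(tbl$smiles, tbl$id)
    y <- as.integer(tbl$true_class == "active")
    hold <- c(seq(1, 40, by = 4), seq(41, 200, by = 4))
    train <- setdiff(seq_len(200), hold)
    ck <- fit_cocktail(fs[train], y[train], config = mc)
    ev <- external_validate(ck, fs[hold], y[hold])
    ev$cooper$balanced_accuracy
  })
  expect_true(all(diff(ba) > 0))
})
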