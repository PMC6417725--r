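## Validation statistics and procedures.
##
## Cooper statistics (sensitivity, specificity, balanced accuracy) on in-AD
## predictions, prevalence-adjusted predictive values, model-agreement
## Matthews correlation, independent repeated stratified k-fold
## cross-validation (every fold-model rebuilds vocabulary, preselection and
## ensemble from its own 80% only), Y-randomization, and external
## validation with leakage guards.

#' Confusion counts from truth and calls
#'
#' @param truth binary vector (1/`"ACTIVE"` = active).
#' @param call character vector `"active"`/`"inactive"`.
#' @return list of class `confusion_counts` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, call) {
  y <- as_binary_labels(truth)
  stopifnot(length(y) == length(call))
  structure(list(
    tp = sum(y == 1 & call == "active"),
    tn = sum(y == 0 & call == "inactive"),
    fp = sum(y == 0 & call == "active"),
    fn = sum(y == 1 & call == "inactive")
  ), class = "confusion_counts")
}

#' Cooper statistics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and balanced
#' accuracy `(sensitivity+specificity)/2`, as percentages. An empty
#' experimental class leaves the corresponding statistic (and the balanced
#' accuracy) `NA`. Values are unrounded; use [round_half_up()] with one
#' decimal for table-style presentation, where the balanced accuracy is
#' conventionally recomputed from the rounded components.
#'
#' @param confusion a `confusion_counts` (or list with tp/tn/fp/fn).
#' @return list with `sensitivity`, `specificity`, `balanced_accuracy`
#'   (percent).
#' @export
#' @examples
#' cooper(list(tp = 544, tn = 1264, fp = 104, fn = 68))
cooper <- function(confusion) {
  tp <- confusion$tp; tn <- confusion$tn
  fp <- confusion$fp; fn <- confusion$fn
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  ba <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
  list(sensitivity = sens, specificity = spec, balanced_accuracy = ba)
}

#' Prevalence-adjusted predictive values
#'
#' `PPV = s*pi / (s*pi + (1-c)(1-pi))` and
#' `NPV = c(1-pi) / (c(1-pi) + (1-s)pi)` for sensitivity `s`, specificity
#' `c` and assumed prevalence of actives `pi`, all as fractions; returned
#' as percentages.
#'
#' @param sensitivity,specificity fractions in `[0, 1]`.
#' @param prevalence assumed prevalence of actives, fraction in `[0, 1]`.
#' @return list with `ppv` and `npv` (percent).
#' @export
#' @examples
#' predictive_values(0.851, 0.971, 0.01)   # PPV ~ 22.9%
predictive_values <- function(sensitivity, specificity, prevalence) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            prevalence >= 0, prevalence <= 1)
  if (prevalence %in% c(0, 1)) {
    warning("degenerate prevalence; returning limit values")
    return(if (prevalence == 0) list(ppv = 0, npv = 100)
           else list(ppv = 100, npv = 0))
  }
  s <- sensitivity; cc <- specificity; pi <- prevalence
  ppv <- s * pi / (s * pi + (1 - cc) * (1 - pi))
  npv <- cc * (1 - pi) / (cc * (1 - pi) + (1 - s) * pi)
  list(ppv = 100 * ppv, npv = 100 * npv)
}

#' Matthews correlation coefficient from model-agreement counts
#'
#' Treats one model's calls as the reference; symmetric in the two models
#' and in the two disagreement directions.
#'
#' @param n_both_pos,n_both_neg substances called positive/negative by both
#'   models.
#' @param n_disagree_ab positives of model A called negative by model B.
#' @param n_disagree_ba negatives of model A called positive by model B.
#' @return MCC in `[-1, 1]`; 0 (with a warning) when a margin is zero.
#' @export
#' @examples
#' mcc_from_agreement(1135, 38305, 4, 34)  # ~ 0.983
mcc_from_agreement <- function(n_both_pos, n_both_neg, n_disagree_ab,
                               n_disagree_ba) {
  tp <- n_both_pos; tn <- n_both_neg
  fp <- n_disagree_ba; fn <- n_disagree_ab
  stopifnot(all(c(tp, tn, fp, fn) >= 0), tp + tn + fp + fn > 0)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) {
    warning("zero margin in agreement table; MCC defined as 0")
    return(0)
  }
  (tp * tn - fp * fn) / den
}

## statistics of one prediction set: in-AD Cooper + coverage
.eval_predictions <- function(pred, truth) {
  y <- as_binary_labels(truth)
  ad <- pred$in_ad
  conf <- if (any(ad)) {
    confusion_counts(y[ad], pred$call[ad])
  } else {
    structure(list(tp = 0, tn = 0, fp = 0, fn = 0),
              class = "confusion_counts")
  }
  cp <- cooper(conf)
  # statistics over every called prediction (p >= 0.5 rule, ignoring the
  # probability-refinement band): used for chance-level diagnostics where
  # the in-AD subset is too small to carry a rate
  called <- !is.na(pred$p)
  cp_all <- if (any(called)) {
    cooper(confusion_counts(y[called], pred$call[called]))
  } else {
    list(sensitivity = NA_real_, specificity = NA_real_,
         balanced_accuracy = NA_real_)
  }
  list(confusion = conf, cooper = cp, cooper_all = cp_all,
       ad_pct = coverage(pred$category),
       coverage_actives = if (any(y == 1)) 100 * mean(ad[y == 1]) else NA,
       coverage_inactives = if (any(y == 0)) 100 * mean(ad[y == 0]) else NA)
}

#' Independent repeated stratified k-fold cross-validation
#'
#' For every repeat and fold, the vocabulary, the chi-squared
#' preselection and the cocktail ensemble are rebuilt from the in-fold
#' training rows only, the held-out rows are predicted, and Cooper
#' statistics are computed over the held-out in-AD predictions. Reported
#' are mean and standard deviation across the `repeats * folds`
#' fold-models plus the pooled confusion counts.
#'
#' @param features `feature_set` of the training set.
#' @param labels binary labels.
#' @param repeats,folds cross-validation plan (default 2 x 5).
#' @param seed master seed for fold assignment.
#' @param config a [model_config()].
#' @param prevalences assumed prevalences for predictive values.
#' @return object of class `validation_report`.
#' @export
crossvalidate <- function(features, labels, repeats = 2, folds = 5,
                          seed = 1, config = model_config(),
                          prevalences = c(0.01, 0.05, 0.10)) {
  y <- as_binary_labels(labels)
  n <- length(y)
  stopifnot(length(features$ids) == n)
  if (min(table(y)) < folds) {
    qc_error("too few members of the minority class for stratified folds")
  }
  per_fold <- list()
  pooled <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (r in seq_len(repeats)) {
    fold_id <- integer(n)
    with_seed(seed_substream(seed, paste0("cv-repeat-", r)), {
      for (cls in c(0, 1)) {
        idx <- which(y == cls)
        fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
    })
    for (f in seq_len(folds)) {
      te <- fold_id == f
      tr_ids <- features$ids[!te]
      te_ids <- features$ids[te]
      stopifnot(length(intersect(tr_ids, te_ids)) == 0)  # no leakage
      vocab <- build_vocabulary(features, rows = tr_ids,
                                min_frequency = config$min_frequency)
      fold_cfg <- config
      fold_cfg$seed <- seed_substream(seed, sprintf("cv-fit-%d-%d", r, f))
      model <- fit_cocktail(features[tr_ids], y[!te], vocab, fold_cfg)
      pred <- predict_probability(model, features[te_ids])
      ev <- .eval_predictions(pred, y[te])
      pooled <- pooled + unlist(ev$confusion)
      per_fold[[length(per_fold) + 1L]] <- data.frame(
        repeat_ = r, fold = f,
        sensitivity = ev$cooper$sensitivity,
        specificity = ev$cooper$specificity,
        balanced_accuracy = ev$cooper$balanced_accuracy,
        ad_pct = ev$ad_pct,
        sensitivity_all = ev$cooper_all$sensitivity,
        specificity_all = ev$cooper_all$specificity,
        balanced_accuracy_all = ev$cooper_all$balanced_accuracy)
    }
  }
  per_fold <- do.call(rbind, per_fold)
  mean_sd <- function(v) c(mean = mean(v, na.rm = TRUE),
                           sd = stats::sd(v, na.rm = TRUE))
  summary <- lapply(per_fold[, c("sensitivity", "specificity",
                                 "balanced_accuracy", "ad_pct",
                                 "sensitivity_all", "specificity_all",
                                 "balanced_accuracy_all")], mean_sd)
  pv <- lapply(prevalences, function(pi) {
    predictive_values(summary$sensitivity["mean"] / 100,
                      summary$specificity["mean"] / 100, pi)
  })
  names(pv) <- paste0("prevalence_", prevalences)
  structure(list(
    type = "crossvalidation", per_fold = per_fold, summary = summary,
    confusion = as.list(pooled), predictive_values = pv,
    repeats = repeats, folds = folds, seed = seed
  ), class = "validation_report")
}

#' Y-randomization test
#'
#' Replaces the labels by a random half/half assignment
#' (`ceiling(N/2)` actives, `floor(N/2)` inactives), rebuilds and
#' cross-validates the model. Chance-level Cooper statistics (about 50%)
#' demonstrate the absence of chance correlation in the modelling
#' pipeline.
#'
#' @inheritParams crossvalidate
#' @return a `validation_report` with the randomized labels attached.
#' @export
y_randomize <- function(features, labels, repeats = 2, folds = 5,
                        seed = 1, config = model_config()) {
  n <- length(features$ids)
  if (n < 10) qc_error("training set too small for Y-randomization")
  n_act <- ceiling(n / 2)
  y_rand <- with_seed(seed_substream(seed, "y-randomize"), {
    sample(c(rep(1L, n_act), rep(0L, n - n_act)))
  })
  rep <- crossvalidate(features, y_rand, repeats, folds,
                       seed = seed_substream(seed, "y-randomize-cv"),
                       config = config)
  rep$type <- "y_randomization"
  rep$randomized_labels <- y_rand
  rep$n_assigned_active <- n_act
  rep
}

#' External validation on a held-out test set
#'
#' Asserts that test and training ids are disjoint (leakage is a hard
#' error), predicts the test set, and reports Cooper statistics over the
#' in-AD predictions, coverage for actives/inactives/total, and
#' prevalence-adjusted predictive values.
#'
#' @param model a fitted qsar model.
#' @param test_features `feature_set` of the test structures.
#' @param test_labels binary labels of the test structures.
#' @param prevalences assumed prevalences of actives.
#' @return object of class `validation_report`.
#' @export
external_validate <- function(model, test_features, test_labels,
                              prevalences = c(0.01, 0.05, 0.10)) {
  train_ids <- unique(unlist(lapply(model_members(model),
                                    function(m) m$train_ids)))
  overlap <- intersect(train_ids, test_features$ids)
  if (length(overlap)) {
    qc_error(sprintf("leakage: %d test id(s) occur in the training set",
                     length(overlap)))
  }
  pred <- predict_probability(model, test_features)
  ev <- .eval_predictions(pred, test_labels)
  pv <- if (!is.na(ev$cooper$sensitivity) &&
            !is.na(ev$cooper$specificity)) {
    out <- lapply(prevalences, function(pi) {
      predictive_values(ev$cooper$sensitivity / 100,
                        ev$cooper$specificity / 100, pi)
    })
    names(out) <- paste0("prevalence_", prevalences)
    out
  } else NULL
  structure(list(
    type = "external", predictions = pred, confusion = ev$confusion,
    cooper = ev$cooper, ad_pct = ev$ad_pct,
    coverage_actives = ev$coverage_actives,
    coverage_inactives = ev$coverage_inactives,
    predictive_values = pv
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.1f", v))
  cat("Validation report (", x$type, ")\n", sep = "")
  if (x$type %in% c("crossvalidation", "y_randomization")) {
    s <- x$summary
    for (nm in names(s)) {
      cat(sprintf("  %-18s %s +/- %s %%\n", nm, fmt(s[[nm]]["mean"]),
                  fmt(s[[nm]]["sd"])))
    }
  } else {
    cat(sprintf("  sensitivity %s%%  specificity %s%%  BA %s%%  coverage %s%%\n",
                fmt(x$cooper$sensitivity), fmt(x$cooper$specificity),
                fmt(x$cooper$balanced_accuracy), fmt(x$ad_pct)))
  }
  cf <- x$confusion
  cat(sprintf("  confusion: TP %d  TN %d  FP %d  FN %d\n",
              cf$tp, cf$tn, cf$fp, cf$fn))
  invisible(x)
}
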