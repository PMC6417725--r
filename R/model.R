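## Partial-logistic-regression (PLR) models and cocktail ensembles.
##
## A single model extracts PLS factors against the binary response treated
## as continuous (mixOmics::pls is the factor engine), chooses the number
## of factors by minimizing the predictive residual sum of squares (PRESS)
## in a seeded internal k-fold split, optionally drops zero-loading
## features and refits, and finally fits a logistic regression on the
## factor scores. A composite model partitions the training inactives into
## balanced chunks, each paired with all actives, and fits one sub-model
## per chunk. The cocktail combines the full-set single model with the
## composite's sub-models; its positive prediction probability is the
## unweighted mean over the members that contain the query in their
## structural domain, and a query outside every member's structural domain
## is out of the (structural) applicability domain altogether.

#' Model configuration
#'
#' @param max_factors maximum number of PLS factors considered (default 10).
#' @param press_folds internal folds for PRESS factor selection (default 5).
#' @param preselect_fraction fraction of descriptor columns kept by the
#'   Yates chi-squared preselection (default 0.30).
#' @param ratio actives:inactives ratio of composite sub-model training
#'   sets (default 1, i.e. balanced).
#' @param min_similarity structural-domain Jaccard threshold (default 0.30,
#'   inclusive).
#' @param min_frequency vocabulary mining frequency floor.
#' @param refit_passes maximum refits after dropping zero-loading features.
#' @param seed seed for the internal PRESS folds and inactive partitioning.
#' @return a list of class `model_config`.
#' @export
model_config <- function(max_factors = 10, press_folds = 5,
                         preselect_fraction = 0.30, ratio = 1,
                         min_similarity = 0.30, min_frequency = 0.01,
                         refit_passes = 2, seed = 1) {
  structure(as.list(environment()), class = "model_config")
}

## accept 0/1, logical, or ACTIVE/INACTIVE labels
as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    stopifnot(all(labels %in% c("ACTIVE", "INACTIVE")))
    as.integer(labels == "ACTIVE")
  } else {
    stopifnot(all(labels %in% c(0, 1)))
    as.integer(labels)
  }
}

## PRESS per factor count from a seeded internal k-fold split
.pls_press <- function(x, y, ncomp_max, folds, seed) {
  n <- nrow(x)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  press <- numeric(ncomp_max)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (sum(tr) <= ncomp_max + 1 || length(unique(y[tr])) < 2) next
    fit <- try(suppressWarnings(
      mixOmics::pls(x[tr, , drop = FALSE], y[tr], ncomp = ncomp_max,
                    mode = "regression", scale = TRUE)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    # noise-only responses can collapse later components into a singular
    # projection; such folds contribute nothing
    pr <- try(suppressWarnings(
      stats::predict(fit, x[!tr, , drop = FALSE]))$predict, silent = TRUE)
    if (inherits(pr, "try-error")) next
    for (k in seq_len(ncomp_max)) {
      press[k] <- press[k] + sum((y[!tr] - pr[, 1, k])^2)
    }
  }
  press
}

#' Fit a single PLR model
#'
#' @param features a `feature_set` of the training structures.
#' @param labels binary labels (1/`"ACTIVE"` = active).
#' @param vocabulary optional `qsar_vocabulary`; built from the training
#'   features when `NULL`.
#' @param config a [model_config()].
#' @return object of class `qsar_single_model`.
#' @export
fit_single <- function(features, labels, vocabulary = NULL,
                       config = model_config()) {
  stopifnot(inherits(features, "feature_set"))
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    qc_error("training set must contain at least two structures per class")
  }
  if (is.null(vocabulary)) {
    vocabulary <- build_vocabulary(features,
                                   min_frequency = config$min_frequency)
  }
  fp <- fingerprint(features, vocabulary)
  x_all <- design_matrix(features, vocabulary)
  # descriptor-incalculable rows cannot inform the fit
  x_all[is.na(x_all)] <- 0

  mask <- preselect(x_all, y, config$preselect_fraction)
  x <- x_all[, mask, drop = FALSE]

  model <- list(
    vocabulary = vocabulary, train_fp = fp, train_ids = features$ids,
    n_active = sum(y == 1), n_inactive = sum(y == 0),
    config = config
  )

  fit_core <- function(x) {
    x <- x[, apply(x, 2, stats::var) > 0, drop = FALSE]
    if (ncol(x) == 0) {
      return(list(type = "intercept", base_rate = mean(y)))
    }
    if (ncol(x) < 2) {
      g <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
      return(list(type = "direct", columns = colnames(x),
                  glm_coef = stats::coef(g), n_factors = 1L))
    }
    ncomp_max <- max(1L, min(config$max_factors, ncol(x) - 1L,
                             nrow(x) - 2L))
    press <- .pls_press(x, y, ncomp_max, config$press_folds,
                        seed_substream(config$seed, "press"))
    n_factors <- if (all(press == 0)) 1L else which.min(press)
    # back off factors whose projection is numerically singular
    repeat {
      pls_fit <- suppressWarnings(
        mixOmics::pls(x, y, ncomp = n_factors, mode = "regression",
                      scale = TRUE))
      probe <- try(suppressWarnings(
        stats::predict(pls_fit, x[1:2, , drop = FALSE])), silent = TRUE)
      if (!inherits(probe, "try-error")) break
      if (n_factors == 1L) {
        return(list(type = "intercept", base_rate = mean(y)))
      }
      n_factors <- n_factors - 1L
    }
    scores <- pls_fit$variates$X
    g <- suppressWarnings(
      stats::glm(y ~ scores, family = stats::binomial()))
    list(type = "pls", columns = colnames(x), pls = pls_fit,
         glm_coef = stats::coef(g), n_factors = n_factors)
  }

  core <- fit_core(x)
  # iterative feature pruning: drop zero-loading features, refit (capped)
  passes <- 0
  while (core$type == "pls" && passes < config$refit_passes) {
    load_abs <- rowSums(abs(core$pls$loadings$X))
    # NaN loadings mark collapsed deflation, not a zero contribution
    keep <- is.na(load_abs) | load_abs > 1e-10
    if (all(keep)) break
    x <- x[, keep, drop = FALSE]
    core <- fit_core(x)
    passes <- passes + 1
  }

  model <- c(model, core)
  model$key_columns <- intersect(model$columns %||% character(0),
                                 colnames(fp))
  class(model) <- "qsar_single_model"
  model
}

## member probabilities for featurized queries
.predict_member_p <- function(member, x_new) {
  x_new[is.na(x_new)] <- 0
  if (member$type == "intercept") {
    return(rep(member$base_rate, nrow(x_new)))
  }
  if (member$type == "direct") {
    eta <- member$glm_coef[1] +
      x_new[, member$columns, drop = FALSE] %*% member$glm_coef[-1]
    return(as.vector(stats::plogis(eta)))
  }
  sc <- suppressWarnings(stats::predict(
    member$pls, x_new[, member$columns, drop = FALSE]))$variates
  sc <- sc[, seq_len(member$n_factors), drop = FALSE]
  eta <- member$glm_coef[1] + sc %*% member$glm_coef[-1]
  as.vector(stats::plogis(eta))
}

#' Fit a composite (balanced sub-model ensemble) model
#'
#' The training inactives are randomly partitioned into
#' `ceiling(n_inactive / (ratio * n_active))` chunks; every sub-model is
#' trained on all actives plus one chunk. If there are fewer inactives than
#' actives a single sub-model uses everything.
#'
#' @inheritParams fit_single
#' @return object of class `qsar_composite_model` with `sub_models` and the
#'   shared `vocabulary`.
#' @export
fit_composite <- function(features, labels, vocabulary = NULL,
                          config = model_config()) {
  y <- as_binary_labels(labels)
  if (is.null(vocabulary)) {
    vocabulary <- build_vocabulary(features,
                                   min_frequency = config$min_frequency)
  }
  act <- which(y == 1); inact <- which(y == 0)
  if (length(inact) < length(act)) {
    chunks <- list(inact)
  } else {
    # nearest-integer chunk count keeps every sub-model's effective
    # actives:inactives ratio as close as possible to the requested one
    n_chunks <- max(1, round_half_up(
      length(inact) / (config$ratio * length(act))))
    perm <- with_seed(seed_substream(config$seed, "composite-partition"),
                      sample(inact))
    chunks <- unname(split(perm, sort(rep_len(seq_len(n_chunks),
                                              length(inact)))))
  }
  sub_models <- lapply(chunks, function(ch) {
    rows <- sort(c(act, ch))
    fit_single(features[rows], y[rows], vocabulary, config)
  })
  structure(list(sub_models = sub_models, vocabulary = vocabulary,
                 ratio = config$ratio, config = config),
            class = "qsar_composite_model")
}

#' Fit a cocktail model
#'
#' Combines the full-training-set single model with the composite model's
#' balanced sub-models; all members carry equal weight in the prediction
#' average.
#'
#' @inheritParams fit_single
#' @return object of class `qsar_cocktail_model` with `full_model`,
#'   `sub_models`, and the shared `vocabulary`.
#' @export
fit_cocktail <- function(features, labels, vocabulary = NULL,
                         config = model_config()) {
  if (is.null(vocabulary)) {
    vocabulary <- build_vocabulary(features,
                                   min_frequency = config$min_frequency)
  }
  full <- fit_single(features, labels, vocabulary, config)
  comp <- fit_composite(features, labels, vocabulary, config)
  structure(list(full_model = full, sub_models = comp$sub_models,
                 vocabulary = vocabulary, config = config),
            class = "qsar_cocktail_model")
}

model_members <- function(model) {
  switch(class(model)[1],
         qsar_single_model = list(model),
         qsar_composite_model = model$sub_models,
         qsar_cocktail_model = c(list(model$full_model), model$sub_models),
         qc_error("not a qsar model"))
}

model_vocabulary <- function(model) {
  if (inherits(model, "qsar_single_model")) model$vocabulary
  else model$vocabulary
}

#' Predict positive prediction probabilities
#'
#' For ensemble models, the probability is the unweighted mean over the
#' members whose structural domain contains the query; a query inside no
#' member's structural domain has `p = NA` and is flagged out of the
#' structural domain.
#'
#' @param model a fitted `qsar_single_model`, `qsar_composite_model` or
#'   `qsar_cocktail_model`.
#' @param features a `feature_set` of the query structures (same catalog
#'   as training).
#' @return data.frame with `id`, `p`, `call`, `category`, `in_ad`,
#'   `max_similarity`, `n_contributing_members`.
#' @export
predict_probability <- function(model, features) {
  stopifnot(inherits(features, "feature_set"))
  vocab <- model_vocabulary(model)
  fp <- fingerprint(features, vocab)
  x_new <- design_matrix(features, vocab)
  members <- model_members(model)
  cfg <- model$config %||% model_config()

  n <- nrow(fp)
  p_mat <- matrix(NA_real_, n, length(members))
  dom_mat <- matrix(FALSE, n, length(members))
  sim_mat <- matrix(0, n, length(members))
  for (j in seq_along(members)) {
    dom <- in_structural_domain(fp, features$descriptors, members[[j]],
                                cfg$min_similarity)
    dom_mat[, j] <- dom$in_domain
    sim_mat[, j] <- dom$max_similarity
    p_mat[, j] <- .predict_member_p(members[[j]], x_new)
  }
  n_contrib <- rowSums(dom_mat)
  p <- vapply(seq_len(n), function(i) {
    if (n_contrib[i] == 0) NA_real_ else mean(p_mat[i, dom_mat[i, ]])
  }, numeric(1))
  category <- classify_outcome(p, in_structural = n_contrib > 0)
  data.frame(
    id = features$ids, p = p,
    call = ifelse(is.na(p), NA_character_, predict_call(p)),
    category = category, in_ad = in_ad(category),
    max_similarity = apply(sim_mat, 1, max),
    n_contributing_members = n_contrib,
    stringsAsFactors = FALSE
  )
}

#' Prediction call from a positive prediction probability
#'
#' @param p probability in `[0, 1]`.
#' @return `"active"` iff `p >= 0.5`, else `"inactive"`.
#' @export
predict_call <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    qc_error("probabilities must lie in [0, 1]")
  }
  ifelse(p >= 0.5, "active", "inactive")
}

#' @export
print.qsar_cocktail_model <- function(x, ...) {
  cat("Cocktail QSAR model: full model +", length(x$sub_models),
      "balanced sub-models;",
      x$full_model$n_active, "actives /", x$full_model$n_inactive,
      "inactives;", nrow(x$vocabulary), "vocabulary keys\n")
  invisible(x)
}

#' @export
print.qsar_single_model <- function(x, ...) {
  cat("Single PLR model:", x$n_active, "actives /", x$n_inactive,
      "inactives;", x$n_factors %||% 0, "factors;",
      length(x$columns %||% character(0)), "features\n")
  invisible(x)
}
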