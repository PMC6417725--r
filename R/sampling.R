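## Training/test splits and iterative training-set expansion.
##
## The study design: actives are split 90/10 into training and external
## test; a fixed-size random pool of inactives becomes the selection set
## from which training inactives are drawn (the remaining inactives are
## the external test inactives). The first model trains on a 2:1 random
## inactive draw; each "rational" iteration predicts the unused pool and
## adds an equal number of inactives from each of four prediction strata
## (out of structural domain, POS_OUT, NEG_OUT, and POS_IN -- the false
## positives). Final models add the test actives plus a multiple of
## randomly drawn pool inactives.

#' Split actives/inactives into training, test and selection pool
#'
#' @param active_ids,inactive_ids character id vectors.
#' @param test_active_frac fraction of actives for the external test set
#'   (default 0.10; rounded half-up).
#' @param pool_size size of the inactive selection pool; remaining
#'   inactives form the external test inactives.
#' @param seed integer seed.
#' @return object of class `split_plan`: list with `test_actives`,
#'   `train_actives`, `selection_pool`, `test_inactives`, `seed`.
#' @export
make_split <- function(active_ids, inactive_ids, test_active_frac = 0.10,
                       pool_size, seed) {
  if (pool_size > length(inactive_ids)) {
    qc_error("pool_size exceeds the number of inactives")
  }
  n_test <- round_half_up(length(active_ids) * test_active_frac)
  with_seed(seed_substream(seed, "split"), {
    test_act <- sample_ids(active_ids, n_test)
    pool <- sample_ids(inactive_ids, pool_size)
  })
  structure(list(
    test_actives = test_act,
    train_actives = setdiff(active_ids, test_act),
    selection_pool = pool,
    test_inactives = setdiff(inactive_ids, pool),
    seed = seed
  ), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf(
    "Split plan: %d/%d train/test actives; %d-inactive selection pool; %d test inactives\n",
    length(x$train_actives), length(x$test_actives),
    length(x$selection_pool), length(x$test_inactives)))
  invisible(x)
}

#' Initial random draw of training inactives
#'
#' @param pool character ids of the selection pool.
#' @param n_actives number of training actives.
#' @param ratio inactives per active (default 2, the initial "2:1" model).
#' @param seed integer seed.
#' @return character vector of `ratio * n_actives` inactive ids.
#' @export
initial_inactive_draw <- function(pool, n_actives, ratio = 2, seed) {
  n <- ratio * n_actives
  if (n > length(pool)) qc_error("selection pool too small for draw")
  with_seed(seed_substream(seed, "initial-draw"), sample_ids(pool, n))
}

EXPANSION_STRATA <- c("OUT_STRUCTURAL", "POS_OUT", "NEG_OUT", "POS_IN")

#' Rational expansion of the training inactives
#'
#' Predicts every candidate inactive in the current model, groups the
#' candidates into the four prediction outcome strata (out of structural
#' domain, POS_OUT, NEG_OUT, and POS_IN = false positives), and draws
#' `n_add / 4` uniformly from each. A stratum holding fewer than its share
#' contributes everything it has and the deficit is drawn from the largest
#' remaining stratum.
#'
#' If the union of the four strata holds fewer than `n_add` candidates
#' (possible only at desk scale), the whole union is taken and the deficit
#' is recorded in the `deficit` attribute of the lineage.
#'
#' @param model a fitted qsar model.
#' @param candidate_features `feature_set` of the candidate pool (selection
#'   pool minus current training inactives).
#' @param n_add total inactives to add (divisible by 4).
#' @param seed integer seed.
#' @return list with `ids` (selected inactive ids) and `lineage`
#'   (data.frame id / stratum / from_topup).
#' @export
rational_expand <- function(model, candidate_features, n_add, seed) {
  if (n_add %% 4 != 0) qc_error("n_add must be divisible by 4")
  pred <- predict_probability(model, candidate_features)
  strata <- lapply(EXPANSION_STRATA,
                   function(s) pred$id[pred$category == s])
  names(strata) <- EXPANSION_STRATA
  if (all(lengths(strata) == 0)) {
    qc_error("all expansion strata are empty")
  }
  per <- n_add / 4
  lineage <- with_seed(seed_substream(seed, "rational-expand"), {
    picked <- lapply(strata, function(s) sample_ids(s, min(per, length(s))))
    lin <- data.frame(
      id = unlist(picked, use.names = FALSE),
      stratum = rep(names(picked), lengths(picked)),
      from_topup = FALSE, stringsAsFactors = FALSE)
    deficit <- n_add - nrow(lin)
    while (deficit > 0) {
      remaining <- lapply(names(strata), function(s) {
        setdiff(strata[[s]], lin$id)
      })
      names(remaining) <- names(strata)
      sizes <- lengths(remaining)
      if (all(sizes == 0)) break  # strata exhausted; expansion falls short
      big <- names(sizes)[which.max(sizes)]
      take <- sample_ids(remaining[[big]], min(deficit, sizes[big]))
      qc_log("stratum shortfall: topping up %d from %s", length(take), big)
      lin <- rbind(lin, data.frame(
        id = take, stratum = big, from_topup = TRUE,
        stringsAsFactors = FALSE))
      deficit <- n_add - nrow(lin)
    }
    if (deficit > 0) {
      qc_log("expansion strata exhausted: %d short of n_add", deficit)
    }
    attr(lin, "deficit") <- deficit
    lin
  })
  list(ids = lineage$id, lineage = lineage)
}

#' Random (reference) expansion of the training inactives
#'
#' Size-matched control for [rational_expand()]: draws `n_add` candidates
#' uniformly.
#'
#' @param candidate_ids character ids of the candidate pool.
#' @param n_add number to add.
#' @param seed integer seed.
#' @return character vector of ids.
#' @export
random_expand <- function(candidate_ids, n_add, seed) {
  if (n_add > length(candidate_ids)) qc_error("candidate pool too small")
  with_seed(seed_substream(seed, "random-expand"),
            sample_ids(candidate_ids, n_add))
}

#' Assemble the final training set
#'
#' Adds the external-test actives plus `per_active_multiplier` times as
#' many pool inactives to an existing training set.
#'
#' @param train_active_ids,train_inactive_ids current training ids.
#' @param test_active_ids external test actives to merge in.
#' @param pool_remaining selection-pool inactives not yet in training.
#' @param per_active_multiplier inactives drawn per added active (default 4).
#' @param seed integer seed.
#' @return list with `active_ids`, `inactive_ids`, `added_inactives`.
#' @export
assemble_final <- function(train_active_ids, train_inactive_ids,
                           test_active_ids, pool_remaining,
                           per_active_multiplier = 4, seed) {
  if (length(intersect(test_active_ids, train_active_ids))) {
    qc_error("test actives overlap the training set")
  }
  n_new <- per_active_multiplier * length(test_active_ids)
  if (n_new > length(pool_remaining)) qc_error("selection pool exhausted")
  added <- with_seed(seed_substream(seed, "final-draw"),
                     sample_ids(pool_remaining, n_new))
  list(
    active_ids = c(train_active_ids, test_active_ids),
    inactive_ids = c(train_inactive_ids, added),
    added_inactives = added
  )
}
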