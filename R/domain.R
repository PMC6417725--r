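## Two-component applicability domain (AD).
##
## Component 1, the structural domain: a query is inside a member model's
## structural domain iff it has >= 30% Jaccard (Tanimoto) similarity to at
## least one training structure of that member, all model descriptors are
## computable, and it carries at least one structural feature used in the
## model. Component 2, the class-probability refinement: only confident
## predictions (p <= 0.3 or p >= 0.7) count as inside the AD; the grey zone
## in between is out of AD, split into named bands.

OUTCOME_CATEGORIES <- c("OUT_STRUCTURAL", "POS_IN", "NEG_IN", "NEG_OUT",
                        "INC_OUT", "POS_OUT")

#' Jaccard (Tanimoto) similarity of two binary fingerprints
#'
#' `|A intersect B| / |A union B|`, defined as 0 when both fingerprints are
#' empty.
#'
#' @param fp_a,fp_b binary vectors on the same vocabulary.
#' @return similarity in `[0, 1]`.
#' @export
jaccard_similarity <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) {
    qc_error("fingerprint length mismatch")
  }
  a <- fp_a != 0; b <- fp_b != 0
  uni <- sum(a | b)
  if (uni == 0) return(0)
  sum(a & b) / uni
}

## rowwise maximum Jaccard similarity of each query against a reference set
jaccard_max <- function(query_fp, ref_fp) {
  q <- query_fp != 0; r <- ref_fp != 0
  storage.mode(q) <- "numeric"; storage.mode(r) <- "numeric"
  inter <- q %*% t(r)
  uni <- outer(rowSums(q), rep(1, nrow(r))) +
    outer(rep(1, nrow(q)), rowSums(r)) - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  apply(sim, 1, max)
}

#' Structural-domain membership of queries against one member model
#'
#' @param query_fp binary fingerprint matrix of the queries (full model
#'   vocabulary).
#' @param query_desc descriptor matrix of the queries (`NA` = incalculable).
#' @param member a `qsar_single_model`.
#' @param min_similarity similarity threshold (inclusive; default 0.30).
#' @return data.frame with `in_domain`, `max_similarity`, and the three
#'   clause columns `similar_enough`, `descriptors_ok`, `has_model_feature`.
#' @export
in_structural_domain <- function(query_fp, query_desc, member,
                                 min_similarity = 0.30) {
  stopifnot(inherits(member, "qsar_single_model"))
  sim <- jaccard_max(query_fp, member$train_fp)
  desc_ok <- !apply(is.na(query_desc), 1, any)
  keys <- member$key_columns
  has_feat <- if (length(keys)) {
    rowSums(query_fp[, keys, drop = FALSE] != 0) > 0
  } else {
    rep(TRUE, nrow(query_fp))
  }
  data.frame(
    in_domain = sim >= min_similarity & desc_ok & has_feat,
    max_similarity = sim,
    similar_enough = sim >= min_similarity,
    descriptors_ok = desc_ok,
    has_model_feature = has_feat
  )
}

#' Classify a prediction into one of the six outcome categories
#'
#' Inside the structural domain the positive prediction probability bands
#' are: `NEG_IN` p <= 0.3, `NEG_OUT` 0.3 < p < 0.4, `INC_OUT`
#' 0.4 <= p < 0.5, `POS_OUT` 0.5 <= p < 0.7, `POS_IN` p >= 0.7. Out of the
#' structural domain every prediction is `OUT_STRUCTURAL`. Only `POS_IN`
#' and `NEG_IN` count as inside the applicability domain.
#'
#' @param p numeric vector of probabilities (`NA` = out of structural
#'   domain).
#' @param in_structural logical vector (default: `!is.na(p)`).
#' @return character vector of categories.
#' @export
#' @examples
#' classify_outcome(c(0.85, 0.3, 0.35, 0.45, 0.55))
classify_outcome <- function(p, in_structural = !is.na(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    qc_error("probabilities must lie in [0, 1]")
  }
  out <- rep("OUT_STRUCTURAL", length(p))
  ins <- in_structural & !is.na(p)
  pi <- p[ins]
  out[ins] <- ifelse(pi <= 0.3, "NEG_IN",
              ifelse(pi < 0.4, "NEG_OUT",
              ifelse(pi < 0.5, "INC_OUT",
              ifelse(pi < 0.7, "POS_OUT", "POS_IN"))))
  out
}

#' Is a prediction inside the applicability domain?
#'
#' @param category character vector of outcome categories.
#' @return logical; `TRUE` for `POS_IN` and `NEG_IN`.
#' @export
in_ad <- function(category) {
  category %in% c("POS_IN", "NEG_IN")
}

#' Coverage of a prediction set
#'
#' Fraction (in percent) of predictions inside the applicability domain.
#'
#' @param category character vector of outcome categories.
#' @return percentage in `[0, 100]`.
#' @export
coverage <- function(category) {
  if (!length(category)) return(NA_real_)
  100 * mean(in_ad(category))
}
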