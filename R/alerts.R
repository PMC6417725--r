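## Structural alert mining.
##
## Activity alerts are ranked by |baseline - xbar| * chi2, where xbar is
## the mean activity of the training structures containing the feature,
## the baseline is the active fraction of the whole training set (0.2 for
## a 1:4 actives:inactives set), and chi2 is the one-degree-of-freedom
## chi-square independence statistic with Yates' correction. The absolute
## difference term measures how over-represented the feature is in one
## class; the chi2 term its significance. Inactivity alerts are the
## "pure" inactivity features -- occurring in no active at all -- ranked
## by chi2 alone.

## per-feature 2x2 counts and chi2 against binary labels
.feature_counts <- function(feature_matrix, labels) {
  y <- as_binary_labels(labels)
  n_act <- sum(y == 1); n_inact <- sum(y == 0)
  with_act <- as.vector(crossprod(feature_matrix != 0, y))
  with_tot <- colSums(feature_matrix != 0)
  with_inact <- with_tot - with_act
  data.frame(
    feature = colnames(feature_matrix),
    n_active_with = with_act,
    n_inactive_with = with_inact,
    x_bar = ifelse(with_tot > 0, with_act / with_tot, NA_real_),
    chi2 = yates_chi2(with_act, n_act - with_act,
                      with_inact, n_inact - with_inact),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Rank features for association with activity
#'
#' @param feature_matrix binary matrix (structures x features), e.g. the
#'   model's selected key columns.
#' @param labels binary labels (1 = active).
#' @param baseline baseline active fraction; defaults to the active
#'   fraction of the scored training set.
#' @return data.frame of class `feature_scores`, sorted by descending
#'   `activity_score = |baseline - x_bar| * chi2`; ties break by chi2,
#'   then feature order. Features present in no structure are excluded.
#' @export
score_activity_features <- function(feature_matrix, labels,
                                    baseline = NULL) {
  y <- as_binary_labels(labels)
  if (is.null(baseline)) baseline <- mean(y)
  if (baseline <= 0 || baseline >= 1) {
    qc_error("baseline must lie in (0, 1)")
  }
  sc <- .feature_counts(feature_matrix, y)
  sc <- sc[!is.na(sc$x_bar), , drop = FALSE]
  sc$activity_score <- abs(baseline - sc$x_bar) * sc$chi2
  sc$pure_inactivity <- sc$n_active_with == 0
  ord <- order(-sc$activity_score, -sc$chi2, seq_len(nrow(sc)))
  sc <- sc[ord, , drop = FALSE]
  sc$rank <- seq_len(nrow(sc))
  rownames(sc) <- NULL
  attr(sc, "baseline") <- baseline
  class(sc) <- c("feature_scores", "data.frame")
  sc
}

#' Rank pure-inactivity features
#'
#' Restricts to features occurring in zero actives and ranks them by the
#' Yates chi-squared statistic alone.
#'
#' @inheritParams score_activity_features
#' @return data.frame of class `feature_scores` (possibly empty).
#' @export
score_inactivity_features <- function(feature_matrix, labels) {
  sc <- .feature_counts(feature_matrix, labels)
  sc <- sc[!is.na(sc$x_bar) & sc$n_active_with == 0, , drop = FALSE]
  sc$activity_score <- sc$chi2
  sc$pure_inactivity <- rep(TRUE, nrow(sc))
  ord <- order(-sc$chi2, seq_len(nrow(sc)))
  sc <- sc[ord, , drop = FALSE]
  if (nrow(sc)) sc$rank <- seq_len(nrow(sc))
  rownames(sc) <- NULL
  class(sc) <- c("feature_scores", "data.frame")
  sc
}

#' Top-k alert report
#'
#' Formats the top-k activity and inactivity features, with occurrence
#' counts displayed as "actives over inactives".
#'
#' @param activity_scores,inactivity_scores `feature_scores` tables.
#' @param k number of features per list (default 10).
#' @return list of class `alert_report` with `activity` and `inactivity`
#'   data.frames (columns incl. `display` = "n_active over n_inactive").
#' @export
report_top_features <- function(activity_scores, inactivity_scores,
                                k = 10) {
  top <- function(sc) {
    sc <- utils::head(sc, k)
    if (nrow(sc)) {
      sc$display <- sprintf("%d over %d", sc$n_active_with,
                            sc$n_inactive_with)
    } else {
      sc$display <- character(0)
    }
    as.data.frame(sc)
  }
  structure(list(activity = top(activity_scores),
                 inactivity = top(inactivity_scores), k = k),
            class = "alert_report")
}

#' @export
print.alert_report <- function(x, ...) {
  cat("Top", x$k, "activity alerts:\n")
  if (nrow(x$activity)) {
    print(x$activity[, c("rank", "feature", "display", "x_bar", "chi2",
                         "activity_score")], digits = 3)
  } else cat("  (none)\n")
  cat("Top", x$k, "inactivity alerts (pure):\n")
  if (nrow(x$inactivity)) {
    print(x$inactivity[, c("rank", "feature", "display", "chi2")],
          digits = 3)
  } else cat("  (none)\n")
  invisible(x)
}

#' Write an alert table to CSV
#'
#' @param scores a `feature_scores` table.
#' @param path output CSV path.
#' @export
write_alert_csv <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE)
  invisible(path)
}
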