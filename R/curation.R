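## Structure curation and activity labelling.
##
## Raw substance tables (id + SMILES + three assay scores) are turned into a
## unique, QSAR-ready, consistently labelled dataset by applying, in order:
## parse/error filter, element whitelist, dissociation + neutralization,
## mixture and low-carbon filters, canonicalization, score-based labelling
## and duplicate resolution. Every removal is recorded in a provenance log
## so that |input| = |kept| + removals + merged duplicates is checkable.

# atoms allowed in QSAR-ready structures
ELEMENT_WHITELIST <- c("H", "B", "C", "N", "O", "F", "Na", "Mg", "Si", "P",
                       "S", "Cl", "K", "Ca", "Br", "I")

CURATION_STATUSES <- c("KEPT", "REMOVED_ELEMENT", "REMOVED_ERROR",
                       "REMOVED_MIXTURE", "REMOVED_LOW_CARBON",
                       "REMOVED_DUPLICATE_CONFLICT", "MERGED_DUPLICATE")

.check_scores <- function(x, field) {
  bad <- !is.na(x) & (x < 0 | x > 100 | x != floor(x))
  if (any(bad)) {
    qc_error(sprintf("%s outside [0,100] for %d record(s)", field, sum(bad)))
  }
  invisible(x)
}

#' Assign an activity label from the three assay scores
#'
#' A substance is `ACTIVE` if its confirmatory score lies in 10-100 *and*
#' its luciferase counterscreen score is 0 (the counterscreen removes
#' luciferase stabilizers that masquerade as receptor activators);
#' `INACTIVE` if its primary-screen score is 0; otherwise `INCONCLUSIVE`.
#' The active rule takes precedence.
#'
#' @param primary_score,confirm_score,counter_score integer vectors of
#'   activity scores in `[0, 100]`, `NA` where the substance was not tested.
#' @return character vector: `"ACTIVE"`, `"INACTIVE"` or `"INCONCLUSIVE"`.
#' @export
#' @examples
#' assign_activity_label(40, 55, 0)    # ACTIVE
#' assign_activity_label(0, NA, NA)    # INACTIVE
#' assign_activity_label(40, 55, 30)   # INCONCLUSIVE (counterscreen positive)
assign_activity_label <- function(primary_score, confirm_score,
                                  counter_score) {
  .check_scores(primary_score, "primary_score")
  .check_scores(confirm_score, "confirm_score")
  .check_scores(counter_score, "counter_score")
  n <- max(length(primary_score), length(confirm_score),
           length(counter_score))
  primary_score <- rep_len(primary_score, n)
  confirm_score <- rep_len(confirm_score, n)
  counter_score <- rep_len(counter_score, n)
  active <- !is.na(confirm_score) & confirm_score >= 10 &
    confirm_score <= 100 & !is.na(counter_score) & counter_score == 0
  inactive <- !active & !is.na(primary_score) & primary_score == 0
  ifelse(active, "ACTIVE", ifelse(inactive, "INACTIVE", "INCONCLUSIVE"))
}

#' Element-whitelist check
#'
#' Keeps only structures whose atoms all belong to the whitelist
#' (H, B, C, N, O, F, Na, Mg, Si, P, S, Cl, K, Ca, Br, I). Applied to the
#' raw structure, before desalting.
#'
#' @param smiles character vector of SMILES.
#' @return data.frame with `keep` (logical) and `offending` (first
#'   non-whitelist element, or `NA`).
#' @export
check_elements <- function(smiles) {
  res <- lapply(smiles, function(s) {
    el <- smiles_elements(s)
    bad <- setdiff(el, ELEMENT_WHITELIST)
    if (length(bad)) list(keep = FALSE, offending = bad[1])
    else list(keep = TRUE, offending = NA_character_)
  })
  data.frame(keep = vapply(res, `[[`, logical(1), "keep"),
             offending = vapply(res, `[[`, character(1), "offending"),
             stringsAsFactors = FALSE)
}

#' Dissociate a structure and neutralize its components
#'
#' Ionic bonds are broken into connected components; each component's formal
#' charges are neutralized by proton addition or removal where chemically
#' valid (carboxylates, phenolates, alkoxides, thiolates are protonated;
#' protonated amines deprotonated). Components carrying a permanent charge
#' (quaternary nitrogen and the like) cannot be neutralized and flag the
#' record for removal. Inorganic counterions (no carbon) are kept only for
#' accounting.
#'
#' @param smiles character vector of parsable SMILES.
#' @param ids unique identifiers.
#' @return list of per-record lists with `components` (neutralized SMILES),
#'   `organic` (logical per component), `ok` (FALSE if any organic
#'   component could not be neutralized).
#' @export
desalt_and_neutralize <- function(smiles, ids) {
  check_ids(ids)
  comp_list <- lapply(smiles, smiles_components)
  flat <- unlist(comp_list)
  flat_ids <- unlist(lapply(seq_along(ids), function(i) {
    paste0(ids[i], "#", seq_along(comp_list[[i]]))
  }))
  neut <- if (length(flat)) {
    chem_canonical(flat, flat_ids, neutralize = TRUE)
  } else character(0)
  out <- vector("list", length(ids))
  names(out) <- ids
  k <- 0L
  for (i in seq_along(ids)) {
    nc <- length(comp_list[[i]])
    comps <- unname(neut[k + seq_len(nc)])
    k <- k + nc
    parse_ok <- !is.na(comps)
    organic <- logical(nc)
    residual <- logical(nc)
    for (j in seq_len(nc)) {
      if (!parse_ok[j]) next
      organic[j] <- smiles_carbon_count(comps[j]) >= 1
      residual[j] <- smiles_net_charge(comps[j]) != 0
    }
    out[[i]] <- list(
      components = comps, organic = organic,
      ok = all(parse_ok) && !any(residual & organic)
    )
  }
  out
}

#' Mixture and low-carbon filter
#'
#' Drops records with two or more organic components ("mixtures"; organic =
#' contains at least one carbon atom) and records whose single organic
#' component has fewer than two carbon atoms. Inorganic counterions never
#' count as organic.
#'
#' @param components one element of the [desalt_and_neutralize()] output.
#' @return list with `keep` (logical), `reason` (`NA`, `"REMOVED_MIXTURE"`
#'   or `"REMOVED_LOW_CARBON"`) and `parent` (the kept organic component or
#'   `NA`).
#' @export
filter_mixture_and_low_carbon <- function(components) {
  org <- components$components[components$organic]
  if (length(org) >= 2) {
    return(list(keep = FALSE, reason = "REMOVED_MIXTURE",
                parent = NA_character_))
  }
  if (length(org) == 0 || smiles_carbon_count(org) < 2) {
    return(list(keep = FALSE, reason = "REMOVED_LOW_CARBON",
                parent = NA_character_))
  }
  list(keep = TRUE, reason = NA_character_, parent = org)
}

#' Canonical SMILES
#'
#' Deterministic canonicalization: two SMILES of the same molecular graph
#' map to the same string, and the output is a fixed point of the function.
#' Stereochemistry is not encoded (duplicate detection is 2D).
#'
#' @param smiles character vector of SMILES.
#' @param ids optional identifiers (defaults to positions).
#' @return character vector of canonical SMILES (`NA` on failure).
#' @export
canonicalize <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("x%d", seq_along(smiles))
  unname(chem_canonical(smiles, ids))
}

#' Resolve duplicate structures
#'
#' Groups records by canonical SMILES. A concordant group keeps one
#' representative (the rest become `MERGED_DUPLICATE`); a group containing
#' both `ACTIVE` and `INACTIVE` labels is removed entirely
#' (`REMOVED_DUPLICATE_CONFLICT`). A group mixing `INCONCLUSIVE` with one
#' conclusive label keeps the conclusive label.
#'
#' @param records data.frame with `id`, `canonical_smiles`, `label` and
#'   `curation_status` columns; only rows with status `"KEPT"` are touched.
#' @return the records data.frame with updated statuses and labels.
#' @export
deduplicate <- function(records) {
  kept <- which(records$curation_status == "KEPT")
  groups <- split(kept, records$canonical_smiles[kept])
  for (g in groups) {
    if (length(g) < 2) next
    labs <- records$label[g]
    if (all(c("ACTIVE", "INACTIVE") %in% labs)) {
      records$curation_status[g] <- "REMOVED_DUPLICATE_CONFLICT"
      next
    }
    conclusive <- labs[labs != "INCONCLUSIVE"]
    rep_label <- if (length(conclusive)) conclusive[1] else "INCONCLUSIVE"
    rep_idx <- g[match(rep_label, labs)]
    records$label[rep_idx] <- rep_label
    records$curation_status[setdiff(g, rep_idx)] <- "MERGED_DUPLICATE"
  }
  records
}

#' Curate a raw substance table
#'
#' Runs the full curation workflow: parse/error filter, element whitelist,
#' dissociation and neutralization, mixture and low-carbon filters,
#' canonicalization, activity labelling and duplicate resolution.
#'
#' @param raw_table data.frame with columns `id`, `smiles`,
#'   `score_primary`, `score_confirm`, `score_counter` (missing scores
#'   `NA`). Extra columns are carried through.
#' @return an object of class `curated_dataset`: a list with `records`
#'   (all input rows plus `curation_status`, `canonical_smiles`, `label`),
#'   `provenance` (one row per non-kept record with the rule applied) and
#'   `counts` (per-rule removal counts).
#' @export
curate <- function(raw_table) {
  req <- c("id", "smiles", "score_primary", "score_confirm",
           "score_counter")
  if (!is.data.frame(raw_table) || nrow(raw_table) == 0) {
    qc_error("raw_table must be a non-empty data.frame")
  }
  miss <- setdiff(req, names(raw_table))
  if (length(miss)) {
    qc_error(paste("raw_table missing column(s):",
                   paste(miss, collapse = ", ")))
  }
  rec <- raw_table
  rec$id <- as.character(rec$id)
  check_ids(rec$id)
  n <- nrow(rec)
  rec$curation_status <- rep("KEPT", n)
  rec$canonical_smiles <- NA_character_
  rec$label <- NA_character_
  detail <- rep(NA_character_, n)

  # 1. parse/error filter
  ok <- chem_is_valid(rec$smiles, rec$id)
  rec$curation_status[!ok] <- "REMOVED_ERROR"
  detail[!ok] <- "unparsable structure"

  # 2. element whitelist on the raw structure
  live <- rec$curation_status == "KEPT"
  if (any(live)) {
    el <- check_elements(rec$smiles[live])
    bad <- which(live)[!el$keep]
    rec$curation_status[bad] <- "REMOVED_ELEMENT"
    detail[bad] <- paste("element", el$offending[!el$keep])
  }

  # 3. dissociate + neutralize; 4. mixture / low-carbon filter
  live <- which(rec$curation_status == "KEPT")
  if (length(live)) {
    parts <- desalt_and_neutralize(rec$smiles[live], rec$id[live])
    for (k in seq_along(live)) {
      i <- live[k]
      if (!parts[[k]]$ok) {
        rec$curation_status[i] <- "REMOVED_ERROR"
        detail[i] <- "non-neutralizable charge"
        next
      }
      f <- filter_mixture_and_low_carbon(parts[[k]])
      if (!f$keep) {
        rec$curation_status[i] <- f$reason
      } else {
        rec$canonical_smiles[i] <- f$parent
      }
    }
  }

  # 5. canonical form is the neutralized parent (already canonical);
  # 6. labelling from the stored scores
  live <- rec$curation_status == "KEPT"
  rec$label[live] <- assign_activity_label(
    rec$score_primary[live], rec$score_confirm[live],
    rec$score_counter[live])

  # 7. duplicate resolution
  rec <- deduplicate(rec)
  merged <- rec$curation_status == "MERGED_DUPLICATE"
  rec$canonical_smiles[!(rec$curation_status %in%
                           c("KEPT", "MERGED_DUPLICATE"))] <- NA_character_

  not_kept <- rec$curation_status != "KEPT"
  provenance <- data.frame(
    id = rec$id[not_kept],
    rule = rec$curation_status[not_kept],
    detail = detail[not_kept],
    stringsAsFactors = FALSE
  )
  counts <- table(factor(rec$curation_status, levels = CURATION_STATUSES))
  qc_log("curation: %d in, %d kept", n, sum(!not_kept))
  structure(list(records = rec, provenance = provenance,
                 counts = as.list(counts)),
            class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat("Curated dataset:", nrow(x$records), "records,",
      x$counts$KEPT, "kept\n")
  nz <- Filter(function(v) v > 0, x$counts)
  for (nm in setdiff(names(nz), "KEPT")) {
    cat(sprintf("  %-27s %d\n", nm, nz[[nm]]))
  }
  lab <- table(x$records$label[x$records$curation_status == "KEPT"])
  if (length(lab)) {
    cat("  labels:", paste(names(lab), lab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Kept records of a curated dataset
#'
#' @param dataset a `curated_dataset`.
#' @param modelling drop `INCONCLUSIVE` records (only actives/inactives
#'   enter modelling).
#' @return data.frame of kept records.
#' @export
kept_records <- function(dataset, modelling = FALSE) {
  stopifnot(inherits(dataset, "curated_dataset"))
  out <- dataset$records[dataset$records$curation_status == "KEPT", ]
  if (modelling) out <- out[out$label %in% c("ACTIVE", "INACTIVE"), ]
  rownames(out) <- NULL
  out
}

#' Read a substance table from CSV
#'
#' Expected columns: `id`, `smiles`, `score_primary`, `score_confirm`,
#' `score_counter` (blank = not tested).
#'
#' @param path CSV file path.
#' @return data.frame ready for [curate()].
#' @export
read_substance_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(id = "character", smiles = "character"))
}

#' Write curation outputs to CSV
#'
#' Writes `<stem>_kept.csv` (id, canonical_smiles, label) and
#' `<stem>_provenance.csv`.
#'
#' @param dataset a `curated_dataset`.
#' @param stem output path stem.
#' @return invisibly, the two file paths.
#' @export
write_curated_csv <- function(dataset, stem) {
  stopifnot(inherits(dataset, "curated_dataset"))
  kept <- kept_records(dataset)[, c("id", "canonical_smiles", "label")]
  fk <- paste0(stem, "_kept.csv")
  fp <- paste0(stem, "_provenance.csv")
  utils::write.csv(kept, fk, row.names = FALSE)
  utils::write.csv(dataset$provenance, fp, row.names = FALSE)
  invisible(c(fk, fp))
}
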