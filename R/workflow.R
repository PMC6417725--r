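## Workflow orchestration.
##
## One config drives the full study: curate -> split -> initial 2:1 fit ->
## iterative rational (and random reference) training-set expansions ->
## final-model assembly -> cross-validation, Y-randomization and external
## validation -> alert ranking -> screening summary. All randomness flows
## from one master seed through named substreams, and a manifest records
## seeds, stage order, counts and output hashes so two runs with the same
## config are byte-identical.

#' Study configuration
#'
#' Defaults describe a desk-scale synthetic study; pass `input_csv` to run
#' on real data instead of the generator.
#'
#' @param seed master seed.
#' @param input_csv optional substance CSV (id, smiles, three scores);
#'   when `NULL` a synthetic universe is generated from `fixture`.
#' @param fixture a [fixture_config()] for the synthetic universe.
#' @param test_active_frac external-test fraction of actives.
#' @param pool_size inactive selection-pool size (default: 80% of the
#'   curated inactives).
#' @param schedule increasing inactive:active ratios of the iterative
#'   models (default `c(2, 3, 4)`).
#' @param final_multiplier pool inactives added per test active in the
#'   final models.
#' @param repeats,folds cross-validation plan.
#' @param prevalences assumed prevalences of actives.
#' @param model a [model_config()].
#' @param arms model arms to run: subset of `c("rational", "random")`.
#' @param output_dir optional directory for CSV/JSON artifacts.
#' @return list of class `study_config`.
#' @export
study_config <- function(seed = 1, input_csv = NULL,
                         fixture = fixture_config(
                           n_active = 64, n_inactive = 800,
                           decoy_rate = 0.12, seed = seed),
                         test_active_frac = 0.10, pool_size = NULL,
                         schedule = c(2, 3, 4), final_multiplier = 4,
                         repeats = 2, folds = 5,
                         prevalences = c(0.01, 0.05, 0.10),
                         model = model_config(seed = seed),
                         arms = c("rational", "random"),
                         output_dir = NULL) {
  if (any(diff(schedule) <= 0)) {
    qc_error("schedule ratios must be strictly increasing")
  }
  structure(as.list(environment()), class = "study_config")
}

#' Screen structures through a fitted model
#'
#' @param model a fitted qsar model.
#' @param features a `feature_set` of the structures to screen (or a
#'   data.frame with `id` and `smiles`, which is featurized first).
#' @return list of class `screen_result` with `predictions` (per-structure
#'   rows) and `summary` (coverage and POS_IN/NEG_IN counts with
#'   percentages of the covered set).
#' @export
run_screen <- function(model, features) {
  if (is.data.frame(features)) {
    if (nrow(features) == 0) qc_error("no structures to screen")
    features <- featurize(features$smiles, features$id)
  }
  pred <- predict_probability(model, features)
  n <- nrow(pred)
  covered <- sum(pred$in_ad)
  pos_in <- sum(pred$category == "POS_IN")
  neg_in <- sum(pred$category == "NEG_IN")
  summary <- list(
    n = n, covered = covered,
    coverage_pct = 100 * covered / n,
    pos_in = pos_in,
    pos_in_pct_of_covered = if (covered) 100 * pos_in / covered else NA,
    neg_in = neg_in,
    neg_in_pct_of_covered = if (covered) 100 * neg_in / covered else NA
  )
  structure(list(predictions = pred, summary = summary),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Screened %d structures: %d covered (%.1f%%), POS_IN %d (%.1f%%), NEG_IN %d (%.1f%%)\n",
              s$n, s$covered, s$coverage_pct, s$pos_in,
              s$pos_in_pct_of_covered, s$neg_in, s$neg_in_pct_of_covered))
  invisible(x)
}

## fit one arm's iterative series; returns models + training id lineage
.run_arm <- function(arm, features, labels_by_id, split, cfg) {
  ratios <- cfg$schedule
  train_act <- split$train_actives
  models <- list(); lineages <- list()
  inact <- initial_inactive_draw(split$selection_pool, length(train_act),
                                 ratios[1],
                                 seed_substream(cfg$seed, paste0(arm, "-init")))
  for (k in seq_along(ratios)) {
    rows <- c(train_act, inact)
    mc <- cfg$model
    mc$seed <- seed_substream(cfg$seed, sprintf("%s-fit-%d", arm, k))
    model <- fit_cocktail(features[rows], labels_by_id[rows], config = mc)
    models[[sprintf("%d:1", ratios[k])]] <- model
    if (k < length(ratios)) {
      n_add <- (ratios[k + 1] - ratios[k]) * length(train_act)
      n_add <- 4 * floor(n_add / 4)
      cand <- setdiff(split$selection_pool, inact)
      if (arm == "rational") {
        ex <- rational_expand(model, features[cand], n_add,
                              seed_substream(cfg$seed,
                                             sprintf("expand-%d", k)))
        lineages[[k]] <- ex$lineage
        inact <- c(inact, ex$ids)
      } else {
        add <- random_expand(cand, n_add,
                             seed_substream(cfg$seed,
                                            sprintf("rand-expand-%d", k)))
        lineages[[k]] <- data.frame(id = add, stratum = "RANDOM",
                                    from_topup = FALSE,
                                    stringsAsFactors = FALSE)
        inact <- c(inact, add)
      }
    }
  }
  # final model: merge test actives + multiplier x inactives from the pool
  fin <- assemble_final(train_act, inact, split$test_actives,
                        setdiff(split$selection_pool, inact),
                        cfg$final_multiplier,
                        seed_substream(cfg$seed, paste0(arm, "-final")))
  rows <- c(fin$active_ids, fin$inactive_ids)
  mc <- cfg$model
  mc$seed <- seed_substream(cfg$seed, paste0(arm, "-fit-final"))
  models[["final"]] <- fit_cocktail(features[rows], labels_by_id[rows],
                                    config = mc)
  list(models = models, train_inactives = inact, final_ids = fin,
       lineages = lineages)
}

#' Run the full study workflow
#'
#' Executes curation, splitting, the iterative rational and random
#' modelling arms, final-model assembly, cross-validation,
#' Y-randomization, external validation, alert ranking and a screening
#' summary, and (optionally) writes all artifacts plus a manifest.
#'
#' @param config a [study_config()].
#' @return list of class `study_result` with elements `curated`, `split`,
#'   `arms` (models and lineages per arm), `validation` (per model),
#'   `alerts`, `screen`, `manifest`.
#' @export
run_full_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  stages <- character(0)
  stage <- function(nm) {
    stages <<- c(stages, nm)
    qc_log("stage: %s", nm)
  }

  stage("curate")
  raw <- if (!is.null(config$input_csv)) {
    read_substance_csv(config$input_csv)
  } else {
    generate_fixture(config$fixture)
  }
  curated <- curate(raw)
  rec <- kept_records(curated, modelling = TRUE)

  stage("featurize")
  features <- featurize(rec$canonical_smiles, rec$id)
  labels_by_id <- stats::setNames(as.integer(rec$label == "ACTIVE"),
                                  rec$id)

  stage("split")
  act <- rec$id[rec$label == "ACTIVE"]
  inact <- rec$id[rec$label == "INACTIVE"]
  pool_size <- config$pool_size %||% floor(0.8 * length(inact))
  split <- make_split(act, inact, config$test_active_frac, pool_size,
                      seed = config$seed)

  arms <- list()
  for (arm in config$arms) {
    stage(paste0("arm-", arm))
    arms[[arm]] <- .run_arm(arm, features, labels_by_id, split, config)
  }

  stage("validate")
  test_ids <- c(split$test_actives, split$test_inactives)
  validation <- list()
  for (arm in names(arms)) {
    for (nm in names(arms[[arm]]$models)) {
      model <- arms[[arm]]$models[[nm]]
      key <- paste(arm, nm, sep = "-")
      is_final <- nm == "final"
      ext_ids <- if (is_final) split$test_inactives else test_ids
      ext_lab <- labels_by_id[ext_ids]
      validation[[key]] <- list(
        external = external_validate(model, features[ext_ids], ext_lab,
                                     config$prevalences))
      if (is_final) {
        rows <- c(arms[[arm]]$final_ids$active_ids,
                  arms[[arm]]$final_ids$inactive_ids)
        mc <- config$model
        mc$seed <- seed_substream(config$seed, paste0(arm, "-cv"))
        validation[[key]]$crossvalidation <- crossvalidate(
          features[rows], labels_by_id[rows], config$repeats,
          config$folds, seed = seed_substream(config$seed,
                                              paste0(arm, "-cv-folds")),
          config = mc, prevalences = config$prevalences)
        validation[[key]]$y_randomization <- y_randomize(
          features[rows], labels_by_id[rows], config$repeats,
          config$folds, seed = seed_substream(config$seed,
                                              paste0(arm, "-yrand")),
          config = mc)
      }
    }
  }

  stage("alerts")
  alerts <- list()
  for (arm in names(arms)) {
    fin <- arms[[arm]]$final_ids
    rows <- c(fin$active_ids, fin$inactive_ids)
    model <- arms[[arm]]$models[["final"]]
    fp <- fingerprint(features[rows], model$vocabulary)
    keys <- model$full_model$key_columns
    fm <- fp[, keys, drop = FALSE]
    y <- labels_by_id[rows]
    alerts[[arm]] <- report_top_features(
      score_activity_features(fm, y),
      score_inactivity_features(fm, y))
  }

  stage("screen")
  screen <- list()
  for (arm in names(arms)) {
    screen[[arm]] <- run_screen(arms[[arm]]$models[["final"]],
                                features[test_ids])
  }

  manifest <- list(
    seed = config$seed, stages = stages,
    n_input = nrow(raw), n_kept = nrow(kept_records(curated)),
    n_modelling = nrow(rec),
    n_train_actives = length(split$train_actives),
    n_test_actives = length(split$test_actives),
    pool_size = pool_size,
    schedule = config$schedule, arms = config$arms,
    timestamp = NULL
  )

  result <- structure(list(
    curated = curated, split = split, features = features, arms = arms,
    validation = validation, alerts = alerts, screen = screen,
    manifest = manifest, config = config
  ), class = "study_result")

  if (!is.null(config$output_dir)) {
    write_study_outputs(result, config$output_dir)
  }
  result
}

#' Write study artifacts to a directory
#'
#' Kept/provenance CSVs, per-model prediction CSVs, validation JSON,
#' alert CSVs and a manifest JSON with md5 hashes of every written file.
#'
#' @param result a `study_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_study_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_curated_csv(result$curated, file.path(dir, "curated"))
  for (arm in names(result$arms)) {
    for (k in seq_along(result$arms[[arm]]$lineages)) {
      utils::write.csv(result$arms[[arm]]$lineages[[k]],
                       file.path(dir, sprintf("%s_lineage_%d.csv", arm, k)),
                       row.names = FALSE)
    }
    utils::write.csv(result$screen[[arm]]$predictions,
                     file.path(dir, sprintf("%s_screen.csv", arm)),
                     row.names = FALSE)
    write_alert_csv(result$alerts[[arm]]$activity,
                    file.path(dir, sprintf("%s_activity_alerts.csv", arm)))
    write_alert_csv(result$alerts[[arm]]$inactivity,
                    file.path(dir, sprintf("%s_inactivity_alerts.csv", arm)))
  }
  val <- lapply(result$validation, function(v) {
    lapply(v, function(r) {
      r$predictions <- NULL
      r$randomized_labels <- NULL
      r$per_fold <- NULL
      unclass(r)
    })
  })
  jsonlite::write_json(val, file.path(dir, "validation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  files <- setdiff(list.files(dir, full.names = TRUE),
                   file.path(dir, "manifest.json"))
  manifest <- result$manifest
  manifest$files <- as.list(tools::md5sum(files))
  names(manifest$files) <- basename(files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(file.path(dir, "manifest.json"))
}

#' Read a study configuration from a YAML file
#'
#' Top-level keys mirror the [study_config()] arguments; nested `fixture:`
#' and `model:` blocks mirror [fixture_config()] and [model_config()].
#' Unknown keys raise an error.
#'
#' @param path YAML file path.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    qc_error(paste("unknown config key(s):", paste(bad, collapse = ", ")))
  }
  seed <- raw$seed %||% 1
  if (!is.null(raw$fixture)) {
    raw$fixture <- do.call(fixture_config,
                           utils::modifyList(list(seed = seed),
                                             raw$fixture))
  }
  if (!is.null(raw$model)) {
    raw$model <- do.call(model_config,
                         utils::modifyList(list(seed = seed), raw$model))
  }
  do.call(study_config, raw)
}

#' @export
print.study_result <- function(x, ...) {
  m <- x$manifest
  cat("Study result:", m$n_input, "input,", m$n_modelling,
      "modelling records;", "arms:", paste(m$arms, collapse = "/"), "\n")
  for (key in names(x$validation)) {
    ext <- x$validation[[key]]$external
    cat(sprintf("  %-16s ext spec %.1f%%  sens %s  coverage %.1f%%\n",
                key, ext$cooper$specificity,
                ifelse(is.na(ext$cooper$sensitivity), "NA",
                       sprintf("%.1f%%", ext$cooper$sensitivity)),
                ext$ad_pct))
  }
  invisible(x)
}
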