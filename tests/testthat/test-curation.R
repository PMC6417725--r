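# Curation: labelling rules, structure filters, deduplication, and the
# end-to-end workflow invariants.

test_that("activity labelling follows the counterscreen-aware rules", {
  # confirmed active: positive retest, clean counterscreen
  expect_equal(assign_activity_label(40, 55, 0), "ACTIVE")
  # zero primary score is inactive
  expect_equal(assign_activity_label(0, NA, NA), "INACTIVE")
  # counterscreen-positive fails the active rule; nonzero primary fails
  # the inactive rule
  expect_equal(assign_activity_label(40, 55, 30), "INCONCLUSIVE")
  # confirmatory score below 10 is not a confirmed active
  expect_equal(assign_activity_label(40, 5, 0), "INCONCLUSIVE")
  # untested confirm/counter with nonzero primary
  expect_equal(assign_activity_label(40, NA, NA), "INCONCLUSIVE")
  # vectorized
  expect_equal(assign_activity_label(c(40, 0), c(55, NA), c(0, NA)),
               c("ACTIVE", "INACTIVE"))
  # score validation names the offending field
  expect_error(assign_activity_label(150, NA, NA), "primary_score")
  expect_error(assign_activity_label(0, -3, NA), "confirm_score")
})

test_that("element whitelist keeps organics and drops exotic atoms", {
  res <- check_elements(c("c1ccccc1", "CC[Se]CC", "[Fe+2].[O-]C(=O)C",
                          "CC(=O)[O-].[Na+]"))
  expect_equal(res$keep, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(res$offending, c(NA, "Se", "Fe", NA))
})

test_that("dissociation and neutralization produce neutral parents", {
  out <- desalt_and_neutralize(
    c("CC(=O)[O-].[Na+]", "c1ccccc1", "C[N+](C)(C)C.[Cl-]", "CC[NH3+]"),
    c("salt", "neutral", "quat", "amine"))
  # sodium acetate: protonated acid + inorganic counterion
  expect_true(out$salt$ok)
  expect_setequal(out$salt$components[out$salt$organic], "CC(=O)O")
  expect_equal(sum(!out$salt$organic), 1)
  # identity on a neutral single component
  expect_true(out$neutral$ok)
  expect_equal(out$neutral$components, "c1ccccc1")
  # permanent quaternary charge cannot be neutralized
  expect_false(out$quat$ok)
  # protonated amine is deprotonated
  expect_true(out$amine$ok)
  expect_equal(qsarcocktail:::smiles_net_charge(
    out$amine$components[out$amine$organic]), 0)
})

test_that("mixture and low-carbon filters apply to organic components", {
  dn <- desalt_and_neutralize(c("CCO.CCN", "C", "CCO", "O.[Na+]"),
                              c("mix", "methane", "ethanol", "inorg"))
  expect_equal(filter_mixture_and_low_carbon(dn$mix)$reason,
               "REMOVED_MIXTURE")
  expect_equal(filter_mixture_and_low_carbon(dn$methane)$reason,
               "REMOVED_LOW_CARBON")
  keep <- filter_mixture_and_low_carbon(dn$ethanol)
  expect_true(keep$keep)
  expect_equal(keep$parent, "CCO")
  # zero organic components counts as low carbon
  expect_equal(filter_mixture_and_low_carbon(dn$inorg)$reason,
               "REMOVED_LOW_CARBON")
})

test_that("canonicalization is graph-invariant and idempotent", {
  expect_equal(canonicalize("OCC"), canonicalize("CCO"))
  expect_equal(canonicalize("c1ccccc1"), canonicalize("C1=CC=CC=C1"))
  once <- canonicalize("N(C)c1ccc2occc2c1")
  expect_equal(canonicalize(once), once)
  expect_true(is.na(canonicalize("not_a_smiles")))
})

test_that("deduplication keeps one concordant representative and drops conflicts", {
  rec <- data.frame(
    id = c("a", "b", "c", "d", "e"),
    canonical_smiles = c("CCO", "CCO", "CCN", "CCN", "CCC"),
    label = c("ACTIVE", "ACTIVE", "ACTIVE", "INACTIVE", "INACTIVE"),
    curation_status = "KEPT", stringsAsFactors = FALSE)
  out <- deduplicate(rec)
  expect_setequal(out$curation_status[out$id %in% c("a", "b")],
                  c("KEPT", "MERGED_DUPLICATE"))
  expect_equal(out$curation_status[out$id %in% c("c", "d")],
               rep("REMOVED_DUPLICATE_CONFLICT", 2))
  expect_equal(out$curation_status[out$id == "e"], "KEPT")
  # inconclusive paired with one conclusive keeps the conclusive label
  rec2 <- data.frame(
    id = c("x", "y"), canonical_smiles = "CCO",
    label = c("INCONCLUSIVE", "ACTIVE"),
    curation_status = "KEPT", stringsAsFactors = FALSE)
  out2 <- deduplicate(rec2)
  expect_equal(out2$label[out2$curation_status == "KEPT"], "ACTIVE")
})

test_that("curate traces the six-record toy table to two kept structures", {
  toy <- data.frame(
    id = paste0("t", 1:6),
    smiles = c("CC[Se]CC", "CC(=O)[O-].[Na+]", "CCO.CCN", "C",
               "OCC", "CCO"),
    score_primary = c(0, 0, 0, 0, 40, 40),
    score_confirm = c(NA, NA, NA, NA, 55, 55),
    score_counter = c(NA, NA, NA, NA, 0, 0),
    stringsAsFactors = FALSE)
  cd <- curate(toy)
  expect_equal(cd$counts$KEPT, 2)
  expect_equal(cd$counts$REMOVED_ELEMENT, 1)
  expect_equal(cd$counts$REMOVED_MIXTURE, 1)
  expect_equal(cd$counts$REMOVED_LOW_CARBON, 1)
  expect_equal(cd$counts$MERGED_DUPLICATE, 1)
  kept <- kept_records(cd)
  expect_setequal(kept$canonical_smiles, c("CC(=O)O", "CCO"))
  expect_setequal(kept$label, c("INACTIVE", "ACTIVE"))
  # provenance covers every non-kept record
  expect_equal(nrow(cd$provenance), 4)
})

test_that("curation is idempotent, unique, conservative and label-consistent", {
  cfg <- fixture_config(
    n_active = 25, n_inactive = 75, interferer_fraction = 0.1,
    contaminant_rates = list(salt = 0.06, mixture = 0.04, low_carbon = 0.04,
                             bad_element = 0.04, duplicate_concordant = 0.05,
                             duplicate_conflict = 0.03),
    seed = 17)
  tbl <- generate_fixture(cfg)
  cd <- curate(tbl)
  rec <- cd$records

  # ground truth from the generator matches rule-by-rule
  removed_classes <- c("REMOVED_MIXTURE", "REMOVED_LOW_CARBON",
                       "REMOVED_ELEMENT", "REMOVED_DUPLICATE_CONFLICT")
  for (cls in removed_classes) {
    expect_setequal(rec$id[rec$curation_status == cls],
                    tbl$id[tbl$expected_status == cls])
  }
  # duplicate groups: one representative kept, the rest merged
  expect_equal(sum(rec$curation_status == "MERGED_DUPLICATE"),
               sum(tbl$expected_status == "MERGED_DUPLICATE"))
  expect_equal(sum(rec$curation_status == "KEPT"),
               sum(tbl$expected_status == "KEPT"))

  # conservation: every input accounted for
  expect_equal(sum(unlist(cd$counts)), nrow(tbl))
  expect_equal(nrow(cd$provenance),
               sum(rec$curation_status != "KEPT"))

  # uniqueness: kept canonical SMILES pairwise distinct, no conflicts
  kept <- kept_records(cd)
  expect_equal(anyDuplicated(kept$canonical_smiles), 0)

  # label function: stored label re-derivable from stored scores
  expect_equal(kept$label,
               assign_activity_label(kept$score_primary,
                                     kept$score_confirm,
                                     kept$score_counter))

  # idempotence: curating the kept output changes nothing
  again <- curate(data.frame(
    id = kept$id, smiles = kept$canonical_smiles,
    score_primary = kept$score_primary,
    score_confirm = kept$score_confirm,
    score_counter = kept$score_counter, stringsAsFactors = FALSE))
  kept2 <- kept_records(again)
  expect_equal(nrow(kept2), nrow(kept))
  expect_equal(kept2$canonical_smiles, kept$canonical_smiles)
  expect_equal(kept2$label, kept$label)
})

test_that("curate rejects empty input and passes clean tables untouched", {
  expect_error(curate(data.frame()), "non-empty")
  clean <- data.frame(id = c("a", "b"), smiles = c("CCO", "CCCN"),
                      score_primary = c(0, 0), score_confirm = NA,
                      score_counter = NA, stringsAsFactors = FALSE)
  cd <- curate(clean)
  expect_equal(cd$counts$KEPT, 2)
  expect_equal(nrow(cd$provenance), 0)
})

test_that("curated CSV round-trips through the readers and writers", {
  clean <- data.frame(id = c("a", "b"), smiles = c("CCO", "c1ccccc1CC"),
                      score_primary = c(40, 0), score_confirm = c(55, NA),
                      score_counter = c(0, NA), stringsAsFactors = FALSE)
  cd <- curate(clean)
  stem <- file.path(withr::local_tempdir(), "cur")
  files <- write_curated_csv(cd, stem)
  kept <- utils::read.csv(files[1], stringsAsFactors = FALSE)
  expect_equal(kept$label, c("ACTIVE", "INACTIVE"))
  raw <- utils::write.csv(clean, file.path(dirname(stem), "raw.csv"),
                          row.names = FALSE)
  back <- read_substance_csv(file.path(dirname(stem), "raw.csv"))
  expect_equal(back$smiles, clean$smiles)
})
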