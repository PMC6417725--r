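## Synthetic chemistry and assay-score generator.
##
## Molecules are assembled from a small grammar of "appendable" SMILES
## fragments: every fragment is written so that plain string concatenation of
## any sequence yields a valid SMILES (rings close internally, the last atom
## of each fragment is a substitutable carbon). Activity is planted as
## heteroaromatic alert substructures (indole, pyrrole, benzofuran,
## pyrimidine-like) carried by a configurable fraction of actives;
## inactivity motifs (sulfonamide, carboxylic acid) are carried
## preferentially by inactives. A configurable fraction of inactives are
## "decoys" that carry an activity alert despite an inactive label, which
## emulates the false-positive-prone inactives the rational selection
## strategy targets. Assay-score triples (primary screen, confirmatory
## triplicate, luciferase counterscreen) are generated to be consistent with
## the labelling rules, with optional interferers and label noise.

# appendable neutral fragments, whitelist elements only
.neutral_frags <- c("C", "CC", "CCC", "CO", "CN", "CCO", "CCN", "C(=O)",
                    "c1ccccc1", "C1CCCCC1", "c1ccncc1", "C1CCOC1")

# activity alert motifs: appendable fragment + SMARTS that detects it
.alert_motifs <- list(
  indole     = list(frag = "c1ccc2[nH]ccc2c1", smarts = "c1ccc2[nH]ccc2c1"),
  pyrrole    = list(frag = "c1cc[nH]c1",       smarts = "c1cc[nH]c1"),
  benzofuran = list(frag = "c1ccc2occc2c1",    smarts = "c1ccc2occc2c1"),
  pyrimidine = list(frag = "c1cncnc1",         smarts = "c1cncnc1")
)

# inactivity motifs; "terminal" fragments may only close a molecule
.inactivity_motifs <- list(
  sulfonamide     = list(frag = "S(=O)(=O)N", smarts = "S(=O)(=O)N",
                         terminal = FALSE),
  carboxylic_acid = list(frag = "C(=O)O", smarts = "C(=O)[OX2H1]",
                         terminal = TRUE)
)

#' Configuration for the synthetic fixture generator
#'
#' Defaults generate a modelling-scale fixture: 200 actives and 800
#' inactives, 90% alert penetrance, clean labels and no contaminants.
#' Contaminant rates are fractions of the base table that are added as (or
#' converted into) salts, mixtures, low-carbon species, disallowed-element
#' species, and duplicate pairs with concordant or conflicting labels.
#'
#' @param n_active,n_inactive class sizes of the base table.
#' @param alert_penetrance fraction of actives carrying a planted activity
#'   alert substructure.
#' @param decoy_rate fraction of inactives carrying an activity alert
#'   (false-positive-prone structural decoys).
#' @param inactive_motif_rate fraction of inactives carrying an inactivity
#'   motif (sulfonamide / carboxylic acid).
#' @param label_noise fraction of records whose assay scores are generated
#'   for the opposite class.
#' @param interferer_fraction fraction of actives turned into luciferase
#'   interferers (positive counterscreen, ground truth inconclusive).
#' @param contaminant_rates named list with elements `salt`, `mixture`,
#'   `low_carbon`, `bad_element`, `duplicate_concordant`,
#'   `duplicate_conflict`; each a fraction in `[0, 1]`.
#' @param seed master seed for the generator.
#' @return a list of class `fixture_config`.
#' @export
fixture_config <- function(n_active = 200, n_inactive = 800,
                           alert_penetrance = 0.9,
                           decoy_rate = 0.05,
                           inactive_motif_rate = 0.5,
                           label_noise = 0,
                           interferer_fraction = 0,
                           contaminant_rates = list(),
                           seed = 1) {
  rates <- list(salt = 0, mixture = 0, low_carbon = 0, bad_element = 0,
                duplicate_concordant = 0, duplicate_conflict = 0)
  rates[names(contaminant_rates)] <- contaminant_rates
  fr <- c(alert_penetrance, decoy_rate, inactive_motif_rate, label_noise,
          interferer_fraction, unlist(rates))
  if (any(fr < 0 | fr > 1)) qc_error("fractions must lie in [0, 1]")
  if (n_active < 0 || n_inactive < 0) qc_error("counts must be >= 0")
  structure(list(
    n_active = n_active, n_inactive = n_inactive,
    alert_penetrance = alert_penetrance, decoy_rate = decoy_rate,
    inactive_motif_rate = inactive_motif_rate, label_noise = label_noise,
    interferer_fraction = interferer_fraction,
    contaminant_rates = rates, seed = seed
  ), class = "fixture_config")
}

#' SMARTS patterns of the planted activity alerts
#' @return named character vector of SMARTS.
#' @export
alert_smarts <- function() {
  vapply(.alert_motifs, `[[`, character(1), "smarts")
}

#' SMARTS patterns of the planted inactivity motifs
#' @return named character vector of SMARTS.
#' @export
inactivity_smarts <- function() {
  vapply(.inactivity_motifs, `[[`, character(1), "smarts")
}

# one random molecule: fragment chain in the 5-40 heavy-atom range,
# optionally carrying a named motif
.assemble_molecule <- function(motif_frag = NULL, terminal = FALSE) {
  n_frag <- sample(2:5, 1)
  frags <- sample(.neutral_frags, n_frag, replace = TRUE)
  if (!is.null(motif_frag)) {
    if (terminal) {
      frags <- c(frags, motif_frag)
    } else {
      pos <- sample(seq_len(n_frag + 1), 1)
      frags <- append(frags, motif_frag, after = pos - 1)
    }
  }
  smi <- paste(frags, collapse = "")
  n_heavy <- length(smiles_atom_tokens(smi))
  while (n_heavy < 5) {
    smi <- paste0("CC", smi)
    n_heavy <- n_heavy + 2
  }
  smi
}

#' Generate a labelled synthetic SMILES table
#'
#' @param config a [fixture_config()].
#' @return data.frame with columns `id`, `smiles`, `true_class`
#'   (`"active"`/`"inactive"`), `alert` (planted alert name or `NA`),
#'   `inactivity_motif` (motif name or `NA`), `expected_status`
#'   (anticipated curation outcome, `"KEPT"` for the clean base table).
#' @export
generate_molecules <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  n <- config$n_active + config$n_inactive
  if (n == 0) {
    return(data.frame(id = character(0), smiles = character(0),
                      true_class = character(0), alert = character(0),
                      inactivity_motif = character(0),
                      expected_status = character(0),
                      stringsAsFactors = FALSE))
  }
  with_seed(seed_substream(config$seed, "molecules"), {
    cls <- c(rep("active", config$n_active),
             rep("inactive", config$n_inactive))
    alert <- rep(NA_character_, n)
    motif <- rep(NA_character_, n)
    smiles <- character(n)
    for (i in seq_len(n)) {
      if (cls[i] == "active") {
        if (runif(1) < config$alert_penetrance) {
          alert[i] <- sample(names(.alert_motifs), 1)
          smiles[i] <- .assemble_molecule(.alert_motifs[[alert[i]]]$frag)
        } else {
          smiles[i] <- .assemble_molecule()
        }
      } else {
        if (runif(1) < config$decoy_rate) {
          alert[i] <- sample(names(.alert_motifs), 1)
          smiles[i] <- .assemble_molecule(.alert_motifs[[alert[i]]]$frag)
        } else if (runif(1) < config$inactive_motif_rate) {
          motif[i] <- sample(names(.inactivity_motifs), 1)
          mo <- .inactivity_motifs[[motif[i]]]
          smiles[i] <- .assemble_molecule(mo$frag, terminal = mo$terminal)
        } else {
          smiles[i] <- .assemble_molecule()
        }
      }
    }
    ids <- sprintf("SYN%05d", seq_len(n))
    # accidental collisions between independently assembled chains would
    # invalidate the per-record ground truth; reassemble until unique
    for (pass in 1:10) {
      canon <- chem_canonical(smiles, ids)
      dup <- which(duplicated(canon))
      if (!length(dup)) break
      for (i in dup) {
        motif_frag <- if (!is.na(alert[i])) .alert_motifs[[alert[i]]]$frag
        smiles[i] <- .assemble_molecule(motif_frag)
      }
    }
    data.frame(
      id = ids, smiles = smiles,
      true_class = cls, alert = alert, inactivity_motif = motif,
      expected_status = "KEPT", stringsAsFactors = FALSE
    )
  })
}

#' Inject curation-rule contaminants into a generated table
#'
#' Adds or transforms records so that every structure-curation rule is
#' exercised: sodium/chloride salt forms (survive curation as the desalted
#' parent), two-organic-component mixtures, low-carbon species, species with
#' non-whitelist elements, and duplicate pairs written as different SMILES
#' strings of the same molecule, with concordant or conflicting labels. The
#' `expected_status` column carries the ground-truth curation outcome of
#' every record.
#'
#' @param tbl output of [generate_molecules()].
#' @param config the same [fixture_config()].
#' @return augmented data.frame, same columns as the input.
#' @export
inject_contaminants <- function(tbl, config) {
  stopifnot(inherits(config, "fixture_config"))
  rates <- config$contaminant_rates
  n <- nrow(tbl)
  counts <- lapply(rates, function(r) floor(r * n))
  if (n == 0 || all(unlist(counts) == 0)) return(tbl)
  with_seed(seed_substream(config$seed, "contaminants"), {
    new_rows <- list()
    next_id <- 0L
    mk_id <- function(tag) {
      next_id <<- next_id + 1L
      sprintf("CNT%s%04d", tag, next_id)
    }
    blank_row <- function(id, smiles, status, class = "inactive") {
      data.frame(id = id, smiles = smiles, true_class = class,
                 alert = NA_character_, inactivity_motif = NA_character_,
                 expected_status = status, stringsAsFactors = FALSE)
    }

    # salt forms: converted in place, still expected KEPT after desalting
    if (counts$salt > 0) {
      cand <- which(tbl$expected_status == "KEPT")
      idx <- sample_ids(cand, min(counts$salt, length(cand)))
      for (i in idx) {
        s <- tbl$smiles[i]
        tbl$smiles[i] <- if (grepl("C\\(=O\\)O$", s)) {
          paste0(sub("C\\(=O\\)O$", "C(=O)[O-]", s), ".[Na+]")
        } else {
          paste0(s, ".[Na+].[Cl-]")
        }
      }
    }
    if (counts$mixture > 0) {
      for (k in seq_len(counts$mixture)) {
        new_rows[[length(new_rows) + 1L]] <- blank_row(
          mk_id("MIX"),
          paste0(.assemble_molecule(), ".", .assemble_molecule()),
          "REMOVED_MIXTURE")
      }
    }
    if (counts$low_carbon > 0) {
      pool <- c("C", "CO", "O", "N", "C(=O)O")
      for (k in seq_len(counts$low_carbon)) {
        new_rows[[length(new_rows) + 1L]] <- blank_row(
          mk_id("LOC"), sample(pool, 1), "REMOVED_LOW_CARBON")
      }
    }
    if (counts$bad_element > 0) {
      pool <- c("CC[Se]CC", "CC[As](C)C", "[Fe+2].[O-]C(=O)CC",
                "CC[Sn](C)C")
      for (k in seq_len(counts$bad_element)) {
        new_rows[[length(new_rows) + 1L]] <- blank_row(
          mk_id("ELE"), sample(pool, 1), "REMOVED_ELEMENT")
      }
    }

    # duplicates: same molecule, different string (OpenBabel re-write)
    dup_src <- which(tbl$expected_status == "KEPT")
    if (counts$duplicate_concordant > 0 && length(dup_src)) {
      idx <- sample_ids(dup_src, min(counts$duplicate_concordant,
                                     length(dup_src)))
      alt <- chem_canonical(tbl$smiles[idx], tbl$id[idx])
      for (j in seq_along(idx)) {
        i <- idx[j]
        new_rows[[length(new_rows) + 1L]] <- blank_row(
          mk_id("DUP"), unname(alt[j]), "MERGED_DUPLICATE",
          class = tbl$true_class[i])
      }
    }
    dup_src <- which(tbl$expected_status == "KEPT")
    if (counts$duplicate_conflict > 0 && length(dup_src)) {
      idx <- sample_ids(dup_src, min(counts$duplicate_conflict,
                                     length(dup_src)))
      alt <- chem_canonical(tbl$smiles[idx], tbl$id[idx])
      for (j in seq_along(idx)) {
        i <- idx[j]
        tbl$expected_status[i] <- "REMOVED_DUPLICATE_CONFLICT"
        flipped <- if (tbl$true_class[i] == "active") "inactive" else "active"
        new_rows[[length(new_rows) + 1L]] <- blank_row(
          mk_id("CFL"), unname(alt[j]), "REMOVED_DUPLICATE_CONFLICT",
          class = flipped)
      }
    }
    if (length(new_rows)) tbl <- rbind(tbl, do.call(rbind, new_rows))
    tbl
  })
}

#' Generate assay-score triples consistent with the labelling rules
#'
#' Actives receive a positive primary and confirmatory score and a zero
#' counterscreen; inactives a zero primary score. A configured fraction of
#' actives become luciferase interferers (positive counterscreen; ground
#' truth inconclusive), and label noise swaps the score pattern of a random
#' fraction of records.
#'
#' @param tbl table with `true_class` column.
#' @param config a [fixture_config()].
#' @return the table with `score_primary`, `score_confirm`, `score_counter`
#'   and `expected_label` columns appended.
#' @export
generate_assay_scores <- function(tbl, config) {
  stopifnot(inherits(config, "fixture_config"))
  n <- nrow(tbl)
  if (n == 0) {
    tbl$score_primary <- tbl$score_confirm <- tbl$score_counter <- integer(0)
    tbl$expected_label <- character(0)
    return(tbl)
  }
  with_seed(seed_substream(config$seed, "scores"), {
    eff <- tbl$true_class
    flip <- runif(n) < config$label_noise
    eff[flip] <- ifelse(eff[flip] == "active", "inactive", "active")
    interf <- eff == "active" & runif(n) < config$interferer_fraction

    p <- integer(n); cf <- rep(NA_integer_, n); ct <- rep(NA_integer_, n)
    act <- eff == "active"
    p[act] <- sample(10:100, sum(act), replace = TRUE)
    cf[act] <- sample(10:100, sum(act), replace = TRUE)
    ct[act] <- 0L
    ct[interf] <- sample(10:100, sum(interf), replace = TRUE)
    p[!act] <- 0L

    tbl$score_primary <- p
    tbl$score_confirm <- cf
    tbl$score_counter <- ct
    tbl$expected_label <- ifelse(interf, "INCONCLUSIVE",
                                 ifelse(act, "ACTIVE", "INACTIVE"))
    tbl
  })
}

#' Generate a complete synthetic fixture
#'
#' Convenience wrapper: [generate_molecules()], [inject_contaminants()],
#' [generate_assay_scores()] under one config.
#'
#' @param config a [fixture_config()].
#' @return the full synthetic substance table.
#' @export
generate_fixture <- function(config = fixture_config()) {
  generate_assay_scores(
    inject_contaminants(generate_molecules(config), config), config)
}
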