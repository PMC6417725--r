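## Featurization: substructure keys + nine continuous descriptors.
##
## The substructure vocabulary is an open stand-in for proprietary key
## libraries: the 166 public MACCS keys (computed by OpenBabel) plus a
## built-in catalog of SMARTS patterns for common ring systems and
## functional groups, "mined" per training set by keeping the patterns that
## occur above a frequency floor. Featurization of a dataset computes the
## full key matrix once; vocabulary selection and per-fold rebuilds are then
## column subsets, which keeps repeated cross-validation refits cheap while
## using only in-fold information (pattern matching is per-structure; the
## frequency floor is evaluated on the training rows alone).

#' Built-in SMARTS fragment catalog
#'
#' Ring systems and functional groups restricted to whitelist elements;
#' includes the heteroaromatic systems typical of receptor-activation
#' alerts (indole, pyrrole, benzofuran, pyrimidine, ...) and common
#' inactivity-associated groups (sulfonamide, sulfonyl, carboxylic acid).
#'
#' @return named character vector of SMARTS patterns.
#' @export
fragment_catalog <- function() {
  c(
    # carbocycles / arenes
    benzene = "c1ccccc1", naphthalene = "c1ccc2ccccc2c1",
    cyclohexane = "C1CCCCC1", cyclopentane = "C1CCCC1",
    # N heteroarenes
    pyridine = "c1ccncc1", pyrimidine = "c1cncnc1", pyrazine = "c1cnccn1",
    pyrrole = "c1cc[nH]c1", imidazole = "c1c[nH]cn1",
    pyrazole = "c1cc[nH]n1", indole = "c1ccc2[nH]ccc2c1",
    quinoline = "c1ccc2ncccc2c1", benzimidazole = "c1ccc2[nH]cnc2c1",
    # O/S heteroarenes and saturated heterocycles
    furan = "c1ccoc1", benzofuran = "c1ccc2occc2c1",
    thiophene = "c1ccsc1", benzothiophene = "c1ccc2sccc2c1",
    tetrahydrofuran = "C1CCOC1", tetrahydropyran = "C1CCOCC1",
    piperidine = "C1CCNCC1", piperazine = "C1CNCCN1",
    morpholine = "C1COCCN1", pyrrolidine = "C1CCNC1",
    # oxygen functions
    hydroxyl = "[OX2H]", phenol = "c[OX2H]", ether = "[#6][OX2][#6]",
    aldehyde = "[CX3H1](=O)[#6]", ketone = "[#6][CX3](=O)[#6]",
    carboxylic_acid = "C(=O)[OX2H1]", ester = "[#6]C(=O)[OX2H0][#6]",
    carbonyl = "[CX3]=[OX1]",
    # nitrogen functions
    primary_amine = "[NX3;H2;!$(NC=O)]", secondary_amine = "[NX3;H1;!$(NC=O)]",
    tertiary_amine = "[NX3;H0;!$(NC=O);!$(N=O)]",
    amide = "C(=O)[NX3]", nitrile = "C#N", nitro = "[N+](=O)[O-]",
    aniline = "c[NX3]", imine = "[CX3]=[NX2]",
    # sulfur functions
    thiol = "[SX2H]", thioether = "[#6][SX2][#6]",
    sulfoxide = "[#16X3]=[OX1]", sulfonyl = "S(=O)(=O)",
    sulfonamide = "S(=O)(=O)N", sulfonic_acid = "S(=O)(=O)[OX2H]",
    # halogens / others
    fluoro = "[F]", chloro = "[Cl]", bromo = "[Br]", iodo = "[I]",
    trifluoromethyl = "C(F)(F)F", phosphate = "P(=O)([OX2])[OX2]",
    # topology probes
    fused_bicyclic_arene = "c1ccc2c(c1)cccc2",
    alkyl_chain4 = "CCCC", branched_carbon = "[CX4H1]([#6])([#6])[#6]",
    quaternary_carbon = "[CX4]([#6])([#6])([#6])[#6]",
    aryl_methyl = "c[CH3]", vinyl = "[CX3]=[CX3]", alkyne = "C#C"
  )
}

#' Compute the nine continuous molecular descriptors
#'
#' AlogP, hydrogen-bond acceptors and donors, Lipinski score (number of
#' rule-of-five violations, 0-4), molecular weight, parent atom number
#' (heavy atoms of the desalted parent), parent molecular weight, polar
#' surface area and rotatable bonds. For single-component (already
#' desalted) input, `mw == parent_mw`.
#'
#' @param smiles character vector of SMILES.
#' @param ids unique identifiers.
#' @return data.frame keyed by id with the nine descriptor columns; `NA`
#'   rows mark descriptor-incalculable structures (feeds the applicability
#'   domain check).
#' @export
compute_descriptors <- function(smiles, ids) {
  check_ids(ids)
  props <- chem_properties(smiles, ids)
  multi <- grepl(".", smiles, fixed = TRUE)
  parent_mw <- props$mw
  parent_atoms <- props$parent_atom_number
  if (any(multi)) {
    parts <- desalt_and_neutralize(smiles[multi], ids[multi])
    for (k in seq_along(parts)) {
      i <- which(multi)[k]
      f <- filter_mixture_and_low_carbon(parts[[k]])
      if (!is.na(f$parent)) {
        pp <- chem_properties(f$parent, "parent")
        parent_mw[i] <- pp$mw
        parent_atoms[i] <- pp$parent_atom_number
      }
    }
  }
  lipinski <- (props$mw > 500) + (props$alogp > 5) +
    (props$hbd > 5) + (props$hba > 10)
  data.frame(
    id = ids,
    alogp = props$alogp, hba = props$hba, hbd = props$hbd,
    lipinski_score = as.numeric(lipinski), mw = props$mw,
    parent_atom_number = parent_atoms, parent_mw = parent_mw,
    psa = props$psa, rotatable_bonds = props$rotatable_bonds,
    stringsAsFactors = FALSE
  )
}

DESCRIPTOR_NAMES <- c("alogp", "hba", "hbd", "lipinski_score", "mw",
                      "parent_atom_number", "parent_mw", "psa",
                      "rotatable_bonds")

#' Featurize a set of structures
#'
#' Computes the full binary key matrix (166 MACCS keys + every catalog
#' pattern) and the nine descriptors. Vocabulary selection
#' ([build_vocabulary()]) and fingerprints are column subsets of this
#' object, so the expensive chemistry runs once per dataset.
#'
#' @param smiles character vector of curated SMILES.
#' @param ids unique identifiers.
#' @param catalog named SMARTS vector (default [fragment_catalog()]).
#' @return object of class `feature_set` with elements `ids`, `keys`
#'   (binary matrix), `descriptors` (numeric matrix), `catalog`.
#' @export
featurize <- function(smiles, ids, catalog = fragment_catalog()) {
  check_ids(ids)
  maccs <- chem_maccs(smiles, ids)
  frag <- chem_match_smarts(smiles, ids, catalog)
  storage.mode(frag) <- "integer"
  keys <- cbind(maccs, frag)
  desc <- compute_descriptors(smiles, ids)
  dm <- as.matrix(desc[, DESCRIPTOR_NAMES])
  rownames(dm) <- ids
  structure(list(ids = ids, keys = keys, descriptors = dm,
                 catalog = catalog),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("Feature set:", length(x$ids), "structures,",
      ncol(x$keys), "substructure keys,",
      ncol(x$descriptors), "descriptors\n")
  invisible(x)
}

## row subset of a feature_set
#' @export
`[.feature_set` <- function(x, i, ...) {
  ids <- if (is.character(i)) i else x$ids[i]
  structure(list(ids = ids, keys = x$keys[ids, , drop = FALSE],
                 descriptors = x$descriptors[ids, , drop = FALSE],
                 catalog = x$catalog),
            class = "feature_set")
}

#' Build a substructure vocabulary from training structures
#'
#' The vocabulary is the fixed 166-key MACCS set plus the catalog patterns
#' whose frequency among the given training structures reaches
#' `min_frequency`. Deterministic and independent of input order.
#'
#' @param features a `feature_set` (or output of [featurize()]).
#' @param rows ids (or indices) of the training rows to mine on; default
#'   all.
#' @param min_frequency frequency floor for mined fragments, as a fraction
#'   of training structures; `include_fragments = FALSE` keeps only the
#'   fixed key set.
#' @param include_fragments logical.
#' @return object of class `qsar_vocabulary`: data.frame with `key`,
#'   `type` (`"maccs"`/`"fragment"`), `pattern` (SMARTS or `NA`).
#' @export
build_vocabulary <- function(features, rows = NULL, min_frequency = 0.01,
                             include_fragments = TRUE) {
  stopifnot(inherits(features, "feature_set"))
  if (is.null(rows)) rows <- features$ids
  sub <- features$keys[rows, , drop = FALSE]
  maccs_cols <- grep("^MACCS", colnames(sub), value = TRUE)
  vocab <- data.frame(key = maccs_cols, type = "maccs",
                      pattern = NA_character_, stringsAsFactors = FALSE)
  if (include_fragments) {
    frag_cols <- setdiff(colnames(sub), maccs_cols)
    freq <- colMeans(sub[, frag_cols, drop = FALSE])
    keep <- frag_cols[freq >= min_frequency]
    if (length(keep)) {
      vocab <- rbind(vocab, data.frame(
        key = keep, type = "fragment",
        pattern = unname(features$catalog[keep]),
        stringsAsFactors = FALSE))
    }
  }
  class(vocab) <- c("qsar_vocabulary", "data.frame")
  vocab
}

#' Fingerprint structures against a vocabulary
#'
#' Bit i is 1 iff key i matches the structure at least once. For structures
#' already featurized, this is a column subset; for new SMILES use
#' [fingerprint_smiles()].
#'
#' @param features a `feature_set`.
#' @param vocabulary a `qsar_vocabulary`.
#' @return binary matrix, structures x vocabulary keys.
#' @export
fingerprint <- function(features, vocabulary) {
  stopifnot(inherits(features, "feature_set"),
            inherits(vocabulary, "qsar_vocabulary"))
  missing <- setdiff(vocabulary$key, colnames(features$keys))
  if (length(missing)) {
    qc_error(paste("vocabulary keys absent from feature set:",
                   paste(utils::head(missing, 3), collapse = ", ")))
  }
  features$keys[, vocabulary$key, drop = FALSE]
}

#' Fingerprint raw SMILES against a vocabulary
#'
#' @param smiles character vector of SMILES.
#' @param ids unique identifiers.
#' @param vocabulary a `qsar_vocabulary`.
#' @return binary matrix, structures x vocabulary keys.
#' @export
fingerprint_smiles <- function(smiles, ids, vocabulary) {
  stopifnot(inherits(vocabulary, "qsar_vocabulary"))
  maccs <- chem_maccs(smiles, ids)
  frag_rows <- vocabulary[vocabulary$type == "fragment", ]
  out <- maccs[, vocabulary$key[vocabulary$type == "maccs"], drop = FALSE]
  if (nrow(frag_rows)) {
    pats <- frag_rows$pattern
    names(pats) <- frag_rows$key
    fm <- chem_match_smarts(smiles, ids, pats)
    storage.mode(fm) <- "integer"
    out <- cbind(out, fm)
  }
  out[, vocabulary$key, drop = FALSE]
}

#' Write / read a vocabulary file
#'
#' One key per line: `key<TAB>type<TAB>pattern`, with a versioned header.
#'
#' @param vocabulary a `qsar_vocabulary`.
#' @param path file path.
#' @return `read_vocabulary()` returns the `qsar_vocabulary`.
#' @export
write_vocabulary <- function(vocabulary, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# qsarcocktail vocabulary v1", con)
  utils::write.table(vocabulary, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  vocab <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                             stringsAsFactors = FALSE)
  vocab$pattern[vocab$pattern == "NA"] <- NA_character_
  class(vocab) <- c("qsar_vocabulary", "data.frame")
  vocab
}

#' Yates-corrected chi-squared statistic for a 2x2 table
#'
#' Chi-square independence test with one degree of freedom and Yates'
#' continuity correction:
#' `N * (max(|n11*n00 - n10*n01| - N/2, 0))^2 /
#'  ((n11+n10)(n01+n00)(n11+n01)(n10+n00))`,
#' defined as 0 when any margin is 0.
#'
#' @param n11,n10,n01,n00 nonnegative integer cell counts (vectorized).
#' @return numeric chi-squared value(s).
#' @export
#' @examples
#' yates_chi2(24, 901, 5, 3695)
yates_chi2 <- function(n11, n10, n01, n00) {
  if (any(c(n11, n10, n01, n00) < 0)) {
    qc_error("cell counts must be nonnegative")
  }
  # double arithmetic: cell products overflow 32-bit integers
  n11 <- as.numeric(n11); n10 <- as.numeric(n10)
  n01 <- as.numeric(n01); n00 <- as.numeric(n00)
  n <- n11 + n10 + n01 + n00
  num <- pmax(abs(n11 * n00 - n10 * n01) - n / 2, 0)^2 * n
  den <- (n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00)
  ifelse(den == 0 | n == 0, 0, num / den)
}

#' Preselect feature columns by Yates chi-squared
#'
#' Ranks every column of the design matrix by the Yates chi-squared of its
#' presence x label 2x2 table and keeps the top `ceiling(fraction * ncol)`.
#' Continuous columns are binarized at their median for the ranking only.
#' Ties break by column order.
#'
#' @param x numeric matrix (binary keys and/or continuous descriptors).
#' @param labels binary vector (1/TRUE = active).
#' @param fraction fraction of columns to keep (default 0.30).
#' @return logical column mask with exactly `ceiling(fraction * ncol)`
#'   `TRUE` entries.
#' @export
preselect <- function(x, labels, fraction = 0.30) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    qc_error("labels must contain both classes for preselection")
  }
  stopifnot(nrow(x) == length(labels))
  chi <- apply(x, 2, function(col) {
    if (any(is.na(col))) col[is.na(col)] <- stats::median(col, na.rm = TRUE)
    if (!all(col %in% c(0, 1))) {
      col <- as.integer(col > stats::median(col))
    }
    yates_chi2(sum(col == 1 & labels == 1), sum(col == 0 & labels == 1),
               sum(col == 1 & labels == 0), sum(col == 0 & labels == 0))
  })
  quota <- ceiling(fraction * ncol(x))
  # constant columns carry no information: they fill the quota last
  constant <- apply(x, 2, function(col) {
    length(unique(col[!is.na(col)])) < 2
  })
  ord <- order(-chi, constant, seq_along(chi))
  mask <- logical(ncol(x))
  mask[ord[seq_len(quota)]] <- TRUE
  names(mask) <- colnames(x)
  mask
}

#' Combined design matrix of a feature set
#'
#' Binary substructure keys followed by the nine continuous descriptors.
#'
#' @param features a `feature_set`.
#' @param vocabulary optional `qsar_vocabulary` restricting the key
#'   columns.
#' @return numeric matrix.
#' @export
design_matrix <- function(features, vocabulary = NULL) {
  keys <- if (is.null(vocabulary)) features$keys
          else fingerprint(features, vocabulary)
  desc <- features$descriptors
  colnames(desc) <- paste0("desc_", colnames(desc))
  cbind(keys, desc)
}
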