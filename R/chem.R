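## Chemistry backend.
##
## All molecular-graph work (SMILES validity, canonicalization, charge
## neutralization, descriptors, MACCS keys, SMARTS matching) is delegated to
## the OpenBabel command-line tool `obabel`, called on whole batches of
## molecules at a time. Batch calls keep the cost per molecule in the
## microsecond range, which matters because cross-validation refits models
## many times. Identifiers travel through OpenBabel as SMILES "titles", so
## records that fail to parse are detected by their id missing from the
## output rather than by positional bookkeeping.

ob_binary <- function() {
  bin <- Sys.which("obabel")
  if (!nzchar(bin)) {
    qc_error("OpenBabel 'obabel' executable not found on PATH")
  }
  bin
}

check_ids <- function(ids) {
  if (anyDuplicated(ids)) qc_error("molecule ids must be unique")
  if (any(grepl("[[:space:]]", ids))) {
    qc_error("molecule ids must not contain whitespace")
  }
  invisible(ids)
}

## Run obabel over (smiles, ids); returns output lines (format dependent).
ob_run <- function(smiles, ids, args) {
  stopifnot(length(smiles) == length(ids))
  check_ids(ids)
  if (length(smiles) == 0) return(character(0))
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile))
  writeLines(paste0(smiles, "\t", ids), infile)
  out <- suppressWarnings(system2(
    ob_binary(), c(shQuote(infile), args, "-e"),
    stdout = TRUE, stderr = FALSE
  ))
  out[nzchar(out)]
}

## ---- SMILES string utilities (lexical; no graph interpretation) ----------

## one regex token per atom: bracket atom, two-letter organic subset, or
## single-letter (possibly aromatic) organic subset atom
.atom_token_re <- "\\[[^]]+\\]|Cl|Br|[BCNOPSFI]|[bcnops]"

smiles_atom_tokens <- function(smiles) {
  regmatches(smiles, gregexpr(.atom_token_re, smiles))[[1]]
}

## element symbol of each atom token
smiles_elements <- function(smiles) {
  toks <- smiles_atom_tokens(smiles)
  vapply(toks, function(tk) {
    if (startsWith(tk, "[")) {
      inner <- sub("^\\[[0-9]*", "", substr(tk, 1, nchar(tk) - 1))
      m <- regmatches(inner, regexpr("^([A-Z][a-z]?|[a-z]{1,2})", inner))
      if (!length(m)) return("?")
      # aromatic bracket atoms are written lower-case
      if (m %in% c("c", "n", "o", "p", "s", "b")) toupper(m)
      else if (m == "se") "Se"
      else if (m == "as") "As"
      else m
    } else if (tk %in% c("b", "c", "n", "o", "p", "s")) {
      toupper(tk)
    } else {
      tk
    }
  }, character(1), USE.NAMES = FALSE)
}

## connected components of a SMILES (dot-separated parts)
smiles_components <- function(smiles) {
  strsplit(smiles, ".", fixed = TRUE)[[1]]
}

smiles_carbon_count <- function(smiles) {
  sum(smiles_elements(smiles) == "C")
}

## net formal charge, summed over bracket atoms
smiles_net_charge <- function(smiles) {
  toks <- grep("^\\[", smiles_atom_tokens(smiles), value = TRUE)
  if (!length(toks)) return(0L)
  chg <- vapply(toks, function(tk) {
    body <- substr(tk, 2, nchar(tk) - 1)
    m <- regmatches(body, regexpr("[+-][0-9]*$|[+]+$|[-]+$", body))
    if (!length(m)) return(0L)
    if (grepl("^[+-][0-9]+$", m)) {
      as.integer(m)
    } else {
      sgn <- if (startsWith(m, "+")) 1L else -1L
      sgn * nchar(m)
    }
  }, integer(1), USE.NAMES = FALSE)
  sum(chg)
}

## ---- batched OpenBabel operations ----------------------------------------

#' Canonical SMILES via OpenBabel
#'
#' @param smiles character vector of SMILES.
#' @param ids unique whitespace-free identifiers.
#' @param neutralize apply OpenBabel's charge neutralization
#'   (protonate/deprotonate where chemically possible) before writing.
#' @return named character vector (names = ids); `NA` where the SMILES did
#'   not parse or could not be written.
#' @keywords internal
chem_canonical <- function(smiles, ids, neutralize = FALSE) {
  args <- c("-ocan", if (neutralize) "--neutralize")
  out <- ob_run(smiles, ids, args)
  res <- rep(NA_character_, length(ids))
  names(res) <- ids
  if (length(out)) {
    parts <- strsplit(out, "\t", fixed = TRUE)
    got_id <- vapply(parts, function(p) trimws(p[2] %||% ""), character(1))
    got_smi <- vapply(parts, `[`, character(1), 1)
    keep <- got_id %in% ids
    res[got_id[keep]] <- trimws(got_smi[keep])
  }
  res
}

## nine-descriptor backend: returns data.frame keyed by id with NA rows for
## molecules whose descriptors could not be computed
chem_properties <- function(smiles, ids) {
  out <- ob_run(smiles, ids,
                c("-otxt", "--append",
                  shQuote("MW logP TPSA rotors atoms HBA1 HBD")))
  res <- data.frame(
    id = ids, mw = NA_real_, alogp = NA_real_, psa = NA_real_,
    rotatable_bonds = NA_real_, parent_atom_number = NA_real_,
    hba = NA_real_, hbd = NA_real_, stringsAsFactors = FALSE
  )
  rownames(res) <- ids
  for (line in out) {
    f <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (length(f) != 8 || !(f[1] %in% ids)) next
    vals <- suppressWarnings(as.numeric(f[2:8]))
    res[f[1], 2:8] <- vals
  }
  res
}

## logical matrix (molecules x patterns) of SMARTS substructure hits
chem_match_smarts <- function(smiles, ids, patterns) {
  check_ids(ids)
  m <- matrix(FALSE, nrow = length(ids), ncol = length(patterns),
              dimnames = list(ids, names(patterns) %||% patterns))
  if (!length(smiles) || !length(patterns)) return(m)
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile))
  writeLines(paste0(smiles, "\t", ids), infile)
  for (j in seq_along(patterns)) {
    hits <- suppressWarnings(system2(
      ob_binary(), c(shQuote(infile), "-otxt", "-e", "-s",
                     shQuote(patterns[[j]])),
      stdout = TRUE, stderr = FALSE
    ))
    hits <- trimws(hits[nzchar(hits)])
    m[hits[hits %in% ids], j] <- TRUE
  }
  m
}

## 166-bit MACCS key matrix (0/1), rows = ids
chem_maccs <- function(smiles, ids) {
  out <- ob_run(smiles, ids, c("-ofps", "-xfMACCS"))
  out <- out[!startsWith(out, "#")]
  m <- matrix(0L, nrow = length(ids), ncol = 166,
              dimnames = list(ids, sprintf("MACCS%03d", 1:166)))
  if (!length(out)) return(m)
  hex2bits <- function(h) {
    nib <- strtoi(strsplit(h, "")[[1]], base = 16L)
    bits <- unlist(lapply(nib, function(x) as.integer(intToBits(x)[4:1])))
    bits
  }
  for (line in out) {
    p <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(p) < 2) next
    id <- trimws(p[2])
    if (!(id %in% ids)) next
    bits <- hex2bits(trimws(p[1]))
    m[id, ] <- bits[seq_len(166)]
  }
  m
}

## parse validity: TRUE where OpenBabel can read and write the structure
chem_is_valid <- function(smiles, ids) {
  !is.na(chem_canonical(smiles, ids))
}
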