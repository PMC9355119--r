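# Structure curation: standardization, salt stripping, removal of inorganics
# and mixtures, duplicate resolution. The workflow follows the established
# QSAR data-curation protocol: records enter as raw SMILES with categorical
# hazard labels and leave as a set of unique, standardized, single-fragment
# organic structures.

#' Build a table of compound records
#'
#' The package-wide container for labeled structures is a plain data.frame
#' with columns `record_id`, `smiles`, `source`, `label` and `flags`.
#'
#' @param smiles character vector of SMILES strings
#' @param label hazard labels: `"POS"`/`"NEG"` for binary endpoints, GHS
#'   categories `"CAT1"`, `"CAT2A"`, `"CAT2B"`, `"NC"` for multiclass, or
#'   `"UNLABELED"` for screening input
#' @param record_id unique identifiers (generated when omitted)
#' @param source free-text provenance
#' @return data.frame of class `compound_records`
#' @export
compound_records <- function(smiles, label = "UNLABELED", record_id = NULL,
                             source = "") {
  n <- length(smiles)
  if (is.null(record_id)) record_id <- sprintf("REC%05d", seq_len(n))
  if (anyDuplicated(record_id)) stop("record_id values must be unique")
  df <- data.frame(
    record_id = as.character(record_id),
    smiles = as.character(smiles),
    source = rep_len(as.character(source), n),
    label = rep_len(as.character(label), n),
    flags = character(n),
    stringsAsFactors = FALSE
  )
  class(df) <- c("compound_records", "data.frame")
  df
}

#' Default counter-ion and solvent dictionary
#'
#' Fragments recognized as counter-ions or solvents are stripped from
#' multi-fragment records during standardization; any other co-fragment
#' makes the record a mixture. The dictionary covers alkali and
#' alkaline-earth cations, halides, common mineral and organic acid
#' counter-ions, and common solvents. It is a plain character vector of
#' SMILES, so callers can extend or replace it.
#'
#' @return character vector of SMILES strings
#' @export
default_counterions <- function() {
  c(
    # cations
    "[Na+]", "[K+]", "[Li+]", "[Cs+]", "[NH4+]", "[Ca+2]", "[Mg+2]",
    "[Ba+2]", "[Zn+2]", "[Al+3]", "[Fe+2]", "[Fe+3]",
    # halides / hydrohalic acids
    "[Cl-]", "[Br-]", "[I-]", "[F-]", "Cl", "Br", "I", "F",
    # water, hydroxide, mineral acids
    "O", "[OH-]", "OS(=O)(=O)O", "OS(=O)O", "O[N+](=O)[O-]", "OP(=O)(O)O",
    "OC(=O)O",
    # organic acid counter-ions
    "CC(=O)O", "OC(=O)C(=O)O", "OC(=O)C=CC(=O)O", "OC(=O)CC(=O)O",
    "OC(=O)C(O)C(O)C(=O)O", "OC(=O)CC(O)(CC(=O)O)C(=O)O",
    "CS(=O)(=O)O", "Cc1ccc(cc1)S(=O)(=O)O",
    # solvents (simple alcohols are deliberately absent: too common as
    # principal structures to strip)
    "CC(=O)C", "CS(C)=O", "CC#N"
  )
}

# cache of canonicalized dictionaries, keyed by the raw dictionary contents
.counterion_cache <- new.env(parent = emptyenv())

#' Canonical forms (charged and neutralized) of a counter-ion dictionary
#' @noRd
counterion_keys <- function(counterions) {
  key <- paste(sort(counterions), collapse = "|")
  hit <- .counterion_cache[[key]]
  if (!is.null(hit)) return(hit)
  canon <- ob_canonical(counterions)
  neut <- ob_neutralize(counterions)
  keys <- unique(stats::na.omit(c(canon, neut)))
  assign(key, keys, envir = .counterion_cache)
  keys
}

#' Standardize a chemical structure
#'
#' Produces one canonical form per structure: recognized counter-ion and
#' solvent fragments are stripped (the principal organic fragment is kept),
#' protonation-state charges are neutralized where valence rules permit
#' (quaternary nitrogen keeps its charge), pentavalent-written nitro groups
#' are rewritten to the canonical charge-separated form, and aromaticity is
#' perceived by the canonicalizer. The operation is idempotent.
#'
#' Multi-fragment inputs whose extra fragments are not in the dictionary are
#' returned with all non-dictionary fragments intact (still dot-separated);
#' classifying and removing such mixtures is the job of
#' [remove_inorganics_and_mixtures()].
#'
#' @param smiles a single SMILES string
#' @param counterions counter-ion/solvent dictionary, see
#'   [default_counterions()]
#' @return canonical SMILES string
#' @export
standardize_structure <- function(smiles, counterions = default_counterions()) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  canon <- ob_canonical(smiles)
  if (is.na(canon)) parse_error(smiles)
  normed <- normalize_nitro(canon)
  if (!identical(normed, canon)) {
    canon <- ob_canonical(normed)
    if (is.na(canon)) parse_error(smiles)
  }

  frags <- split_fragments(canon)
  if (length(frags) > 1L) {
    keys <- counterion_keys(counterions)
    frag_canon <- ob_canonical(frags)
    in_dict <- frag_canon %in% keys | ob_neutralize(frags) %in% keys
    organic <- has_carbon(frags)
    principal <- organic & !in_dict
    if (sum(principal) >= 1L) {
      frags <- frags[principal]
    } else if (any(organic)) {
      # salt/solvate of a dictionary acid: keep the largest organic fragment
      heavy <- smarts_count(frags, "[!#1]")
      heavy[!organic] <- -Inf
      frags <- frags[which.max(heavy)]
    } # else fully inorganic: keep all fragments, removed downstream
    canon <- paste(frags, collapse = ".")
  }

  out <- ob_neutralize(canon)
  if (is.na(out)) out <- canon
  out2 <- normalize_nitro(out)
  if (!identical(out2, out)) out <- ob_canonical(out2)
  out
}

#' Construct a curation log
#' @noRd
curation_log <- function(input_count, output_count,
                         unparseable = 0L, inorganic = 0L, mixture = 0L,
                         discordant = 0L, redundant = 0L) {
  log <- list(
    input_count = as.integer(input_count),
    output_count = as.integer(output_count),
    removed = c(
      unparseable = as.integer(unparseable),
      inorganic = as.integer(inorganic),
      mixture = as.integer(mixture),
      discordant_duplicate = as.integer(discordant),
      redundant_duplicate = as.integer(redundant)
    )
  )
  stopifnot(log$input_count == log$output_count + sum(log$removed))
  class(log) <- "curation_log"
  log
}

#' @export
print.curation_log <- function(x, ...) {
  cat("Curation log:", x$input_count, "records in,", x$output_count,
      "records out\n")
  for (nm in names(x$removed)) {
    if (x$removed[[nm]] > 0)
      cat(sprintf("  removed (%s): %d\n", gsub("_", " ", nm), x$removed[[nm]]))
  }
  invisible(x)
}

#' Merge curation logs from successive stages
#' @noRd
merge_curation_logs <- function(...) {
  logs <- list(...)
  removed <- Reduce(`+`, lapply(logs, function(l) l$removed))
  curation_log(
    input_count = logs[[1L]]$input_count,
    output_count = logs[[length(logs)]]$output_count,
    unparseable = removed[["unparseable"]],
    inorganic = removed[["inorganic"]],
    mixture = removed[["mixture"]],
    discordant = removed[["discordant_duplicate"]],
    redundant = removed[["redundant_duplicate"]]
  )
}

#' Append a flag to record flag strings
#' @noRd
add_flag <- function(flags, flag, which = TRUE) {
  upd <- ifelse(nzchar(flags), paste(flags, flag, sep = ";"), flag)
  ifelse(which, upd, flags)
}

#' Standardize every record in a table
#'
#' Applies [standardize_structure()] to each record. Unparseable records are
#' dropped and counted. Records whose structure changed are flagged
#' `STANDARDIZED`; records that lost fragments are additionally flagged
#' `SALT_STRIPPED`.
#'
#' @param records a `compound_records` table
#' @inheritParams standardize_structure
#' @return list with elements `records` (standardized table) and `log`
#'   (a `curation_log`)
#' @export
standardize_records <- function(records, counterions = default_counterions()) {
  n <- nrow(records)
  out <- vapply(records$smiles, function(s) {
    tryCatch(standardize_structure(s, counterions),
             oculotox_parse_error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
  ok <- !is.na(out)
  kept <- records[ok, , drop = FALSE]
  changed <- out[ok] != kept$smiles
  lost_frags <- lengths(strsplit(out[ok], ".", fixed = TRUE)) <
    lengths(strsplit(kept$smiles, ".", fixed = TRUE))
  kept$flags <- add_flag(kept$flags, "STANDARDIZED", changed)
  kept$flags <- add_flag(kept$flags, "SALT_STRIPPED", lost_frags)
  kept$smiles <- out[ok]
  rownames(kept) <- NULL
  list(records = kept,
       log = curation_log(n, nrow(kept), unparseable = n - nrow(kept)))
}

#' Remove inorganic structures and true mixtures
#'
#' Drops records with no carbon atom (inorganics) and records whose
#' standardized structure still has more than one fragment (true mixtures:
#' standardization already stripped recognized counter-ions, so whatever
#' remains dot-separated is a mixture).
#'
#' @param records standardized `compound_records`
#' @return list with `records` and `log`
#' @export
remove_inorganics_and_mixtures <- function(records) {
  n <- nrow(records)
  if (n == 0L) {
    return(list(records = records, log = curation_log(0L, 0L)))
  }
  organic <- has_carbon(records$smiles)
  organic[is.na(organic)] <- FALSE
  multi <- grepl(".", records$smiles, fixed = TRUE)
  inorganic <- !organic
  mixture <- organic & multi
  kept <- records[!inorganic & !mixture, , drop = FALSE]
  rownames(kept) <- NULL
  list(records = kept,
       log = curation_log(n, nrow(kept),
                          inorganic = sum(inorganic),
                          mixture = sum(mixture)))
}

#' Resolve duplicate structures
#'
#' Groups records by canonical structure key. Groups whose labels all agree
#' collapse to the first record (flagged `DEDUPLICATED`); groups with
#' discordant labels are removed entirely, since a structure with
#' inconsistent hazard calls cannot be trusted as training data.
#'
#' @param records standardized `compound_records`
#' @return list with `records` and `log`
#' @export
deduplicate <- function(records) {
  n <- nrow(records)
  if (n == 0L) {
    return(list(records = records, log = curation_log(0L, 0L)))
  }
  groups <- split(seq_len(n), records$smiles)
  keep_idx <- integer(0)
  flag_dedup <- integer(0)
  n_discordant <- 0L
  n_redundant <- 0L
  for (idx in groups) {
    labs <- unique(records$label[idx])
    if (length(labs) > 1L) {
      n_discordant <- n_discordant + length(idx)
    } else {
      keep_idx <- c(keep_idx, idx[1L])
      if (length(idx) > 1L) {
        flag_dedup <- c(flag_dedup, idx[1L])
        n_redundant <- n_redundant + length(idx) - 1L
      }
    }
  }
  keep_idx <- sort(keep_idx)
  kept <- records[keep_idx, , drop = FALSE]
  kept$flags <- add_flag(kept$flags, "DEDUPLICATED", keep_idx %in% flag_dedup)
  rownames(kept) <- NULL
  list(records = kept,
       log = curation_log(n, nrow(kept),
                          discordant = n_discordant,
                          redundant = n_redundant))
}

#' Run the full curation workflow
#'
#' Standardization, inorganic/mixture removal and duplicate resolution in
#' sequence. The combined log reconciles: input count equals output count
#' plus the sum of all removal counts. The workflow is idempotent: curating
#' its own output changes nothing.
#'
#' @param records raw `compound_records`
#' @inheritParams standardize_structure
#' @return list with `records` (curated table) and `log`
#' @export
curate <- function(records, counterions = default_counterions()) {
  s1 <- standardize_records(records, counterions)
  s2 <- remove_inorganics_and_mixtures(s1$records)
  s3 <- deduplicate(s2$records)
  list(records = s3$records,
       log = merge_curation_logs(s1$log, s2$log, s3$log))
}
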