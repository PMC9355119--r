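# Descriptor spaces. Three spaces are supported: 2048-bit circular (Morgan,
# radius 2) fingerprints, the 166 public structural keys, and a
# whole-molecule physicochemical descriptor set. Fingerprint bits come from
# OpenBabel (ECFP4 folded to 2048 bits; the structural-key SMARTS
# dictionary); physicochemical values combine OpenBabel property and
# SMARTS-count calculators.

MORGAN_BITS <- 2048L
KEYS166_BITS <- 166L

#' Construct a descriptor block
#'
#' A descriptor block is the package's matrix container for one descriptor
#' space over a compound set: an `n x p` numeric matrix plus the space name,
#' the kind of values it holds, feature names and row-aligned compound ids.
#'
#' @param matrix numeric matrix, compounds in rows
#' @param space one of `"MORGAN"`, `"KEYS166"`, `"PHYSCHEM"`
#' @param kind `"BIT"` or `"CONTINUOUS"`
#' @param feature_names column names (taken from the matrix when omitted)
#' @param compound_ids row-aligned compound identifiers
#' @return object of class `descriptor_block`
#' @export
descriptor_block <- function(matrix, space, kind,
                             feature_names = colnames(matrix),
                             compound_ids = rownames(matrix)) {
  space <- match.arg(space, c("MORGAN", "KEYS166", "PHYSCHEM"))
  kind <- match.arg(kind, c("BIT", "CONTINUOUS"))
  matrix <- as.matrix(matrix)
  if (is.null(feature_names))
    feature_names <- sprintf("f%04d", seq_len(ncol(matrix)))
  if (is.null(compound_ids))
    compound_ids <- sprintf("CMP%05d", seq_len(nrow(matrix)))
  stopifnot(length(feature_names) == ncol(matrix),
            length(compound_ids) == nrow(matrix))
  if (anyNA(matrix)) stop("descriptor block contains missing values")
  if (kind == "BIT" && !all(matrix %in% c(0, 1)))
    stop("BIT block must contain only 0/1 values")
  dimnames(matrix) <- list(compound_ids, feature_names)
  structure(list(space = space, kind = kind, matrix = matrix,
                 feature_names = feature_names,
                 compound_ids = as.character(compound_ids)),
            class = "descriptor_block")
}

#' @export
print.descriptor_block <- function(x, ...) {
  cat(sprintf("<descriptor_block> %s (%s): %d compounds x %d features\n",
              x$space, x$kind, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Subset the rows of a descriptor block
#'
#' @param block a `descriptor_block`
#' @param idx integer, logical or compound-id index
#' @return a `descriptor_block` over the selected compounds
#' @export
block_rows <- function(block, idx) {
  if (is.character(idx)) idx <- match(idx, block$compound_ids)
  descriptor_block(block$matrix[idx, , drop = FALSE], block$space, block$kind,
                   block$feature_names, block$compound_ids[idx])
}

#' Morgan bits for a SMILES vector: ECFP4 (4096 bits) folded to 2048 by
#' OR-ing the halves. Computed in one external OpenBabel call.
#' @return list(ok = logical, matrix = n x 2048 integer)
#' @noRd
morgan_batch <- function(smiles) {
  raw <- ob_ecfp4_batch(smiles)
  ok <- !is.na(raw[, 1L])
  half <- ncol(raw) %/% 2L
  folded <- (raw[, seq_len(half), drop = FALSE] |
               raw[, half + seq_len(half), drop = FALSE]) * 1L
  folded[!ok, ] <- NA_integer_
  storage.mode(folded) <- "integer"
  list(ok = ok, matrix = folded)
}

#' @noRd
keys166_from_mol <- function(molref) {
  fp <- ChemmineOB::fingerprint_OB(list(molref), "MACCS")
  as.integer(fp)[seq_len(KEYS166_BITS)]
}

#' Physicochemical feature names
#'
#' The whole-molecule descriptor set computed by [compute_physchem()]. The
#' exact composition is toolkit-dependent and is recorded, not enforced:
#' models consume whatever features this function lists.
#'
#' @return character vector of feature names
#' @export
physchem_features <- function() {
  c("MW", "ExactMW", "LogP", "MolarRefractivity", "TPSA",
    "HBondDonors", "HBondAcceptors1", "HBondAcceptors2", "NumFluorine",
    "HeavyAtoms", "CarbonAtoms", "Heteroatoms", "NitrogenAtoms",
    "OxygenAtoms", "SulfurAtoms", "HalogenAtoms", "AromaticAtoms",
    "RingAtoms", "RotatableBonds")
}

# SMARTS used for the count-type physicochemical descriptors
.physchem_smarts <- c(
  HeavyAtoms = "[!#1]", CarbonAtoms = "[#6]", Heteroatoms = "[!#6;!#1]",
  NitrogenAtoms = "[#7]", OxygenAtoms = "[#8]", SulfurAtoms = "[#16]",
  HalogenAtoms = "[F,Cl,Br,I]", AromaticAtoms = "a", RingAtoms = "[R]",
  RotatableBonds = "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"
)

#' @noRd
physchem_from_mol <- function(molref) {
  p <- ChemmineOB::prop_OB(list(molref))
  counts <- vapply(.physchem_smarts, function(sm) ob_count_matches(molref, sm),
                   numeric(1))
  v <- c(MW = p$MW, ExactMW = ChemmineOB::exactMass_OB(list(molref)),
         LogP = p$logP, MolarRefractivity = p$MR, TPSA = p$TPSA,
         HBondDonors = p$HBD, HBondAcceptors1 = p$HBA1,
         HBondAcceptors2 = p$HBA2, NumFluorine = p$nF, counts)
  as.numeric(v[physchem_features()])
}

#' @noRd
space_fun <- function(space) {
  switch(space,
         KEYS166 = keys166_from_mol,
         PHYSCHEM = physchem_from_mol,
         stop("unknown descriptor space: ", space))
}

#' @noRd
space_kind <- function(space) {
  if (space == "PHYSCHEM") "CONTINUOUS" else "BIT"
}

#' @noRd
space_feature_names <- function(space) {
  switch(space,
         MORGAN = sprintf("morgan_%04d", seq_len(MORGAN_BITS)),
         KEYS166 = sprintf("key_%03d", seq_len(KEYS166_BITS)),
         PHYSCHEM = physchem_features())
}

#' Compute descriptor blocks for a compound set
#'
#' Parses each structure once and computes every requested descriptor space
#' from the same parse. Structures that fail to parse or yield non-finite
#' descriptor values are either dropped from all blocks (`on_error =
#' "omit"`, recorded in the `"failed_ids"` attribute of the result) or raise
#' an error (`on_error = "stop"`).
#'
#' @param smiles character vector of standardized SMILES
#' @param compound_ids identifiers aligned to `smiles`
#' @param spaces descriptor spaces to compute
#' @param on_error `"omit"` or `"stop"`
#' @return named list of `descriptor_block`s, one per space
#' @export
featurize <- function(smiles, compound_ids = NULL,
                      spaces = c("MORGAN", "KEYS166", "PHYSCHEM"),
                      on_error = c("omit", "stop")) {
  on_error <- match.arg(on_error)
  spaces <- match.arg(spaces, several.ok = TRUE)
  if (is.null(compound_ids)) compound_ids <- sprintf("CMP%05d", seq_along(smiles))
  stopifnot(length(compound_ids) == length(smiles))

  # Morgan bits come from one external OpenBabel call; the other spaces
  # share a single in-process parse per molecule.
  morgan <- if ("MORGAN" %in% spaces) morgan_batch(smiles) else NULL
  mol_spaces <- setdiff(spaces, "MORGAN")
  rows <- NULL
  if (length(mol_spaces)) {
    funs <- lapply(mol_spaces, space_fun)
    names(funs) <- mol_spaces
    rows <- mol_apply(smiles, function(m) lapply(funs, function(f) f(m)))
  }
  ok <- rep(TRUE, length(smiles))
  if (!is.null(morgan)) ok <- ok & morgan$ok
  if (!is.null(rows)) {
    ok <- ok & vapply(rows, function(r) {
      !is.null(r) && all(vapply(r, function(v) all(is.finite(v)),
                                logical(1)))
    }, logical(1))
  }
  if (!all(ok) && on_error == "stop") {
    stop("descriptor computation failed for: ",
         paste(compound_ids[!ok], collapse = ", "))
  }
  blocks <- lapply(spaces, function(sp) {
    mat <- if (sp == "MORGAN") {
      morgan$matrix[ok, , drop = FALSE]
    } else {
      do.call(rbind, lapply(rows[ok], `[[`, sp))
    }
    if (is.null(mat)) mat <- matrix(numeric(0), 0L,
                                    length(space_feature_names(sp)))
    descriptor_block(mat, sp, space_kind(sp),
                     feature_names = space_feature_names(sp),
                     compound_ids = compound_ids[ok])
  })
  names(blocks) <- spaces
  attr(blocks, "failed_ids") <- compound_ids[!ok]
  blocks
}

#' Morgan (circular, radius 2) fingerprints, 2048 bits
#'
#' @param smiles character vector of SMILES
#' @return integer matrix, one row per structure, 2048 binary columns
#' @export
compute_morgan <- function(smiles) {
  featurize(smiles, spaces = "MORGAN", on_error = "stop")$MORGAN$matrix
}

#' Public 166 structural keys
#'
#' @param smiles character vector of SMILES
#' @return integer matrix, one row per structure, 166 binary columns
#' @export
compute_keys166 <- function(smiles) {
  featurize(smiles, spaces = "KEYS166", on_error = "stop")$KEYS166$matrix
}

#' Whole-molecule physicochemical descriptors
#'
#' @param smiles character vector of SMILES
#' @return numeric matrix, one row per structure, see [physchem_features()]
#' @export
compute_physchem <- function(smiles) {
  featurize(smiles, spaces = "PHYSCHEM", on_error = "stop")$PHYSCHEM$matrix
}

#' Remove invariant and highly correlated features
#'
#' Zero-variance columns are removed first. Then, scanning feature pairs in
#' column order, the later-indexed feature of every pair with absolute
#' Pearson correlation above `threshold` is removed, so the surviving set
#' has no pair with |r| > threshold. The scan order makes the result
#' deterministic. Applying the filter to its own output removes nothing.
#'
#' Bit-fingerprint spaces are conventionally left unfiltered in the modeling
#' pipeline (the correlation filter targets continuous descriptor
#' collections); the function itself operates on whatever block it is given.
#'
#' @param block a `descriptor_block`
#' @param threshold correlation cutoff in (0, 1], default 0.9
#' @return list with `block` (filtered) and `report` (a `filter_report` with
#'   `removed_invariant`, `removed_correlated` and `threshold`)
#' @export
filter_features <- function(block, threshold = 0.9) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be a single value in (0, 1]")
  }
  m <- block$matrix
  vars <- apply(m, 2L, stats::var)
  invariant <- vars == 0 | !is.finite(vars)
  removed_invariant <- block$feature_names[invariant]
  m <- m[, !invariant, drop = FALSE]

  removed_correlated <- data.frame(kept = character(0), removed = character(0),
                                   correlation = numeric(0))
  if (ncol(m) > 1L) {
    cm <- suppressWarnings(stats::cor(m))
    keep <- rep(TRUE, ncol(m))
    for (j in 2:ncol(m)) {
      prior <- which(keep[seq_len(j - 1L)])
      if (!length(prior)) next
      r <- abs(cm[prior, j])
      off <- which(r > threshold)
      if (length(off)) {
        keep[j] <- FALSE
        i <- prior[off[which.max(r[off])]]
        removed_correlated <- rbind(removed_correlated, data.frame(
          kept = colnames(m)[i], removed = colnames(m)[j],
          correlation = cm[i, j]))
      }
    }
    m <- m[, keep, drop = FALSE]
  }
  out <- descriptor_block(m, block$space, block$kind,
                          feature_names = colnames(m),
                          compound_ids = block$compound_ids)
  report <- structure(list(removed_invariant = removed_invariant,
                           removed_correlated = removed_correlated,
                           threshold = threshold),
                      class = "filter_report")
  list(block = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d invariant, %d correlated (>|%.2f|) removed\n",
              length(x$removed_invariant), nrow(x$removed_correlated),
              x$threshold))
  invisible(x)
}

#' Apply a fitted feature filter to another block
#'
#' Projects a block onto the feature set that survived [filter_features()]
#' on a reference (training) block — used so held-out compounds are filtered
#' with training-set decisions only.
#'
#' @param block a `descriptor_block`
#' @param fitted the filtered block returned by [filter_features()]
#' @return a `descriptor_block` restricted to the fitted feature set
#' @export
apply_feature_filter <- function(block, fitted) {
  keep <- match(fitted$feature_names, block$feature_names)
  if (anyNA(keep)) stop("block lacks features present in the fitted filter")
  descriptor_block(block$matrix[, keep, drop = FALSE], block$space,
                   block$kind, fitted$feature_names, block$compound_ids)
}
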