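#' @importFrom ChemmineOB convertFormat forEachMol fingerprint_OB prop_OB
#'   smartsSearch_OB exactMass_OB
NULL

# Internal OpenBabel wrappers. All structure handling in the package funnels
# through these so that parsing, canonicalization and error behaviour are
# uniform. OpenBabel reports parse failures by emitting an empty string (and
# noise on stderr); we convert that into a structured R condition.

#' Signal a structure parse error
#'
#' @param smiles offending structure string
#' @param call calling context
#' @noRd
parse_error <- function(smiles, call = sys.call(-1)) {
  stop(structure(
    class = c("oculotox_parse_error", "error", "condition"),
    list(message = sprintf("cannot parse structure: '%s'", smiles),
         call = call, smiles = smiles)
  ))
}

#' Canonical SMILES via OpenBabel
#'
#' @param smiles character vector of SMILES strings
#' @param options optional OpenBabel option data.frame (names, args)
#' @return character vector of canonical SMILES; `NA_character_` where the
#'   input does not parse
#' @noRd
ob_canonical <- function(smiles, options = NULL) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- tryCatch({
      if (is.null(options)) {
        ChemmineOB::convertFormat("SMI", "CAN", s)
      } else {
        ChemmineOB::convertFormat("SMI", "CAN", s, options = options)
      }
    }, error = function(e) "")
    out <- sub("[\t\n ].*$", "", out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

#' Canonical SMILES after charge neutralization
#'
#' Applies OpenBabel's neutralize operation: protonation-state charges
#' ([O-] on acids, [NH3+] on amines, ...) are removed where valence rules
#' permit; non-neutralizable centers such as quaternary ammonium keep their
#' charge.
#' @noRd
ob_neutralize <- function(smiles) {
  ob_canonical(smiles, options = data.frame(names = "neutralize", args = ""))
}

#' Apply a function to each parsed molecule
#'
#' Parses each SMILES once and calls `f(molRef)` on it, so several
#' descriptor spaces can be computed per parse.
#'
#' @param smiles character vector
#' @param f function of a single OBMol reference
#' @return list of results; elements are `NULL` where parsing or `f` failed
#' @noRd
mol_apply <- function(smiles, f) {
  lapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NULL)
    res <- tryCatch(
      ChemmineOB::forEachMol("SMILES", s, function(m) f(m)),
      error = function(e) NULL
    )
    if (is.list(res) && length(res) == 1L) res[[1L]] else res
  })
}

#' Count SMARTS pattern matches in one molecule
#' @noRd
ob_count_matches <- function(molref, smarts) {
  as.numeric(ChemmineOB::smartsSearch_OB(list(molref), smarts))
}

#' Count SMARTS matches for a vector of SMILES
#'
#' @return numeric vector; NA where the structure does not parse
#' @noRd
smarts_count <- function(smiles, smarts) {
  out <- mol_apply(smiles, function(m) ob_count_matches(m, smarts))
  vapply(out, function(x) if (is.null(x)) NA_real_ else x, numeric(1))
}

#' Locate the OpenBabel command-line binary
#' @noRd
obabel_bin <- function() {
  bin <- Sys.which("obabel")
  if (!nzchar(bin)) stop("the 'obabel' executable is not on the PATH")
  bin
}

#' Batch canonical SMILES via the OpenBabel command line
#'
#' One subprocess canonicalizes the whole vector; index titles keep the
#' output aligned when some inputs fail to parse. Used on the hot paths
#' (fixture generation, large tables) where one external call beats
#' thousands of in-process ones.
#'
#' @param smiles character vector
#' @return character vector, `NA_character_` where parsing failed
#' @noRd
ob_canonical_batch <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  infile <- tempfile(fileext = ".smi"); outfile <- tempfile(fileext = ".smi")
  on.exit(unlink(c(infile, outfile)))
  writeLines(paste(smiles, sprintf("m%d", seq_len(n))), infile)
  suppressWarnings(system2(obabel_bin(),
                           c(infile, "-ocan", "-e", "-O", outfile),
                           stdout = FALSE, stderr = FALSE))
  out <- rep(NA_character_, n)
  if (file.exists(outfile)) {
    lines <- readLines(outfile)
    parts <- strsplit(lines, "[ \t]+")
    for (p in parts) {
      if (length(p) >= 2L) {
        i <- suppressWarnings(as.integer(sub("^m", "", p[[2L]])))
        if (!is.na(i)) out[i] <- p[[1L]]
      }
    }
  }
  out
}

#' Batch ECFP4 fingerprints via the OpenBabel command line
#'
#' The in-process fingerprint plugin retains native memory per call, which
#' matters at thousands of molecules; a one-shot subprocess returns the
#' same fingerprints (FPS hex) and releases everything on exit.
#'
#' @param smiles character vector
#' @return integer matrix n x 4096; all-NA rows where parsing failed
#' @noRd
ob_ecfp4_batch <- function(smiles) {
  n <- length(smiles)
  out <- matrix(NA_integer_, n, 4096L)
  if (n == 0L) return(out)
  infile <- tempfile(fileext = ".smi"); outfile <- tempfile(fileext = ".fps")
  on.exit(unlink(c(infile, outfile)))
  writeLines(paste(smiles, sprintf("m%d", seq_len(n))), infile)
  suppressWarnings(system2(obabel_bin(),
                           c(infile, "-ofps", "-xfECFP4", "-e", "-O",
                             outfile),
                           stdout = FALSE, stderr = FALSE))
  if (!file.exists(outfile)) return(out)
  lines <- readLines(outfile)
  lines <- lines[!startsWith(lines, "#")]
  # hex nibble -> 4 bits, most significant first
  nib <- sapply(0:15, function(v) as.integer(intToBits(v))[4:1])
  for (ln in lines) {
    p <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(p) < 2L) next
    i <- suppressWarnings(as.integer(sub("^m", "", p[[2L]])))
    if (is.na(i)) next
    chars <- strtoi(strsplit(tolower(p[[1L]]), "")[[1L]], 16L)
    out[i, ] <- as.integer(nib[, chars + 1L])
  }
  out
}

#' Does the structure contain at least one carbon atom?
#' @noRd
has_carbon <- function(smiles) {
  n <- smarts_count(smiles, "[#6]")
  !is.na(n) & n > 0
}

#' Split a (canonical) SMILES into fragments
#' @noRd
split_fragments <- function(smiles) {
  strsplit(smiles, ".", fixed = TRUE)[[1L]]
}

# Pentavalent nitro forms are rewritten to the charge-separated resonance
# form before canonicalization so that both common ways of writing a nitro
# group map to one canonical structure.
#' @noRd
normalize_nitro <- function(smiles) {
  s <- gsub("O=N(=O)", "O=[N+]([O-])", smiles, fixed = TRUE)
  gsub("N(=O)=O", "[N+](=O)[O-]", s, fixed = TRUE)
}

#' Hazard-ordered class labels
#'
#' Orders a set of class labels from most to least hazardous, used for
#' conservative tie-breaking: when votes or probabilities tie, the more
#' hazardous class wins. Labels not in the known alphabet keep their
#' incoming order, after the known ones.
#'
#' @param labels character vector of class labels
#' @return `labels` reordered, most hazardous first
#' @export
hazard_order <- function(labels) {
  known <- c("CAT1", "CORROSIVE", "POS", "CAT2A", "CAT2B", "IRRITANT",
             "NEG", "NC", "UNLABELED")
  rank <- match(labels, known)
  rank[is.na(rank)] <- length(known) + seq_len(sum(is.na(rank)))
  labels[order(rank)]
}
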