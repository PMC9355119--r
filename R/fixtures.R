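# Synthetic structure generator. Emits valid SMILES from a small, auditable
# scaffold grammar (alkyl/aryl chains with decorating groups) and plants a
# toxophore substructure in the positive fraction, so that every pipeline
# stage — curation, descriptors, balancing, modeling, validation — can be
# exercised with known ground truth and no external data. Optional
# injections (label noise, concordant/discordant duplicates, salt forms,
# inorganics, mixtures) emulate the artifacts real regulatory datasets
# carry into curation.

# grammar fragments: chain units are valid when concatenated; tails are
# valid terminal fragments
.chain_units <- c("C", "CC", "CCC", "C(C)", "C(Cl)", "C(F)", "C(O)",
                  "C(C)(C)")
.neutral_tails <- c("", "c1ccccc1", "C1CCCCC1", "c1ccc(Cl)cc1",
                    "c1ccc(O)cc1", "c1ccc(OC)cc1", "C(=O)OC", "C(=O)OCC",
                    "OC", "OCC", "N(C)C", "N", "O", "C#N", "SC",
                    "c1ccco1")
.salt_suffixes <- c(".[Na+].[Cl-]", ".O", ".Cl")
.inorganic_pool <- c("O", "[Na+].[Cl-]", "OS(=O)(=O)O", "N#N", "O=C=O",
                     "[Mg+2].[Cl-].[Cl-]")
.mixture_pool <- c("CCO.CCCC", "CCCCO.c1ccccc1", "CCN.CCCO",
                   "c1ccccc1C.CCOCC")

#' Fixture generator configuration
#'
#' Defaults describe the planted-signal recovery setting used throughout
#' the package's validation: 400 compounds, balanced classes, a sulfonic
#' acid toxophore and 10% label noise, with no curation artifacts injected.
#'
#' @param n_compounds number of core (labeled, pre-injection) records
#' @param toxophore substructure planted in positives, written as a
#'   terminal SMILES fragment that is also a valid SMARTS pattern
#' @param noise_rate fraction of core labels flipped (label =
#'   contains(toxophore) XOR noise); exactly `round(noise_rate * n)` flips
#' @param imbalance_ratio negative:positive ratio of the core set
#' @param duplicate_rate fraction of core records duplicated (half
#'   concordant, half discordant copies)
#' @param salt_rate fraction of core records rewritten as salt/solvate forms
#' @param n_inorganics,n_mixtures junk records appended for curation tests
#' @param class_counts optional named GHS counts
#'   (`c(CAT1 = , CAT2A = , CAT2B = , NC = )`); when given, the generator
#'   produces a multiclass fixture and `n_compounds`/`imbalance_ratio` are
#'   ignored
#' @param rng_seed seed; the whole fixture is reproducible from it
#' @return object of class `fixture_config`
#' @export
fixture_config <- function(n_compounds = 400L, toxophore = "S(=O)(=O)O",
                           noise_rate = 0.1, imbalance_ratio = 1,
                           duplicate_rate = 0, salt_rate = 0,
                           n_inorganics = 0L, n_mixtures = 0L,
                           class_counts = NULL, rng_seed = 1L) {
  stopifnot(noise_rate >= 0, noise_rate <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1,
            salt_rate >= 0, salt_rate <= 1,
            imbalance_ratio >= 0)
  if (!is.null(class_counts)) {
    stopifnot(setequal(names(class_counts),
                       c("CAT1", "CAT2A", "CAT2B", "NC")))
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 toxophore = toxophore, noise_rate = noise_rate,
                 imbalance_ratio = imbalance_ratio,
                 duplicate_rate = duplicate_rate, salt_rate = salt_rate,
                 n_inorganics = as.integer(n_inorganics),
                 n_mixtures = as.integer(n_mixtures),
                 class_counts = class_counts,
                 rng_seed = as.integer(rng_seed)),
            class = "fixture_config")
}

#' Random scaffold chain from the grammar
#' @noRd
random_chain <- function(n) {
  vapply(seq_len(n), function(i) {
    len <- sample(1:6, 1L)
    paste(sample(.chain_units, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate n structurally unique SMILES of one class
#'
#' @param tails terminal fragments appended to the chain
#' @param exclude canonical keys already taken
#' @noRd
gen_unique_smiles <- function(n, tails, exclude = character(0)) {
  out <- character(0); keys <- character(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > 60L) stop("scaffold grammar exhausted: cannot generate ",
                          n, " unique structures")
    m <- max(16L, 2L * (n - length(out)))
    cand <- paste0(random_chain(m), sample(tails, m, replace = TRUE))
    canon <- ob_canonical_batch(cand)
    ok <- !is.na(canon) & !duplicated(canon) & !(canon %in% keys) &
      !(canon %in% exclude)
    out <- c(out, cand[ok])
    keys <- c(keys, canon[ok])
  }
  list(smiles = out[seq_len(n)], keys = keys[seq_len(n)])
}

#' Generate a synthetic labeled structure set
#'
#' Produces raw, pre-curation records: core compounds with a planted
#' toxophore signal, plus the configured injections. Same seed, same
#' output. The injected-artifact counts are recorded and retrievable with
#' [fixture_manifest()].
#'
#' @param cfg a [fixture_config()]
#' @return `compound_records` table (with a `"manifest"` attribute)
#' @export
generate_fixture <- function(cfg = fixture_config()) {
  stopifnot(inherits(cfg, "fixture_config"))
  with_seed(cfg$rng_seed, {
    tox_tails <- c(cfg$toxophore, paste0("C", cfg$toxophore),
                   paste0("c1ccc(", cfg$toxophore, ")cc1"))
    ald_tails <- c("C=O", "CC=O", "c1ccc(C=O)cc1")

    if (is.null(cfg$class_counts)) {
      n <- cfg$n_compounds
      n_pos <- round(n / (1 + cfg$imbalance_ratio))
      n_neg <- n - n_pos
      pos <- gen_unique_smiles(n_pos, tox_tails)
      neg <- gen_unique_smiles(n_neg, .neutral_tails)
      smiles <- c(pos$smiles, neg$smiles)
      label <- c(rep("POS", n_pos), rep("NEG", n_neg))
    } else {
      cc <- cfg$class_counts
      n <- sum(cc)
      cat1 <- gen_unique_smiles(cc[["CAT1"]], tox_tails)
      irr <- gen_unique_smiles(cc[["CAT2A"]] + cc[["CAT2B"]], ald_tails)
      nc <- gen_unique_smiles(cc[["NC"]], .neutral_tails)
      smiles <- c(cat1$smiles, irr$smiles, nc$smiles)
      label <- c(rep("CAT1", cc[["CAT1"]]), rep("CAT2A", cc[["CAT2A"]]),
                 rep("CAT2B", cc[["CAT2B"]]), rep("NC", cc[["NC"]]))
    }

    # label noise: exactly round(noise_rate * n) flips
    n_noise <- round(cfg$noise_rate * n)
    if (n_noise > 0L) {
      flip <- sample.int(n, n_noise)
      classes <- unique(label)
      label[flip] <- vapply(label[flip], function(l) {
        sample(setdiff(classes, l), 1L)
      }, character(1))
    }

    # salt/solvate forms
    n_salt <- round(cfg$salt_rate * n)
    if (n_salt > 0L) {
      si <- sample.int(n, n_salt)
      smiles[si] <- paste0(smiles[si],
                           sample(.salt_suffixes, n_salt, replace = TRUE))
    }

    # duplicates: half concordant, half discordant
    n_dup <- round(cfg$duplicate_rate * n)
    n_conc <- ceiling(n_dup / 2); n_disc <- n_dup - n_conc
    dup_smiles <- character(0); dup_label <- character(0)
    if (n_dup > 0L) {
      di <- sample.int(n, n_dup)
      dup_smiles <- smiles[di]
      dup_label <- label[di]
      if (n_disc > 0L) {
        disc <- seq.int(n_conc + 1L, n_dup)
        classes <- unique(label)
        dup_label[disc] <- vapply(dup_label[disc], function(l) {
          sample(setdiff(classes, l), 1L)
        }, character(1))
      }
    }

    junk_smiles <- c(
      if (cfg$n_inorganics > 0L)
        sample(.inorganic_pool, cfg$n_inorganics, replace = TRUE),
      if (cfg$n_mixtures > 0L)
        sample(.mixture_pool, cfg$n_mixtures, replace = TRUE)
    )

    all_smiles <- c(smiles, dup_smiles, junk_smiles)
    all_label <- c(label, dup_label, rep("NEG", length(junk_smiles)))
    records <- compound_records(
      all_smiles, label = all_label,
      record_id = sprintf("CMP%05d", seq_along(all_smiles)),
      source = "synthetic"
    )
    attr(records, "manifest") <- list(
      seed = cfg$rng_seed,
      n_core = n,
      class_counts = table(label),
      n_noise = n_noise,
      n_dup_concordant = n_conc,
      n_dup_discordant = n_disc,
      n_salt = n_salt,
      n_inorganic = cfg$n_inorganics,
      n_mixture = cfg$n_mixtures
    )
    records
  })
}

#' Summarize a fixture
#'
#' Reports observed class counts together with the injected-artifact counts
#' recorded at generation time; used as ground truth in curation tests.
#'
#' @param records a table produced by [generate_fixture()]
#' @return list with `n_records`, `class_counts` and `injected`
#' @export
fixture_manifest <- function(records) {
  injected <- attr(records, "manifest")
  list(n_records = nrow(records),
       class_counts = table(records$label),
       injected = injected)
}
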