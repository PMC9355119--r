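# Readers and writers: SMILES tables (CSV/TSV), SDF with labels in a named
# SD tag, descriptor blocks as dense CSV with a JSON sidecar, curation logs
# and applicability domains as JSON, and model bundles for round-tripping
# trained models.

#' Read a SMILES table into compound records
#'
#' @param path CSV or TSV file (separator inferred from the extension
#'   unless given)
#' @param smiles_col,id_col,label_col,source_col column names; `id_col`,
#'   `label_col` and `source_col` are optional in the file
#' @param sep field separator override
#' @return `compound_records` table
#' @export
read_smiles_table <- function(path, smiles_col = "smiles",
                              id_col = "record_id", label_col = "label",
                              source_col = "source", sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t"
           else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (!smiles_col %in% names(df))
    stop("column '", smiles_col, "' not found in ", path)
  compound_records(
    smiles = df[[smiles_col]],
    label = if (label_col %in% names(df)) df[[label_col]] else "UNLABELED",
    record_id = if (id_col %in% names(df)) df[[id_col]] else NULL,
    source = if (source_col %in% names(df)) df[[source_col]] else path
  )
}

#' Read an SDF file into compound records
#'
#' Structures are converted to SMILES; labels are taken from a named SD
#' data tag when present.
#'
#' @param path SDF file
#' @param label_tag SD tag holding the hazard label
#' @param id_tag SD tag holding the record id (molecule titles otherwise)
#' @return `compound_records` table
#' @export
read_sdf_records <- function(path, label_tag = "LABEL", id_tag = NULL) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("reading SDF requires the ChemmineR package")
  sdf <- ChemmineR::read.SDFset(path)
  smiles <- as.character(ChemmineR::sdf2smiles(sdf))
  tags <- ChemmineR::datablock(sdf)
  get_tag <- function(block, tag) {
    if (tag %in% names(block)) unname(block[[tag]]) else NA_character_
  }
  labels <- vapply(tags, get_tag, character(1), tag = label_tag)
  labels[is.na(labels)] <- "UNLABELED"
  ids <- if (!is.null(id_tag)) {
    vapply(tags, get_tag, character(1), tag = id_tag)
  } else NULL
  compound_records(smiles, label = labels, record_id = ids, source = path)
}

#' Write compound records to CSV
#'
#' @param records `compound_records` table (or the output of
#'   [as.data.frame.balanced_set()])
#' @param path output file
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Write a curation log as JSON
#'
#' @param log a `curation_log`
#' @param path output file
#' @export
write_curation_log <- function(log, path) {
  jsonlite::write_json(list(input_count = log$input_count,
                            output_count = log$output_count,
                            removed = as.list(log$removed)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a descriptor block as CSV plus JSON sidecar
#'
#' The matrix goes to `<path>`; space, kind, feature names (and, when
#' given, the feature-filter report) go to `<path>.json`.
#'
#' @param block a `descriptor_block`
#' @param path CSV output file
#' @param report optional `filter_report` to record alongside
#' @export
write_block <- function(block, path, report = NULL) {
  df <- data.frame(compound_id = block$compound_ids, block$matrix,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(space = block$space, kind = block$kind,
               feature_names = block$feature_names)
  if (!is.null(report)) {
    meta$filter <- list(threshold = report$threshold,
                        removed_invariant = report$removed_invariant,
                        removed_correlated = report$removed_correlated)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a descriptor block written by [write_block()]
#'
#' @param path CSV file with a `<path>.json` sidecar
#' @return a `descriptor_block`
#' @export
read_block <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  descriptor_block(m, meta$space, meta$kind,
                   feature_names = meta$feature_names,
                   compound_ids = df$compound_id)
}

#' Persist an applicability domain as JSON
#'
#' @param ad an `ad_threshold`
#' @param path output file
#' @export
write_ad <- function(ad, path) {
  jsonlite::write_json(unclass(ad), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an applicability domain written by [write_ad()]
#' @param path JSON file
#' @return an `ad_threshold`
#' @export
read_ad <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(k = as.integer(x$k), Z = x$Z, y_bar = x$y_bar,
                 sigma = x$sigma, D_T = x$D_T,
                 scaling = list(center = x$scaling$center,
                                scale = x$scaling$scale),
                 space = x$space),
            class = "ad_threshold")
}

#' Save a trained model bundle
#'
#' Writes a directory holding a JSON description plus the model state: the
#' serialized forest and its training block for RF; descriptor CSVs and
#' labels for a MuDRA reference. [load_model_bundle()] restores an object
#' whose predictions are bit-identical to the original's.
#'
#' @param model an `oculotox_rf` or `mudra_reference`
#' @param dir bundle directory (created if needed)
#' @export
save_model_bundle <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(model, "oculotox_rf")) {
    jsonlite::write_json(
      list(type = "rf", space = model$space, classes = model$classes,
           spec = unclass(model$spec)),
      file.path(dir, "bundle.json"), auto_unbox = TRUE, pretty = TRUE,
      null = "null")
    saveRDS(model, file.path(dir, "model.rds"))
  } else if (inherits(model, "mudra_reference")) {
    jsonlite::write_json(
      list(type = "mudra", spaces = names(model$blocks), k = model$k,
           similarity_floor = model$similarity_floor,
           classes = model$classes, labels = model$labels),
      file.path(dir, "bundle.json"), auto_unbox = TRUE, pretty = TRUE)
    for (sp in names(model$blocks)) {
      write_block(model$blocks[[sp]],
                  file.path(dir, paste0("reference_", sp, ".csv")))
    }
  } else {
    stop("unsupported model type")
  }
  invisible(dir)
}

#' Load a model bundle saved by [save_model_bundle()]
#'
#' @param dir bundle directory
#' @return an `oculotox_rf` or `mudra_reference`
#' @export
load_model_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "bundle.json"),
                              simplifyVector = TRUE)
  if (identical(meta$type, "rf")) {
    readRDS(file.path(dir, "model.rds"))
  } else if (identical(meta$type, "mudra")) {
    blocks <- lapply(meta$spaces, function(sp)
      read_block(file.path(dir, paste0("reference_", sp, ".csv"))))
    names(blocks) <- meta$spaces
    mudra_reference(blocks, meta$labels, k = meta$k,
                    similarity_floor = meta$similarity_floor)
  } else {
    stop("unrecognized bundle type in ", dir)
  }
}
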