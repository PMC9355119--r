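# Pipeline orchestration and batch virtual screening. A single
# configuration (list, YAML or JSON) drives curate -> featurize -> balance
# -> train -> validate, writing every intermediate artifact plus a
# provenance manifest; screening applies a saved model bundle to label-free
# structure lists.

#' @noRd
read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      config <- yaml::read_yaml(config)
    } else {
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  defaults <- list(endpoint = "irritation", algorithm = "rf",
                   spaces = c("MORGAN", "KEYS166", "PHYSCHEM"),
                   seed = 1L, balance = TRUE, ad = FALSE, ad_k = 5L,
                   ad_z = 0.5, n_trees = 500L, k = 5L,
                   similarity_floor = 0, filter_threshold = 0.9,
                   acceptability_threshold = 0.6, n_folds = 5L,
                   y_randomization_rounds = 0L)
  utils::modifyList(defaults, config)
}

#' @noRd
build_spec <- function(cfg) {
  if (toupper(cfg$algorithm) == "RF") {
    classifier_spec("RF", spaces = cfg$spaces[1L], n_trees = cfg$n_trees,
                    rng_seed = cfg$seed)
  } else {
    classifier_spec("MUDRA", spaces = cfg$spaces, k = cfg$k,
                    similarity_floor = cfg$similarity_floor)
  }
}

#' @noRd
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full modeling pipeline
#'
#' Executes curate, featurize, balance (binary endpoints), train and
#' validate from one configuration, writing every intermediate artifact and
#' a provenance manifest into `out_dir`. A stage failure halts the run with
#' the stage name; artifacts written by earlier stages are preserved.
#'
#' Configuration fields (all optional except the input): `input` (SMILES
#' CSV/TSV path) or `fixture` (arguments for [fixture_config()]);
#' `endpoint` (`"irritation"`, `"corrosion"` or `"ghs3"`); `algorithm`
#' (`"rf"` or `"mudra"`); `spaces`; `seed`; `balance`; `ad`, `ad_k`,
#' `ad_z`; `n_trees`; `k`; `similarity_floor`; `filter_threshold`;
#' `acceptability_threshold`; `y_randomization_rounds`.
#'
#' @param config configuration list, or path to a YAML/JSON file
#' @param out_dir artifact directory (created if needed)
#' @return (invisibly) a list with the curated records, blocks, model,
#'   `cv` result, `acceptability`, and the artifact directory
#' @export
run_pipeline <- function(config, out_dir = tempfile("oculotox_run_")) {
  cfg <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  raw <- run_stage("input", {
    if (!is.null(cfg$fixture)) {
      generate_fixture(do.call(fixture_config, cfg$fixture))
    } else if (!is.null(cfg$input)) {
      read_smiles_table(cfg$input)
    } else {
      stop("config needs either 'input' or 'fixture'")
    }
  })

  cur <- run_stage("curate", curate(raw))
  write_records_csv(cur$records, file.path(out_dir, "curated.csv"))
  write_curation_log(cur$log, file.path(out_dir, "curation_log.json"))

  records <- cur$records
  labels <- records$label
  if (cfg$endpoint == "ghs3") labels <- ghs_collapse(labels)

  spec <- build_spec(cfg)
  blocks <- run_stage("featurize", {
    b <- featurize(records$smiles, records$record_id, spaces = cfg$spaces)
    if (length(attr(b, "failed_ids")))
      stop("descriptors failed for: ",
           paste(attr(b, "failed_ids"), collapse = ", "))
    b
  })

  if (isTRUE(cfg$balance) && length(unique(labels)) == 2L) {
    bal <- run_stage("balance", {
      pos_lab <- hazard_order(unique(labels))[1L]
      balance_dataset(records[labels == pos_lab, , drop = FALSE],
                      records[labels != pos_lab, , drop = FALSE],
                      balance_config(
                        fingerprint_space =
                          if (spec$spaces[1L] %in% c("MORGAN", "KEYS166"))
                            spec$spaces[1L] else "MORGAN",
                        rng_seed = cfg$seed),
                      blocks = blocks)
    })
    bal_df <- as.data.frame(bal)
    write_records_csv(bal_df, file.path(out_dir, "balanced.csv"))
    jsonlite::write_json(
      list(seed = cfg$seed, n_similarity = nrow(bal$negatives_similarity),
           n_random = nrow(bal$negatives_random),
           similarity_scores = bal$similarity_scores),
      file.path(out_dir, "balance_manifest.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    keep <- match(bal_df$record_id, records$record_id)
    records <- records[keep, , drop = FALSE]
    labels <- labels[keep]
    blocks <- lapply(blocks, block_rows, idx = bal_df$record_id)
  }

  for (sp in names(blocks)) {
    write_block(blocks[[sp]],
                file.path(out_dir, paste0("block_", sp, ".csv")))
  }

  model <- run_stage("train", {
    if (spec$algorithm == "RF") {
      b <- blocks[[spec$spaces]]
      if (b$kind == "CONTINUOUS")
        b <- filter_features(b, cfg$filter_threshold)$block
      train_rf(b, labels, spec)
    } else {
      fb <- lapply(blocks[spec$spaces], function(b) {
        if (b$kind == "CONTINUOUS")
          filter_features(b, cfg$filter_threshold)$block else b
      })
      mudra_reference(fb, labels, k = spec$k,
                      similarity_floor = spec$similarity_floor)
    }
  })
  save_model_bundle(model, file.path(out_dir, "model_bundle"))

  cv <- run_stage("validate", {
    five_fold_external_cv(blocks, labels, spec, seed = cfg$seed,
                          n_folds = cfg$n_folds, ad = isTRUE(cfg$ad),
                          ad_k = cfg$ad_k, ad_z = cfg$ad_z,
                          filter_threshold = cfg$filter_threshold)
  })
  acc <- acceptability_check(
    if (inherits(cv$metrics, "multiclass_metrics")) cv$metrics
    else cv$metrics,
    threshold = cfg$acceptability_threshold)

  yrand <- NULL
  if (cfg$y_randomization_rounds > 0L) {
    yrand <- run_stage("validate", {
      y_randomization(blocks, labels, spec,
                      n_rounds = cfg$y_randomization_rounds,
                      seed = cfg$seed, n_folds = cfg$n_folds,
                      filter_threshold = cfg$filter_threshold)
    })
  }

  metrics_out <- metrics_as_list(cv$metrics)
  metrics_out$acceptability <- acc
  if (!is.null(yrand))
    metrics_out$y_randomization <- lapply(yrand, metrics_as_list)
  jsonlite::write_json(metrics_out, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(cv$predictions,
                   file.path(out_dir, "cv_predictions.csv"),
                   row.names = FALSE)

  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  provenance <- list(
    package = "oculotox",
    package_version = as.character(utils::packageVersion("oculotox")),
    r_version = R.version.string,
    seed = cfg$seed,
    config = cfg,
    config_md5 = unname(tools::md5sum(tmp))
  )
  unlink(tmp)
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(records = records, labels = labels, blocks = blocks,
                 model = model, cv = cv, acceptability = acc,
                 y_randomization = yrand, out_dir = out_dir))
}

#' @noRd
metrics_as_list <- function(m) {
  if (inherits(m, "metrics_report")) {
    out <- m[c("Se", "Sp", "CCR", "PPV", "NPV", "F1", "MCC", "Coverage")]
    out$counts <- unclass(m$counts)
    out
  } else if (inherits(m, "multiclass_metrics")) {
    list(average = m$average,
         per_class = lapply(m$per_class, metrics_as_list))
  } else {
    m
  }
}

#' Screen a structure list with a trained model
#'
#' Standardizes the input structures (rows that fail to parse are reported
#' with `status = "error"` and the batch continues), computes the
#' descriptor spaces the model needs, predicts every compound, and writes a
#' per-compound CSV report plus a summary. Nearest-neighbor evidence is
#' included for MuDRA models.
#'
#' @param input a `compound_records` table, a character vector of SMILES,
#'   or a path to a SMILES CSV/TSV
#' @param model an `oculotox_rf` or `mudra_reference` (or a bundle
#'   directory path)
#' @param ad optional `ad_threshold` for RF domain flags
#' @param out optional CSV output path
#' @return list with `report` (per-compound data.frame) and `summary`
#'   (counts, including `n_predicted_positive`)
#' @export
screen_compounds <- function(input, model, ad = NULL, out = NULL) {
  if (is.character(model) && length(model) == 1L)
    model <- load_model_bundle(model)
  records <- if (is.character(input) && length(input) == 1L &&
                 file.exists(input)) {
    read_smiles_table(input)
  } else if (is.character(input)) {
    compound_records(input)
  } else {
    input
  }
  if (nrow(records) == 0L) {
    rep0 <- data.frame(record_id = character(0), smiles = character(0),
                       predicted_label = character(0),
                       confidence = numeric(0), in_ad = character(0),
                       status = character(0))
    if (!is.null(out)) utils::write.csv(rep0, out, row.names = FALSE)
    return(list(report = rep0,
                summary = list(n_input = 0L, n_predicted = 0L,
                               n_failed = 0L, n_predicted_positive = 0L)))
  }

  std <- vapply(records$smiles, function(s) {
    tryCatch(standardize_structure(s),
             oculotox_parse_error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
  ok <- !is.na(std)

  spaces <- if (inherits(model, "oculotox_rf")) model$space
            else names(model$blocks)
  blocks <- featurize(std[ok], records$record_id[ok], spaces = spaces)
  failed <- attr(blocks, "failed_ids")
  preds <- predict_batch(model, blocks, ad = ad,
                         compound_ids = records$record_id[ok])
  evidence <- attr(preds, "evidence")

  report <- data.frame(record_id = records$record_id,
                       smiles = ifelse(ok, std, records$smiles),
                       predicted_label = NA_character_,
                       confidence = NA_real_,
                       in_ad = "NOT_ASSESSED",
                       status = ifelse(ok, "ok", "parse_error"),
                       stringsAsFactors = FALSE)
  m <- match(preds$compound_id, report$record_id)
  report$predicted_label[m] <- preds$predicted_label
  report$confidence[m] <- preds$confidence
  report$in_ad[m] <- preds$in_ad
  report$status[m] <- ifelse(preds$status == "ok", report$status[m],
                             "descriptor_error")
  if (!is.null(evidence)) {
    nn <- vapply(report$record_id, function(id) {
      e <- evidence[[id]]
      if (is.null(e)) NA_character_
      else paste(vapply(e, function(sp)
        sprintf("%s:%s(%.2f)", sp$space, sp$nn_id, sp$nn_similarity),
        character(1)), collapse = ";")
    }, character(1), USE.NAMES = FALSE)
    report$nearest_neighbors <- nn
  }

  hazard <- hazard_order(model$classes)[1L]
  summary <- list(
    n_input = nrow(records),
    n_predicted = sum(report$status == "ok"),
    n_failed = sum(report$status != "ok"),
    n_predicted_positive = sum(report$predicted_label == hazard,
                               na.rm = TRUE)
  )
  if (!is.null(out)) utils::write.csv(report, out, row.names = FALSE)
  list(report = report, summary = summary)
}
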