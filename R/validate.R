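# Model validation: confusion-matrix statistics, stratified five-fold
# external cross-validation, Y-randomization, and one-vs-all multiclass
# averaging.

#' Confusion counts for a binary endpoint
#'
#' @param truth,pred true and predicted labels
#' @param positive label counted as the positive (hazardous) class; defaults
#'   to the more hazardous of the observed labels
#' @return object of class `confusion_counts` with fields TP, TN, FP, FN
#' @export
confusion_counts <- function(truth, pred, positive = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  if (is.null(positive)) positive <- hazard_order(sort(unique(truth)))[1L]
  structure(list(
    TP = sum(truth == positive & pred == positive),
    TN = sum(truth != positive & pred != positive),
    FP = sum(truth != positive & pred == positive),
    FN = sum(truth == positive & pred != positive),
    positive = positive
  ), class = "confusion_counts")
}

#' @noRd
as_confusion_counts <- function(x) {
  if (inherits(x, "confusion_counts")) return(x)
  stopifnot(all(c("TP", "TN", "FP", "FN") %in% names(x)))
  structure(list(TP = x[["TP"]], TN = x[["TN"]], FP = x[["FP"]],
                 FN = x[["FN"]],
                 positive = if (!is.null(x[["positive"]])) x[["positive"]]
                            else NA_character_),
            class = "confusion_counts")
}

#' @noRd
safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Binary classification metrics
#'
#' Computes sensitivity, specificity, the correct classification rate
#' (balanced accuracy, `CCR = (Se + Sp) / 2`), positive and negative
#' predictive values, the F1 score and the Matthews correlation coefficient
#' from a confusion table. Any metric whose denominator is zero is reported
#' as `NA` (undefined), never silently as 0.
#'
#' @param counts a [confusion_counts()] object or a named list/vector with
#'   TP, TN, FP, FN
#' @param coverage optional coverage value (fraction of predictions inside
#'   the applicability domain), carried through into the report
#' @return object of class `metrics_report`
#' @export
binary_metrics <- function(counts, coverage = NULL) {
  cc <- as_confusion_counts(counts)
  if (any(unlist(cc[c("TP", "TN", "FP", "FN")]) < 0))
    stop("confusion counts must be non-negative")
  n <- cc$TP + cc$TN + cc$FP + cc$FN
  if (n == 0L) stop("no evaluated predictions")
  se <- safe_ratio(cc$TP, cc$TP + cc$FN)
  sp <- safe_ratio(cc$TN, cc$TN + cc$FP)
  mcc_den2 <- prod(c(cc$TP + cc$FP, cc$TP + cc$FN, cc$TN + cc$FP,
                     cc$TN + cc$FN))
  structure(list(
    Se = se, Sp = sp,
    CCR = if (is.na(se) || is.na(sp)) NA_real_ else (se + sp) / 2,
    PPV = safe_ratio(cc$TP, cc$TP + cc$FP),
    NPV = safe_ratio(cc$TN, cc$TN + cc$FN),
    F1 = safe_ratio(2 * cc$TP, 2 * cc$TP + cc$FP + cc$FN),
    MCC = if (mcc_den2 == 0) NA_real_ else
      (cc$TP * cc$TN - cc$FP * cc$FN) / sqrt(mcc_den2),
    Coverage = if (is.null(coverage)) NA_real_ else coverage,
    counts = cc
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  v <- unlist(x[c("CCR", "Se", "PPV", "Sp", "NPV", "F1", "MCC", "Coverage")])
  cat("<metrics_report>\n")
  print(round(v, digits))
  invisible(x)
}

#' Stratified fold assignment
#'
#' Shuffles within each class and deals compounds round-robin over folds
#' with a rotating per-class offset, so overall fold sizes differ by at most
#' one and class proportions are preserved.
#'
#' @param labels class labels
#' @param n_folds number of folds
#' @param seed RNG seed
#' @return integer vector of fold indices in `1..n_folds`
#' @export
stratified_folds <- function(labels, n_folds = 5L, seed = 1L) {
  labels <- as.character(labels)
  folds <- integer(length(labels))
  with_seed(seed, {
    offset <- 0L
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
      offset <- (offset + length(idx)) %% n_folds
    }
  })
  folds
}

#' @noRd
fit_fold_model <- function(spec, train_blocks, train_labels,
                           filter_threshold) {
  # continuous spaces: invariance/correlation filter fitted on training only
  fitted_blocks <- lapply(train_blocks, function(b) {
    if (b$kind == "CONTINUOUS") filter_features(b, filter_threshold)$block
    else b
  })
  if (spec$algorithm == "RF") {
    train_rf(fitted_blocks[[spec$spaces]], train_labels, spec)
  } else {
    mudra_reference(fitted_blocks, train_labels, k = spec$k,
                    similarity_floor = spec$similarity_floor)
  }
}

#' Five-fold external cross-validation
#'
#' The dataset is partitioned into `n_folds` stratified, near-equal parts
#' (an 80/20 modeling/test split at each iteration for five folds). Each
#' part serves once as the external test set: descriptor filtering, model
#' training and applicability-domain fitting happen strictly inside the
#' remaining training portion, and the held-out compounds are predicted.
#' Out-of-fold predictions are pooled and the headline metrics are computed
#' on the pool; per-fold reports are retained.
#'
#' @param blocks named list of `descriptor_block`s over the full dataset
#'   (all sharing the same compound ids, aligned to `labels`)
#' @param labels class labels aligned to the blocks
#' @param spec a [classifier_spec()]
#' @param seed fold-assignment seed
#' @param n_folds number of folds, default 5
#' @param ad assess the applicability domain of each fold's model (RF only)
#' @param ad_k,ad_z applicability-domain parameters
#' @param filter_threshold correlation cutoff for continuous spaces
#' @return object of class `cv_result`: `fold_assignments`, pooled
#'   `predictions`, overall `metrics`, `per_fold` reports, `seed`, `spec`
#' @export
five_fold_external_cv <- function(blocks, labels, spec, seed = 1L,
                                  n_folds = 5L, ad = FALSE, ad_k = 5L,
                                  ad_z = 0.5, filter_threshold = 0.9) {
  spaces <- spec$spaces
  ids <- blocks[[spaces[1L]]]$compound_ids
  labels <- as.character(labels)
  stopifnot(length(labels) == length(ids))
  folds <- stratified_folds(labels, n_folds, seed)
  preds <- vector("list", n_folds)
  per_fold <- vector("list", n_folds)

  for (f in seq_len(n_folds)) {
    tr <- folds != f; te <- !tr
    if (length(unique(labels[tr])) < 2L)
      stop("a class is absent from the training portion of fold ", f)
    train_blocks <- lapply(blocks[spaces], block_rows, idx = which(tr))
    test_blocks <- lapply(blocks[spaces], block_rows, idx = which(te))
    model <- fit_fold_model(spec, train_blocks, labels[tr], filter_threshold)
    ad_obj <- if (ad && spec$algorithm == "RF") {
      fit_ad(model$train_block, k = ad_k, Z = ad_z)
    } else NULL
    p <- predict_batch(model, test_blocks, ad = ad_obj)
    p$truth <- labels[te][match(p$compound_id, ids[te])]
    p$fold <- f
    preds[[f]] <- p[, c("compound_id", "truth", "predicted_label",
                        "confidence", "in_ad", "fold")]
    per_fold[[f]] <- pooled_metrics(preds[[f]])
  }
  pooled <- do.call(rbind, preds)
  rownames(pooled) <- NULL
  structure(list(
    fold_assignments = stats::setNames(folds, ids),
    predictions = pooled,
    metrics = pooled_metrics(pooled),
    per_fold = per_fold,
    seed = seed, spec = spec
  ), class = "cv_result")
}

#' Metrics over a prediction table with a truth column
#' @noRd
pooled_metrics <- function(p) {
  classes <- sort(unique(p$truth))
  coverage <- if (all(p$in_ad != "NOT_ASSESSED")) ad_coverage(p) else NULL
  if (length(classes) <= 2L) {
    binary_metrics(confusion_counts(p$truth, p$predicted_label),
                   coverage = coverage)
  } else {
    multiclass_metrics(p$truth, p$predicted_label)
  }
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s on %s, %d folds, %d pooled predictions\n",
              x$spec$algorithm, paste(x$spec$spaces, collapse = "+"),
              length(x$per_fold), nrow(x$predictions)))
  m <- if (inherits(x$metrics, "metrics_report")) x$metrics
       else x$metrics$average
  print(m)
  invisible(x)
}

#' Y-randomization
#'
#' Permutes the labels (seeded), reruns the full external cross-validation,
#' and records the resulting metrics — repeated `n_rounds` times. Models
#' refitted on shuffled labels should perform at chance (CCR near 0.5, MCC
#' near 0); real-model performance clearly above the shuffled distribution
#' indicates the signal is not an artifact.
#'
#' @inheritParams five_fold_external_cv
#' @param n_rounds number of label-shuffling rounds, default 10
#' @param ... further arguments passed to [five_fold_external_cv()]
#' @param .permutations optional list of explicit permutations (testing
#'   hook; an identity permutation reproduces the un-shuffled metrics)
#' @return list of per-round metric reports (class `y_randomization`)
#' @export
y_randomization <- function(blocks, labels, spec, n_rounds = 10L, seed = 1L,
                            ..., .permutations = NULL) {
  n <- length(labels)
  perms <- if (is.null(.permutations)) {
    with_seed(seed, lapply(seq_len(n_rounds), function(i) sample.int(n)))
  } else {
    .permutations
  }
  fold_seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2,
                                           length(perms)))
  reports <- lapply(seq_along(perms), function(i) {
    cv <- five_fold_external_cv(blocks, as.character(labels)[perms[[i]]],
                                spec, seed = fold_seeds[i], ...)
    cv$metrics
  })
  class(reports) <- "y_randomization"
  reports
}

#' @export
print.y_randomization <- function(x, ...) {
  ccr <- vapply(x, function(m) {
    if (inherits(m, "metrics_report")) m$CCR else m$average$CCR
  }, numeric(1))
  cat(sprintf("<y_randomization> %d rounds, mean shuffled CCR = %.3f\n",
              length(x), mean(ccr, na.rm = TRUE)))
  invisible(x)
}

#' Collapse GHS categories to the three modeling classes
#'
#' `CAT1` becomes `CORROSIVE`, `CAT2A` and `CAT2B` become `IRRITANT`, `NC`
#' stays `NC`.
#'
#' @param labels GHS category labels
#' @return character vector of three-class labels
#' @export
ghs_collapse <- function(labels) {
  map <- c(CAT1 = "CORROSIVE", CAT2A = "IRRITANT", CAT2B = "IRRITANT",
           NC = "NC")
  out <- map[as.character(labels)]
  if (anyNA(out)) stop("unknown GHS label: ",
                       paste(unique(labels[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Multiclass metrics by one-vs-all averaging
#'
#' Each class is collapsed to a one-vs-all binary problem and scored with
#' [binary_metrics()]; the overall report is the unweighted mean of the
#' per-class values, skipping undefined (NA) entries with a warning.
#'
#' @param truth,pred class labels
#' @param classes the class alphabet (defaults to the labels observed in
#'   `truth`); predictions outside the alphabet raise an error
#' @return list of class `multiclass_metrics` with `per_class` (named list
#'   of `metrics_report`s), `average` (named numeric vector) and the
#'   cross-tabulation `table`
#' @export
multiclass_metrics <- function(truth, pred, classes = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (is.null(classes)) classes <- sort(unique(truth))
  bad <- setdiff(unique(c(truth, pred)), classes)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  per_class <- lapply(classes, function(cl) {
    binary_metrics(confusion_counts(truth == cl, pred == cl,
                                    positive = "TRUE"))
  })
  names(per_class) <- classes
  metric_names <- c("Se", "Sp", "CCR", "PPV", "NPV", "F1", "MCC")
  avg <- vapply(metric_names, function(m) {
    v <- vapply(per_class, `[[`, numeric(1), m)
    if (anyNA(v)) {
      warning("metric ", m, " undefined for some class; ",
              "averaging over the defined classes", call. = FALSE)
      v <- v[!is.na(v)]
    }
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  structure(list(per_class = per_class, average = as.list(avg),
                 table = table(truth = truth, pred = pred)),
            class = "multiclass_metrics")
}

#' @export
print.multiclass_metrics <- function(x, digits = 2, ...) {
  cat("<multiclass_metrics> one-vs-all averages:\n")
  print(round(unlist(x$average), digits))
  invisible(x)
}

#' Check a metrics report against the model-acceptability threshold
#'
#' A model is acceptable when sensitivity, specificity, CCR, PPV and NPV
#' all reach the threshold (inclusive), by default 0.6. Undefined (NA)
#' metrics count as failing.
#'
#' @param report a `metrics_report`, a `multiclass_metrics` (its average is
#'   checked), or a named list of metric values
#' @param threshold acceptance threshold, default 0.6
#' @return list with `pass` (logical) and `failing` (character vector of
#'   metric names below threshold)
#' @export
acceptability_check <- function(report, threshold = 0.6) {
  if (inherits(report, "multiclass_metrics")) report <- report$average
  checked <- c("Se", "Sp", "CCR", "PPV", "NPV")
  vals <- vapply(checked, function(m) {
    v <- report[[m]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  failing <- checked[is.na(vals) | vals < threshold]
  list(pass = length(failing) == 0L, failing = failing)
}
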