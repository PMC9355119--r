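# Classifier back ends. Two learners share a train/predict contract:
# a Random Forest over a single descriptor space, and MuDRA
# (multi-descriptor read-across), an instance-based predictor that consults
# nearest neighbors in several descriptor spaces at once and lets the space
# holding the most similar neighbor decide.

#' Classifier specification
#'
#' @param algorithm `"RF"` or `"MUDRA"`
#' @param spaces descriptor spaces the classifier consumes. RF uses exactly
#'   one; MuDRA is multi-descriptor and requires at least two (a
#'   single-space MuDRA — plain kNN read-across — is permitted only with
#'   `allow_single_space = TRUE`, for testing).
#' @param n_trees,max_depth,rng_seed Random-Forest hyperparameters: number
#'   of trees (default 500), depth cap (`NULL` = unlimited) and seed.
#' @param k,similarity_floor MuDRA hyperparameters: neighbor count (default
#'   5) and minimum similarity for a neighbor to contribute to the vote
#'   (default 0, i.e. no floor).
#' @param allow_single_space permit a one-space MuDRA
#' @return object of class `classifier_spec`
#' @export
classifier_spec <- function(algorithm = c("RF", "MUDRA"), spaces,
                            n_trees = 500L, max_depth = NULL, rng_seed = 1L,
                            k = 5L, similarity_floor = 0,
                            allow_single_space = FALSE) {
  algorithm <- match.arg(algorithm)
  spaces <- match.arg(spaces, c("MORGAN", "KEYS166", "PHYSCHEM"),
                      several.ok = TRUE)
  if (algorithm == "RF" && length(spaces) != 1L)
    stop("RF uses exactly one descriptor space")
  if (algorithm == "MUDRA" && length(spaces) < 2L && !allow_single_space)
    stop("MuDRA is multi-descriptor: configure at least two spaces")
  structure(list(algorithm = algorithm, spaces = spaces,
                 n_trees = as.integer(n_trees), max_depth = max_depth,
                 rng_seed = as.integer(rng_seed), k = as.integer(k),
                 similarity_floor = similarity_floor),
            class = "classifier_spec")
}

#' Train a Random-Forest classifier on one descriptor block
#'
#' A seeded, single-threaded probability forest. Class labels are assigned
#' from class probabilities with a conservative tie rule: in the binary case
#' the more hazardous class is predicted when its probability is >= 0.5; in
#' the multiclass case probability ties break toward the more hazardous
#' class (see [hazard_order()]).
#'
#' @param block training `descriptor_block`
#' @param labels class labels aligned to block rows
#' @param spec a [classifier_spec()] with `algorithm = "RF"`
#' @return object of class `oculotox_rf`
#' @export
train_rf <- function(block, labels, spec) {
  stopifnot(inherits(spec, "classifier_spec"), spec$algorithm == "RF")
  labels <- as.character(labels)
  if (length(labels) != nrow(block$matrix))
    stop("labels are not aligned to the descriptor block")
  classes <- hazard_order(sort(unique(labels)))
  if (length(classes) < 2L)
    stop("training data contains a single class")
  x <- block$matrix
  colnames(x) <- make.names(colnames(x))
  forest <- ranger::ranger(
    x = x, y = factor(labels, levels = classes),
    probability = TRUE,
    num.trees = spec$n_trees,
    mtry = max(1L, floor(sqrt(ncol(x)))),
    max.depth = if (is.null(spec$max_depth)) 0 else spec$max_depth,
    seed = spec$rng_seed,
    num.threads = 1L
  )
  structure(list(forest = forest, spec = spec, space = block$space,
                 classes = classes, train_block = block),
            class = "oculotox_rf")
}

#' @export
print.oculotox_rf <- function(x, ...) {
  cat(sprintf("<oculotox_rf> %s space, %d trees, classes: %s\n",
              x$space, x$spec$n_trees, paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Class probabilities and labels for an RF model
#' @noRd
rf_predict <- function(model, block) {
  m <- apply_feature_filter(block, model$train_block)$matrix
  colnames(m) <- make.names(colnames(m))
  probs <- stats::predict(model$forest, data = m,
                          num.threads = 1L)$predictions
  probs <- probs[, model$classes, drop = FALSE]
  hazard <- model$classes[1L] # most hazardous class
  if (length(model$classes) == 2L) {
    lab <- ifelse(probs[, hazard] >= 0.5, hazard, model$classes[2L])
  } else {
    lab <- apply(probs, 1L, function(p) {
      top <- which(p == max(p))
      names(p)[top[1L]] # columns already in hazard order
    })
  }
  conf <- probs[cbind(seq_len(nrow(probs)), match(lab, colnames(probs)))]
  data.frame(compound_id = block$compound_ids, predicted_label = lab,
             confidence = conf, stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a MuDRA reference (the stored training instances)
#'
#' MuDRA fits no model: prediction consults these training instances
#' directly. Every configured space must index the identical compound list.
#' Continuous spaces are z-scaled with training statistics so that their
#' inverse-distance similarity is comparable with the Tanimoto similarity of
#' the bit spaces.
#'
#' @param blocks named list of training `descriptor_block`s (>= 2 spaces for
#'   a genuine multi-descriptor reference)
#' @param labels class labels aligned to the blocks
#' @param k neighbor count, default 5
#' @param similarity_floor neighbors below this similarity do not vote
#' @return object of class `mudra_reference`
#' @export
mudra_reference <- function(blocks, labels, k = 5L, similarity_floor = 0) {
  stopifnot(length(blocks) >= 1L)
  ids <- blocks[[1L]]$compound_ids
  for (b in blocks) {
    if (!identical(b$compound_ids, ids))
      stop("all spaces must index the identical training compound list")
  }
  labels <- as.character(labels)
  if (length(labels) != length(ids))
    stop("labels are not aligned to the training blocks")
  if (k < 1L || k > length(ids))
    stop("k must be between 1 and the training-set size")
  scalings <- lapply(blocks, ad_scale_params)
  structure(list(blocks = blocks, labels = labels, ids = ids,
                 k = as.integer(k), similarity_floor = similarity_floor,
                 classes = hazard_order(sort(unique(labels))),
                 scalings = scalings),
            class = "mudra_reference")
}

#' @export
print.mudra_reference <- function(x, ...) {
  cat(sprintf("<mudra_reference> %d instances, spaces: %s, k=%d\n",
              length(x$ids), paste(names(x$blocks), collapse = ", "), x$k))
  invisible(x)
}

#' Similarity of query rows to the training instances in one space
#' @noRd
mudra_similarity <- function(ref, space, qmat) {
  b <- ref$blocks[[space]]
  if (ncol(qmat) != ncol(b$matrix))
    stop("query vector length does not match space ", space)
  if (b$kind == "BIT") {
    tanimoto_matrix(qmat, b$matrix)
  } else {
    sc <- ref$scalings[[space]]
    1 / (1 + euclidean_cross(ad_apply_scale(qmat, sc),
                             ad_apply_scale(b$matrix, sc)))
  }
}

#' MuDRA predictions for a set of query matrices
#'
#' @param qmats named list of query matrices (rows aligned across spaces)
#' @param ids query compound ids
#' @return list(predictions = data.frame, evidence = list)
#' @noRd
mudra_predict_all <- function(qmats, ids, ref) {
  spaces <- names(ref$blocks)
  sims <- lapply(spaces, function(sp) mudra_similarity(ref, sp, qmats[[sp]]))
  names(sims) <- spaces
  n <- length(ids)
  out <- data.frame(compound_id = ids,
                    predicted_label = character(n),
                    confidence = numeric(n),
                    low_evidence = logical(n),
                    stringsAsFactors = FALSE)
  evidence <- vector("list", n)
  names(evidence) <- ids
  for (i in seq_len(n)) {
    per_space <- lapply(spaces, function(sp) {
      s <- sims[[sp]][i, ]
      ord <- order(-s, seq_along(s)) # stable: ties by training index
      nn <- ord[seq_len(ref$k)]
      w <- s[nn]
      w[w < ref$similarity_floor] <- 0
      votes <- vapply(ref$classes, function(cl)
        sum(w[ref$labels[nn] == cl]), numeric(1))
      winner <- ref$classes[which.max(votes)] # classes in hazard order
      list(space = sp,
           nn_id = ref$ids[ord[1L]],
           nn_similarity = unname(s[ord[1L]]),
           votes = votes,
           local_vote = winner)
    })
    names(per_space) <- spaces
    top_sims <- vapply(per_space, `[[`, numeric(1), "nn_similarity")
    total_votes <- vapply(per_space, function(e) sum(e$votes), numeric(1))
    if (all(total_votes == 0)) {
      # no evidence anywhere: conservative hazardous call, zero confidence
      out$predicted_label[i] <- ref$classes[1L]
      out$confidence[i] <- 0
      out$low_evidence[i] <- TRUE
    } else {
      best <- which.max(top_sims) # ties: first configured space
      e <- per_space[[best]]
      out$predicted_label[i] <- e$local_vote
      tot <- sum(e$votes)
      out$confidence[i] <- if (tot > 0) max(e$votes) / tot else 0
      out$low_evidence[i] <- tot == 0
    }
    evidence[[i]] <- per_space
  }
  list(predictions = out, evidence = evidence)
}

#' Predict one compound with MuDRA
#'
#' In each descriptor space the `k` most similar training compounds form a
#' similarity-weighted class vote; the consensus label is taken from the
#' space whose top neighbor is most similar to the query, and the confidence
#' is that space's winning vote fraction. Per-space evidence (nearest
#' neighbor, similarity, local vote) is returned for every configured
#' space. When every neighbor in every space has zero similarity the most
#' hazardous class is returned with confidence 0 and `low_evidence = TRUE`.
#'
#' @param query_blocks named list of query feature vectors (or 1-row
#'   matrices), one per reference space
#' @param ref a [mudra_reference()]
#' @param compound_id id reported in the prediction
#' @return a list with `compound_id`, `predicted_label`, `confidence`,
#'   `low_evidence`, `per_space_evidence` and `in_ad = "NOT_ASSESSED"`
#' @export
mudra_predict <- function(query_blocks, ref, compound_id = "query") {
  qmats <- lapply(names(ref$blocks), function(sp) {
    q <- query_blocks[[sp]]
    if (is.null(q)) stop("query lacks a vector in space ", sp)
    if (inherits(q, "descriptor_block")) q <- q$matrix
    if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
    q
  })
  names(qmats) <- names(ref$blocks)
  res <- mudra_predict_all(qmats, compound_id, ref)
  p <- res$predictions
  list(compound_id = p$compound_id, predicted_label = p$predicted_label,
       confidence = p$confidence, low_evidence = p$low_evidence,
       per_space_evidence = res$evidence[[1L]], in_ad = "NOT_ASSESSED")
}

#' Batch prediction with optional applicability-domain assessment
#'
#' One prediction row per compound. For RF models an `ad_threshold` can be
#' supplied and each query is flagged `IN`/`OUT`; MuDRA predictions are
#' `NOT_ASSESSED` (instance-based prediction carries its own neighborhood
#' evidence instead of a model domain). Compounds listed in `compound_ids`
#' but missing from the descriptor blocks produce `status = "error"` rows;
#' the batch continues.
#'
#' @param object an `oculotox_rf` or `mudra_reference`
#' @param blocks named list of `descriptor_block`s covering the queries
#' @param ad optional [fit_ad()] result (RF only)
#' @param compound_ids compounds to predict (default: every compound in the
#'   relevant blocks)
#' @return data.frame with `compound_id`, `predicted_label`, `confidence`,
#'   `in_ad`, `status`; MuDRA results carry the per-compound evidence in
#'   `attr(, "evidence")`
#' @export
predict_batch <- function(object, blocks, ad = NULL, compound_ids = NULL) {
  UseMethod("predict_batch")
}

#' @noRd
empty_predictions <- function() {
  data.frame(compound_id = character(0), predicted_label = character(0),
             confidence = numeric(0), in_ad = character(0),
             status = character(0), stringsAsFactors = FALSE)
}

#' @noRd
error_rows <- function(ids) {
  data.frame(compound_id = ids, predicted_label = NA_character_,
             confidence = NA_real_, in_ad = "NOT_ASSESSED",
             status = "error", stringsAsFactors = FALSE)
}

#' @export
predict_batch.oculotox_rf <- function(object, blocks, ad = NULL,
                                      compound_ids = NULL) {
  block <- blocks[[object$space]]
  if (is.null(block)) stop("blocks does not contain space ", object$space)
  if (is.null(compound_ids)) compound_ids <- block$compound_ids
  if (length(compound_ids) == 0L) return(empty_predictions())
  present <- compound_ids %in% block$compound_ids
  out <- error_rows(compound_ids)
  if (any(present)) {
    sub <- block_rows(block, compound_ids[present])
    p <- rf_predict(object, sub)
    p$in_ad <- "NOT_ASSESSED"
    if (!is.null(ad)) {
      q <- apply_feature_filter(sub, object$train_block)$matrix
      p$in_ad <- ifelse(in_domain(q, object$train_block, ad), "IN", "OUT")
    }
    p$status <- "ok"
    out[present, ] <- p[, colnames(out)]
  }
  rownames(out) <- NULL
  out
}

#' @export
predict_batch.mudra_reference <- function(object, blocks, ad = NULL,
                                          compound_ids = NULL) {
  spaces <- names(object$blocks)
  missing_space <- setdiff(spaces, names(blocks))
  if (length(missing_space))
    stop("blocks lack space(s): ", paste(missing_space, collapse = ", "))
  if (is.null(compound_ids)) {
    compound_ids <- Reduce(intersect, lapply(blocks[spaces],
                                             `[[`, "compound_ids"))
  }
  if (length(compound_ids) == 0L) return(empty_predictions())
  present <- Reduce(`&`, lapply(blocks[spaces], function(b)
    compound_ids %in% b$compound_ids))
  out <- error_rows(compound_ids)
  evidence <- stats::setNames(vector("list", length(compound_ids)),
                              compound_ids)
  if (any(present)) {
    ids_ok <- compound_ids[present]
    qmats <- lapply(spaces, function(sp)
      block_rows(blocks[[sp]], ids_ok)$matrix)
    names(qmats) <- spaces
    res <- mudra_predict_all(qmats, ids_ok, object)
    p <- res$predictions
    p$in_ad <- "NOT_ASSESSED"
    p$status <- "ok"
    out[present, ] <- p[, colnames(out)]
    evidence[ids_ok] <- res$evidence
  }
  rownames(out) <- NULL
  attr(out, "evidence") <- evidence
  out
}
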