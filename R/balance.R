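# Similarity-driven under-sampling. The minority (toxic) class is kept
# whole; the majority class is reduced to the same size by taking half of
# the quota as the negatives most similar to their nearest positive (the
# hard, boundary-defining examples) and the other half uniformly at random
# from the remainder (chemical-space coverage).

#' Run an expression with a temporary RNG state
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Tanimoto similarity of two bit vectors
#'
#' `|a AND b| / |a OR b|`, defined as 0 when both vectors are all-zero.
#'
#' @param a,b equal-length binary vectors
#' @return similarity in \[0, 1\]
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("bit vectors differ in length")
  a <- a != 0; b <- b != 0
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Tanimoto similarity matrix between two bit matrices
#' @noRd
tanimoto_matrix <- function(A, B) {
  A <- (A != 0) * 1; B <- (B != 0) * 1
  inter <- A %*% t(B)
  union <- outer(rowSums(A), rowSums(B), `+`) - inter
  s <- inter / union
  s[union == 0] <- 0
  s
}

#' Nearest-positive similarity for each negative compound
#'
#' For every negative, the maximum Tanimoto similarity to any positive —
#' the row maxima of the full negative-by-positive similarity matrix.
#'
#' @param neg_fps bit matrix (or BIT `descriptor_block`) of negatives
#' @param pos_fps bit matrix (or BIT `descriptor_block`) of positives
#' @return numeric vector of length `nrow(neg_fps)`
#' @export
nearest_positive_similarity <- function(neg_fps, pos_fps) {
  if (inherits(neg_fps, "descriptor_block")) neg_fps <- neg_fps$matrix
  if (inherits(pos_fps, "descriptor_block")) pos_fps <- pos_fps$matrix
  if (nrow(pos_fps) == 0L) stop("positive set is empty")
  if (ncol(neg_fps) != ncol(pos_fps)) stop("fingerprint lengths differ")
  s <- tanimoto_matrix(neg_fps, pos_fps)
  apply(s, 1L, max)
}

#' Balancing configuration
#'
#' Half of the negative quota (rounded up) is filled by similarity
#' selection, the remainder at random; the similarity space and the random
#' seed are configurable.
#'
#' @param fingerprint_space bit space used for the similarity matrix
#' @param rng_seed seed for the random-fill stage
#' @return object of class `balance_config`
#' @export
balance_config <- function(fingerprint_space = "MORGAN", rng_seed = 1L) {
  fingerprint_space <- match.arg(fingerprint_space, c("MORGAN", "KEYS166"))
  structure(list(similarity_fraction = 0.5,
                 fingerprint_space = fingerprint_space,
                 rng_seed = as.integer(rng_seed)),
            class = "balance_config")
}

#' Balance a binary dataset by similarity-plus-random under-sampling
#'
#' Keeps all `n_pos` positives and selects `n_pos` negatives:
#' `ceiling(n_pos / 2)` with the largest nearest-positive Tanimoto
#' similarity (ties broken by record id, so the selection is deterministic),
#' then `floor(n_pos / 2)` drawn uniformly at random (seeded) from the
#' remaining negatives.
#'
#' @param pos,neg `compound_records` tables for the two classes
#' @param cfg a [balance_config()]
#' @param blocks optional named list of precomputed BIT `descriptor_block`s
#'   covering all records (by `record_id`); fingerprints are computed from
#'   the SMILES when omitted
#' @return object of class `balanced_set` with elements `positives`,
#'   `negatives_similarity`, `negatives_random`, `similarity_scores` (max
#'   Tanimoto to any positive, for every selected negative) and `config`
#' @export
balance_dataset <- function(pos, neg, cfg = balance_config(), blocks = NULL) {
  n_pos <- nrow(pos); n_neg <- nrow(neg)
  if (n_pos < 1L) stop("positive set is empty")
  if (n_neg < n_pos)
    stop("cannot balance by under-sampling: fewer negatives (", n_neg,
         ") than positives (", n_pos, ")")
  sp <- cfg$fingerprint_space
  if (is.null(blocks)) {
    pos_fp <- compute_morgan_space(pos$smiles, sp)
    neg_fp <- compute_morgan_space(neg$smiles, sp)
  } else {
    b <- blocks[[sp]]
    if (is.null(b)) stop("blocks does not contain space ", sp)
    pos_fp <- b$matrix[match(pos$record_id, b$compound_ids), , drop = FALSE]
    neg_fp <- b$matrix[match(neg$record_id, b$compound_ids), , drop = FALSE]
    if (anyNA(pos_fp) || anyNA(neg_fp))
      stop("blocks do not cover every record")
  }

  score <- nearest_positive_similarity(neg_fp, pos_fp)
  n_sim <- as.integer(ceiling(n_pos / 2))
  n_rand <- n_pos - n_sim
  ord <- order(-score, neg$record_id)
  sim_idx <- ord[seq_len(n_sim)]
  rest <- setdiff(seq_len(n_neg), sim_idx)
  rand_idx <- if (n_rand > 0L) {
    with_seed(cfg$rng_seed, sort(sample(rest, n_rand)))
  } else integer(0)

  structure(list(
    positives = pos,
    negatives_similarity = neg[sim_idx, , drop = FALSE],
    negatives_random = neg[rand_idx, , drop = FALSE],
    similarity_scores = c(score[sim_idx], score[rand_idx]),
    config = cfg
  ), class = "balanced_set")
}

#' @noRd
compute_morgan_space <- function(smiles, space) {
  switch(space,
         MORGAN = compute_morgan(smiles),
         KEYS166 = compute_keys166(smiles))
}

#' @export
print.balanced_set <- function(x, ...) {
  cat(sprintf(paste0("<balanced_set> %d positives + %d negatives ",
                     "(%d similarity-selected, %d random)\n"),
              nrow(x$positives),
              nrow(x$negatives_similarity) + nrow(x$negatives_random),
              nrow(x$negatives_similarity), nrow(x$negatives_random)))
  invisible(x)
}

#' Flatten a balanced set into one record table
#'
#' @param x a `balanced_set`
#' @param ... unused
#' @return `compound_records` table with a `selection` column
#'   (`"positive"`, `"similarity"` or `"random"`)
#' @export
as.data.frame.balanced_set <- function(x, ...) {
  tag <- function(df, sel) {
    df <- as.data.frame(unclass(df), stringsAsFactors = FALSE)
    df$selection <- rep_len(sel, nrow(df))
    df
  }
  out <- rbind(
    tag(x$positives, "positive"),
    tag(x$negatives_similarity, "similarity"),
    tag(x$negatives_random, "random")
  )
  rownames(out) <- NULL
  out
}
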