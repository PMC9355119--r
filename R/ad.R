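# k-nearest-neighbor Euclidean applicability domain. A single distance
# threshold D_T = y_bar + Z * sigma is pooled over the training set, where
# y_bar and sigma are the mean and SD of each training compound's mean
# Euclidean distance to its k nearest (other) training compounds. A query
# is in-domain when its own mean k-nearest-training distance is <= D_T
# (boundary inclusive). Continuous features are z-scaled with training
# statistics before distances; bit features are used raw.

#' @noRd
ad_scale_params <- function(block) {
  if (block$kind == "BIT") {
    list(center = rep(0, ncol(block$matrix)),
         scale = rep(1, ncol(block$matrix)))
  } else {
    ctr <- colMeans(block$matrix)
    scl <- apply(block$matrix, 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    list(center = ctr, scale = scl)
  }
}

#' @noRd
ad_apply_scale <- function(m, scaling) {
  sweep(sweep(m, 2L, scaling$center, `-`), 2L, scaling$scale, `/`)
}

#' Mean distance to the k nearest rows of a reference matrix
#'
#' @param d distance matrix, queries in rows, reference in columns
#' @param k neighbor count
#' @noRd
mean_knn_dist <- function(d, k) {
  apply(d, 1L, function(row) mean(sort(row, partial = k)[seq_len(k)]))
}

#' Fit a k-nearest-neighbor Euclidean applicability domain
#'
#' For each training compound, the mean Euclidean distance to its `k`
#' nearest other training compounds is computed (self excluded); `y_bar` and
#' `sigma` are the mean and standard deviation of these per-compound values
#' pooled over the whole training set, and the threshold is
#' `D_T = y_bar + Z * sigma`.
#'
#' @param train_block training `descriptor_block` (bit or continuous)
#' @param k neighbor count, default 5
#' @param Z significance-control scalar, default 0.5
#' @return object of class `ad_threshold` with fields `k`, `Z`, `y_bar`,
#'   `sigma`, `D_T` and the feature scaling used
#' @export
fit_ad <- function(train_block, k = 5L, Z = 0.5) {
  n <- nrow(train_block$matrix)
  if (k >= n) stop("k (", k, ") must be smaller than the training size (",
                   n, ")")
  if (k < 1L) stop("k must be at least 1")
  scaling <- ad_scale_params(train_block)
  m <- ad_apply_scale(train_block$matrix, scaling)
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf # exclude self
  per_compound <- mean_knn_dist(d, k)
  y_bar <- mean(per_compound)
  sigma <- stats::sd(per_compound)
  if (!is.finite(sigma)) sigma <- 0
  structure(list(k = as.integer(k), Z = Z, y_bar = y_bar, sigma = sigma,
                 D_T = y_bar + Z * sigma, scaling = scaling,
                 space = train_block$space),
            class = "ad_threshold")
}

#' @export
print.ad_threshold <- function(x, ...) {
  cat(sprintf("<ad_threshold> %s space, k=%d, Z=%.2f: D_T = %.4f (ybar %.4f, sigma %.4f)\n",
              x$space, x$k, x$Z, x$D_T, x$y_bar, x$sigma))
  invisible(x)
}

#' Is a query inside the applicability domain?
#'
#' A query is in-domain when its mean Euclidean distance to its `k` nearest
#' training compounds is at most `D_T` (inclusive).
#'
#' @param query a feature vector, or a matrix/`descriptor_block` of queries
#' @param train_block the training `descriptor_block` the domain was fitted on
#' @param ad an `ad_threshold` from [fit_ad()]
#' @return logical vector, one value per query
#' @export
in_domain <- function(query, train_block, ad) {
  if (inherits(query, "descriptor_block")) query <- query$matrix
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  if (ncol(query) != ncol(train_block$matrix))
    stop("query dimension (", ncol(query), ") does not match training block (",
         ncol(train_block$matrix), ")")
  tm <- ad_apply_scale(train_block$matrix, ad$scaling)
  qm <- ad_apply_scale(query, ad$scaling)
  d <- euclidean_cross(qm, tm)
  mean_knn_dist(d, ad$k) <= ad$D_T
}

#' Cross Euclidean distances between the rows of two matrices
#' @noRd
euclidean_cross <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, `+`) - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Fraction of predictions inside the applicability domain
#'
#' @param predictions a prediction data.frame with an `in_ad` column
#'   (`"IN"`, `"OUT"`, `"NOT_ASSESSED"`) or a character vector of those
#'   values
#' @return coverage in \[0, 1\]
#' @export
ad_coverage <- function(predictions) {
  flags <- if (is.data.frame(predictions)) predictions$in_ad else predictions
  if (length(flags) == 0L) stop("no predictions to compute coverage over")
  if (any(flags == "NOT_ASSESSED"))
    stop("coverage requires every prediction to have an assessed domain")
  mean(flags == "IN")
}
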