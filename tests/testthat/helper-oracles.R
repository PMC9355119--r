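# Independent brute-force reference implementations used as oracles.
# Deliberately naive (double loops, direct formula transcription) and kept
# free of any package internals beyond plain matrices and vectors.

oracle_tanimoto <- function(a, b) {
  inter <- 0; union <- 0
  for (i in seq_along(a)) {
    ai <- a[i] != 0; bi <- b[i] != 0
    if (ai && bi) inter <- inter + 1
    if (ai || bi) union <- union + 1
  }
  if (union == 0) 0 else inter / union
}

oracle_nearest_positive <- function(neg, pos) {
  out <- numeric(nrow(neg))
  for (i in seq_len(nrow(neg))) {
    best <- 0
    for (j in seq_len(nrow(pos))) {
      s <- oracle_tanimoto(neg[i, ], pos[j, ])
      if (s > best) best <- s
    }
    out[i] <- best
  }
  out
}

oracle_euclid <- function(a, b) sqrt(sum((a - b)^2))

# kNN-AD threshold on an already-scaled matrix
oracle_ad_threshold <- function(m, k, Z) {
  n <- nrow(m)
  per <- numeric(n)
  for (i in seq_len(n)) {
    d <- numeric(0)
    for (j in seq_len(n)) {
      if (j != i) d <- c(d, oracle_euclid(m[i, ], m[j, ]))
    }
    per[i] <- mean(sort(d)[seq_len(k)])
  }
  list(y_bar = mean(per), sigma = sd(per),
       D_T = mean(per) + Z * sd(per))
}

oracle_mean_knn_dist <- function(q, m, k) {
  d <- apply(m, 1L, function(row) oracle_euclid(q, row))
  mean(sort(d)[seq_len(k)])
}

oracle_binary_metrics <- function(TP, TN, FP, FN) {
  div <- function(n, d) if (d == 0) NA_real_ else n / d
  se <- div(TP, TP + FN); sp <- div(TN, TN + FP)
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  list(Se = se, Sp = sp,
       CCR = if (is.na(se) || is.na(sp)) NA_real_ else (se + sp) / 2,
       PPV = div(TP, TP + FP), NPV = div(TN, TN + FN),
       F1 = div(2 * TP, 2 * TP + FP + FN),
       MCC = if (den == 0) NA_real_ else (TP * TN - FP * FN) / sqrt(den))
}

# MuDRA consensus by exhaustive evaluation of the full similarity tables.
# sims: list over spaces of query-by-training similarity matrices (one
# query row); labels: training labels; classes in tie-break order.
oracle_mudra_one <- function(sims, labels, classes, k) {
  per_space <- lapply(sims, function(s) {
    ord <- order(-s, seq_along(s))
    nn <- ord[seq_len(k)]
    votes <- sapply(classes, function(cl) sum(s[nn][labels[nn] == cl]))
    list(top = s[ord[1]], winner = classes[which.max(votes)],
         votes = votes)
  })
  tops <- sapply(per_space, `[[`, "top")
  best <- which.max(tops)
  list(label = per_space[[best]]$winner,
       confidence = max(per_space[[best]]$votes) /
         sum(per_space[[best]]$votes))
}

# random bit matrix helper for oracle comparisons
random_bits <- function(n, p, seed, density = 0.3) {
  set.seed(seed)
  matrix(rbinom(n * p, 1, density), nrow = n)
}

# reproduce the derived per-round fold seed used inside y_randomization
with_seed_probe <- function(seed, i) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  set.seed(seed)
  s <- sample.int(.Machine$integer.max %/% 2, i)[i]
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  s
}
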