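bit_block <- function(m, ids = sprintf("T%02d", seq_len(nrow(m))),
                      space = "MORGAN") {
  descriptor_block(m, space, "BIT",
                   feature_names = sprintf("b%03d", seq_len(ncol(m))),
                   compound_ids = ids)
}

test_that("classifier specs enforce the space arity of each algorithm", {
  expect_error(classifier_spec("RF", c("MORGAN", "KEYS166")), "exactly one")
  expect_error(classifier_spec("MUDRA", "MORGAN"), "at least two")
  expect_s3_class(classifier_spec("MUDRA", "MORGAN",
                                  allow_single_space = TRUE),
                  "classifier_spec")
  expect_s3_class(classifier_spec("RF", "MORGAN"), "classifier_spec")
})

test_that("RF separates planted-bit data and is seed-deterministic", {
  set.seed(50)
  n <- 60
  m <- matrix(rbinom(n * 40, 1, 0.3), n, 40)
  labels <- rep(c("POS", "NEG"), each = n / 2)
  m[labels == "POS", 1:3] <- 1 # fully informative planted bits
  m[labels == "NEG", 1:3] <- 0
  block <- bit_block(m, sprintf("C%02d", 1:n))
  spec <- classifier_spec("RF", "MORGAN", n_trees = 100, rng_seed = 9)
  model <- train_rf(block, labels, spec)
  p <- predict_batch(model, list(MORGAN = block))
  cc <- confusion_counts(labels, p$predicted_label)
  expect_equal(binary_metrics(cc)$CCR, 1)
  expect_true(all(p$confidence >= 0 & p$confidence <= 1))
  # same seed twice gives identical predictions
  model2 <- train_rf(block, labels, spec)
  p2 <- predict_batch(model2, list(MORGAN = block))
  expect_equal(p$predicted_label, p2$predicted_label)
  expect_equal(p$confidence, p2$confidence)
  expect_error(train_rf(block, rep("POS", n), spec), "single class")
})

test_that("MuDRA retrieves identical training compounds exactly", {
  train <- random_bits(6, 32, seed = 60)
  ref <- mudra_reference(
    list(MORGAN = bit_block(train),
         KEYS166 = bit_block(random_bits(6, 16, seed = 61),
                             space = "KEYS166")),
    labels = c("POS", "NEG", "POS", "NEG", "POS", "NEG"), k = 1)
  q <- list(MORGAN = train[2, ],
            KEYS166 = ref$blocks$KEYS166$matrix[2, ])
  p <- mudra_predict(q, ref)
  expect_equal(p$predicted_label, "NEG")
  expect_equal(p$confidence, 1)
  expect_equal(p$per_space_evidence$MORGAN$nn_id, "T02")
  expect_equal(p$in_ad, "NOT_ASSESSED")
  # single-compound reference with k = 1 returns its label for any query
  ref1 <- mudra_reference(
    list(MORGAN = bit_block(train[1, , drop = FALSE], "T01"),
         KEYS166 = bit_block(matrix(1, 1, 16), "T01", space = "KEYS166")),
    labels = "POS", k = 1)
  p1 <- mudra_predict(list(MORGAN = rbinom(32, 1, 0.5),
                           KEYS166 = rbinom(16, 1, 0.5)), ref1)
  expect_equal(p1$predicted_label, "POS")
})

test_that("MuDRA consensus equals the brute-force full-table oracle", {
  labels <- c("POS", "NEG", "POS", "NEG", "POS", "NEG")
  classes <- c("POS", "NEG") # hazard order
  s1 <- random_bits(6, 24, seed = 70)
  s2 <- random_bits(6, 12, seed = 71, density = 0.5)
  ref <- mudra_reference(
    list(MORGAN = bit_block(s1),
         KEYS166 = bit_block(s2, space = "KEYS166")),
    labels = labels, k = 3)
  for (qseed in 1:8) {
    set.seed(qseed + 500)
    q1 <- rbinom(24, 1, 0.3); q2 <- rbinom(12, 1, 0.5)
    p <- mudra_predict(list(MORGAN = q1, KEYS166 = q2), ref)
    sims <- list(
      sapply(1:6, function(j) oracle_tanimoto(q1, s1[j, ])),
      sapply(1:6, function(j) oracle_tanimoto(q2, s2[j, ]))
    )
    want <- oracle_mudra_one(sims, labels, classes, k = 3)
    expect_equal(p$predicted_label, want$label, label = paste("q", qseed))
    expect_equal(p$confidence, want$confidence, label = paste("q", qseed))
  }
})

test_that("agreement across spaces propagates and one space reduces to kNN", {
  # consistency: when every space's nearest neighbor has the same label,
  # the consensus equals that label
  labels <- c("POS", "POS", "NEG", "NEG")
  s1 <- rbind(c(1, 1, 1, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 0, 1))
  s2 <- rbind(c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  ref <- mudra_reference(
    list(MORGAN = bit_block(s1), KEYS166 = bit_block(s2, space = "KEYS166")),
    labels = labels, k = 1)
  p <- mudra_predict(list(MORGAN = c(1, 1, 1, 0), KEYS166 = c(1, 0)), ref)
  nn_labels <- vapply(p$per_space_evidence, function(e) {
    labels[match(e$nn_id, ref$ids)]
  }, character(1))
  expect_equal(length(unique(nn_labels)), 1L)
  expect_equal(p$predicted_label, unique(nn_labels))

  # single-space MuDRA is plain similarity-weighted kNN read-across
  ref1 <- mudra_reference(list(MORGAN = bit_block(s1)), labels, k = 3)
  q <- c(1, 1, 0, 1)
  p1 <- mudra_predict(list(MORGAN = q), ref1)
  sims <- sapply(1:4, function(j) oracle_tanimoto(q, s1[j, ]))
  nn <- order(-sims)[1:3]
  votes <- sapply(c("POS", "NEG"), function(cl)
    sum(sims[nn][labels[nn] == cl]))
  expect_equal(p1$predicted_label, names(which.max(votes)))
})

test_that("zero similarity everywhere yields a low-evidence call", {
  ref <- mudra_reference(
    list(MORGAN = bit_block(rbind(c(1, 1, 0, 0), c(1, 0, 1, 0))),
         KEYS166 = bit_block(rbind(c(1, 0), c(0, 1)), space = "KEYS166")),
    labels = c("POS", "NEG"), k = 2)
  p <- mudra_predict(list(MORGAN = c(0, 0, 1, 1) * 0, KEYS166 = c(0, 0)),
                     ref)
  expect_equal(p$confidence, 0)
  expect_true(p$low_evidence)
  expect_true(p$predicted_label %in% c("POS", "NEG"))
  # length mismatch is a hard error
  expect_error(mudra_predict(list(MORGAN = c(1, 0), KEYS166 = c(1, 0)),
                             ref), "length")
})

test_that("batch prediction honors the contract on edges and AD flags", {
  fx <- clean_fixture(n = 60, seed = 3)
  labels <- fx$records$label
  spec <- classifier_spec("RF", "MORGAN", n_trees = 100, rng_seed = 2)
  model <- train_rf(fx$blocks$MORGAN, labels, spec)
  # empty input
  expect_equal(nrow(predict_batch(model, fx$blocks,
                                  compound_ids = character(0))), 0L)
  # training batch with a huge Z: every prediction defined and in-domain
  ad <- fit_ad(model$train_block, k = 3, Z = 50)
  p <- predict_batch(model, fx$blocks, ad = ad)
  expect_equal(nrow(p), nrow(fx$records))
  expect_true(all(p$status == "ok"))
  expect_true(all(p$in_ad == "IN"))
  expect_true(all(p$confidence >= 0 & p$confidence <= 1))
  # a requested compound missing from the blocks becomes an error row
  p2 <- predict_batch(model, fx$blocks,
                      compound_ids = c(fx$records$record_id[1:3], "GHOST"))
  expect_equal(sum(p2$status == "error"), 1L)
  expect_equal(p2$compound_id[p2$status == "error"], "GHOST")
  expect_equal(sum(p2$status == "ok"), 3L)
})

test_that("model bundles round-trip with bit-identical predictions", {
  fx <- clean_fixture(n = 60, seed = 3)
  labels <- fx$records$label
  dir_rf <- file.path(tempdir(), "bundle_rf")
  dir_mu <- file.path(tempdir(), "bundle_mu")

  rf <- train_rf(fx$blocks$MORGAN, labels,
                 classifier_spec("RF", "MORGAN", n_trees = 100,
                                 rng_seed = 4))
  save_model_bundle(rf, dir_rf)
  rf2 <- load_model_bundle(dir_rf)
  expect_equal(predict_batch(rf2, fx$blocks), predict_batch(rf, fx$blocks))

  mu <- mudra_reference(fx$blocks, labels, k = 5)
  save_model_bundle(mu, dir_mu)
  mu2 <- load_model_bundle(dir_mu)
  p1 <- predict_batch(mu, fx$blocks)
  p2 <- predict_batch(mu2, fx$blocks)
  expect_equal(p1$predicted_label, p2$predicted_label)
  expect_equal(p1$confidence, p2$confidence)
  unlink(c(dir_rf, dir_mu), recursive = TRUE)
})
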