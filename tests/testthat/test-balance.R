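test_that("tanimoto matches hand-computed and oracle values", {
  expect_equal(tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(tanimoto(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(tanimoto(c(1, 1, 0), c(0, 0, 1)), 0)
  expect_equal(tanimoto(c(0, 0, 0), c(0, 0, 0)), 0) # both-empty convention
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length")
  # random vectors against the double-loop oracle
  for (seed in 1:5) {
    set.seed(seed)
    a <- rbinom(64, 1, 0.3); b <- rbinom(64, 1, 0.3)
    expect_equal(tanimoto(a, b), oracle_tanimoto(a, b))
  }
})

test_that("nearest-positive maxima equal the brute-force double loop", {
  neg <- random_bits(5, 32, seed = 101)
  pos <- random_bits(5, 32, seed = 202)
  expect_equal(nearest_positive_similarity(neg, pos),
               oracle_nearest_positive(neg, pos))
  # a negative identical to some positive scores exactly 1
  neg2 <- rbind(neg, pos[3, ])
  expect_equal(nearest_positive_similarity(neg2, pos)[6], 1)
  # single positive, single negative: the plain pairwise similarity
  expect_equal(nearest_positive_similarity(neg[1, , drop = FALSE],
                                           pos[1, , drop = FALSE]),
               tanimoto(neg[1, ], pos[1, ]))
  expect_error(nearest_positive_similarity(neg, pos[0, , drop = FALSE]),
               "empty")
})

make_balance_input <- function(n_pos, n_neg, seed = 1) {
  pos <- compound_records(rep("CCS(=O)(=O)O", n_pos), label = "POS",
                          record_id = sprintf("P%05d", seq_len(n_pos)))
  neg <- compound_records(rep("CCCC", n_neg), label = "NEG",
                          record_id = sprintf("N%05d", seq_len(n_neg)))
  fp <- random_bits(n_pos + n_neg, 64, seed = seed)
  block <- descriptor_block(fp, "MORGAN", "BIT",
                            feature_names = sprintf("b%02d", 1:64),
                            compound_ids = c(pos$record_id, neg$record_id))
  list(pos = pos, neg = neg, blocks = list(MORGAN = block))
}

test_that("balancing returns equal classes with the half-ceil split", {
  inp <- make_balance_input(9, 30)
  bal <- balance_dataset(inp$pos, inp$neg, balance_config(rng_seed = 3),
                         blocks = inp$blocks)
  expect_equal(nrow(bal$negatives_similarity), 5L) # ceil(9/2)
  expect_equal(nrow(bal$negatives_random), 4L)
  df <- as.data.frame(bal)
  expect_equal(nrow(df), 18L)
  expect_equal(sum(df$selection == "positive"), 9L)
  # the two negative sublists are disjoint
  expect_equal(length(intersect(bal$negatives_similarity$record_id,
                                bal$negatives_random$record_id)), 0L)
})

test_that("similarity stage picks the provably most similar negatives", {
  inp <- make_balance_input(6, 40, seed = 17)
  bal <- balance_dataset(inp$pos, inp$neg, balance_config(rng_seed = 1),
                         blocks = inp$blocks)
  b <- inp$blocks$MORGAN
  score <- nearest_positive_similarity(
    b$matrix[match(inp$neg$record_id, b$compound_ids), ],
    b$matrix[match(inp$pos$record_id, b$compound_ids), ])
  sel <- inp$neg$record_id %in% bal$negatives_similarity$record_id
  # minimum selected score >= maximum unselected score
  expect_gte(min(score[sel]), max(score[!sel]))
  # similarity scores reported for the similarity sublist are sorted
  k <- nrow(bal$negatives_similarity)
  expect_equal(bal$similarity_scores[seq_len(k)],
               sort(bal$similarity_scores[seq_len(k)], decreasing = TRUE))
})

test_that("balancing is seed-deterministic and degenerate cases behave", {
  inp <- make_balance_input(8, 25, seed = 4)
  b1 <- balance_dataset(inp$pos, inp$neg, balance_config(rng_seed = 7),
                        blocks = inp$blocks)
  b2 <- balance_dataset(inp$pos, inp$neg, balance_config(rng_seed = 7),
                        blocks = inp$blocks)
  expect_equal(as.data.frame(b1), as.data.frame(b2))
  b3 <- balance_dataset(inp$pos, inp$neg, balance_config(rng_seed = 8),
                        blocks = inp$blocks)
  # different seed changes only the random sublist
  expect_equal(b1$negatives_similarity$record_id,
               b3$negatives_similarity$record_id)
  # |pos| = 1 forces one similarity pick, no random picks
  inp1 <- make_balance_input(1, 10)
  bal1 <- balance_dataset(inp1$pos, inp1$neg, blocks = inp1$blocks)
  expect_equal(nrow(as.data.frame(bal1)), 2L)
  expect_equal(nrow(bal1$negatives_random), 0L)
  # cannot balance when negatives are scarcer than positives
  inp2 <- make_balance_input(10, 5)
  expect_error(balance_dataset(inp2$pos, inp2$neg, blocks = inp2$blocks),
               "under-sampling")
})

test_that("balancing computes fingerprints from SMILES when no blocks given", {
  fx <- generate_fixture(fixture_config(n_compounds = 30, noise_rate = 0,
                                        imbalance_ratio = 2, rng_seed = 21))
  pos <- fx[fx$label == "POS", ]
  neg <- fx[fx$label == "NEG", ]
  bal <- balance_dataset(pos, neg, balance_config(rng_seed = 2))
  expect_equal(nrow(as.data.frame(bal)), 2L * nrow(pos))
})
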