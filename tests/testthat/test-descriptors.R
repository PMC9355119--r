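test_that("fingerprint contracts: length, determinism, canonical equivalence", {
  m <- compute_morgan(c("CCO", "OCC", "c1ccccc1O"))
  expect_equal(ncol(m), 2048L)
  expect_true(all(m %in% c(0L, 1L)))
  # differently written ethanol gives identical bits
  expect_equal(unname(m[1, ]), unname(m[2, ]))
  expect_equal(tanimoto(m[1, ], m[2, ]), 1)
  # repeated computation is bit-identical
  expect_equal(compute_morgan("c1ccccc1O"), m[3, , drop = FALSE],
               ignore_attr = TRUE)

  k <- compute_keys166(c("C", "c1ccccc1", "C1CCCCC1"))
  expect_equal(ncol(k), 166L)
  # methane has no ring, so no key shared with the carbocycles' ring keys
  ring_keys <- which(k[2, ] == 1 & k[3, ] == 1)
  expect_true(all(k[1, ring_keys] == 0))
  # benzene and cyclohexane differ in aromaticity-sensitive keys
  expect_gt(sum(k[2, ] != k[3, ]), 0)
})

test_that("physicochemical descriptors are finite and match simple oracles", {
  p <- compute_physchem(c("CCO", "c1ccccc1"))
  expect_true(all(is.finite(p)))
  # ethanol molecular weight from atomic masses: 2C + 6H + O
  mw_ethanol <- 2 * 12.011 + 6 * 1.008 + 15.999
  expect_equal(p["CMP00001", "MW"], mw_ethanol, tolerance = 1e-3)
  expect_equal(p["CMP00002", "HeavyAtoms"], 6)
  expect_equal(p["CMP00002", "AromaticAtoms"], 6)
  # identical molecules give identical vectors
  p2 <- compute_physchem("OCC")
  expect_equal(unname(p2[1, ]), unname(p["CMP00001", ]))
})

test_that("featurize drops failing structures from all blocks and records them", {
  bl <- featurize(c("CCO", "notasmiles((", "CCN"), c("a", "b", "c"))
  expect_equal(attr(bl, "failed_ids"), "b")
  for (b in bl) expect_equal(b$compound_ids, c("a", "c"))
  expect_error(featurize("notasmiles((", on_error = "stop"), "failed")
})

test_that("feature filter removes invariant and correlated columns", {
  set.seed(42)
  n <- 200
  base <- rnorm(n)
  # planted structure: a constant, an exact duplicate, a pair at r ~ 0.95,
  # a pair at r ~ 0.85, and independent noise
  r95 <- 0.95 * scale(base) + sqrt(1 - 0.95^2) * scale(rnorm(n))
  r85 <- 0.85 * scale(base) + sqrt(1 - 0.85^2) * scale(rnorm(n))
  m <- cbind(base = base, const = rep(1, n), dup = base,
             r95 = as.numeric(r95), r85 = as.numeric(r85),
             noise = rnorm(n))
  # verify the planted correlations with a direct formula oracle
  r_oracle <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_gt(abs(r_oracle(m[, "base"], m[, "r95"])), 0.9)
  expect_lt(abs(r_oracle(m[, "base"], m[, "r85"])), 0.9)

  block <- descriptor_block(m, "PHYSCHEM", "CONTINUOUS")
  res <- filter_features(block, threshold = 0.9)
  expect_equal(res$report$removed_invariant, "const")
  expect_true("dup" %in% res$report$removed_correlated$removed)
  expect_true("r95" %in% res$report$removed_correlated$removed)
  expect_true("r85" %in% res$block$feature_names)
  expect_true("base" %in% res$block$feature_names)
  # every removed feature appears exactly once across the report
  removed <- c(res$report$removed_invariant,
               res$report$removed_correlated$removed)
  expect_equal(anyDuplicated(removed), 0L)
  expect_true(all(abs(res$report$removed_correlated$correlation) > 0.9))
})

test_that("filtering is a projection with a checkable postcondition", {
  set.seed(7)
  m <- matrix(rnorm(100 * 12), 100, 12)
  m[, 2] <- m[, 1] * 0.99 + rnorm(100, sd = 0.01) # near-duplicate
  m[, 5] <- 3                                      # invariant
  block <- descriptor_block(m, "PHYSCHEM", "CONTINUOUS")
  res <- filter_features(block, threshold = 0.9)
  cm <- abs(stats::cor(res$block$matrix))
  diag(cm) <- 0
  expect_lte(max(cm), 0.9)
  # applying the filter to its own output removes nothing
  res2 <- filter_features(res$block, threshold = 0.9)
  expect_equal(res2$block$feature_names, res$block$feature_names)
  expect_equal(length(res2$report$removed_invariant), 0L)
  expect_equal(nrow(res2$report$removed_correlated), 0L)
  # threshold validation
  expect_error(filter_features(block, threshold = 0), "threshold")
  expect_error(filter_features(block, threshold = 1.5), "threshold")
})

test_that("descriptor blocks round-trip through CSV + sidecar", {
  bl <- featurize(c("CCO", "CCN"), c("x1", "x2"), spaces = "PHYSCHEM")
  path <- file.path(tempdir(), "block_test.csv")
  write_block(bl$PHYSCHEM, path)
  back <- read_block(path)
  expect_equal(back$matrix, bl$PHYSCHEM$matrix)
  expect_equal(back$space, "PHYSCHEM")
  expect_equal(back$kind, "CONTINUOUS")
  unlink(c(path, paste0(path, ".json")))
})
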