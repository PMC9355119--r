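# Shared small fixtures, built once per test run.

# a clean planted-signal set for model tests (no curation artifacts)
clean_fixture <- local({
  cache <- NULL
  function(n = 120, seed = 11, noise = 0.1) {
    key <- paste(n, seed, noise)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$value)
    fx <- generate_fixture(fixture_config(
      n_compounds = n, noise_rate = noise, rng_seed = seed))
    bl <- featurize(fx$smiles, fx$record_id,
                    spaces = c("MORGAN", "KEYS166"))
    cache <<- list(key = key, value = list(records = fx, blocks = bl))
    cache$value
  }
})

# tiny record table for curation tests
make_records <- function(smiles, label = "POS", ...) {
  compound_records(smiles, label = label, ...)
}

expect_parse_error <- function(expr) {
  testthat::expect_error(expr, class = "oculotox_parse_error")
}
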