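# Shared fixtures, lazily built and cached for the whole test run.
ss_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = ss_cache)) assign(key, builder(), envir = ss_cache)
  get(key, envir = ss_cache)
}

standin_dict <- function() {
  cached("dict", function() load_dictionary(standin_dictionary_path()))
}

# strong-effect study: train 300 / test 150, the reference evaluation run
strong_study <- function() {
  cached("strong_study", function() {
    co <- generate_cohort(cohort_config(450, seed = 11, train_fraction = 2/3))
    run_screening_study(co, seed = 11)
  })
}

strong_cohort300 <- function() {
  cached("cohort300", function() {
    co <- generate_cohort(cohort_config(300, seed = 21))
    feats <- extract_cohort_features(co$transcripts, standin_dict())
    list(cohort = co, features = feats)
  })
}

small_study <- function() {
  cached("small_study", function() {
    co <- generate_cohort(cohort_config(100, seed = 5))
    run_screening_study(co, seed = 5)
  })
}

# deterministic random token streams for oracle suites
random_token_stream <- function(n, vocab_size = 40) {
  sample(paste0("w", seq_len(vocab_size)), n, replace = TRUE)
}

# a tiny dictionary written to disk and parsed, for io tests
tiny_dictionary_file <- function(lines) {
  path <- tempfile(fileext = ".dict")
  writeLines(lines, path)
  path
}
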