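# Shared, lazily built fixtures.  Training the decoder and quality models is
# the expensive step, so it happens once per test run and is reused.

vg_cache <- new.env(parent = emptyenv())

vg_fixture <- function(name, expr) {
  if (!exists(name, envir = vg_cache)) {
    assign(name, force(expr), envir = vg_cache)
  }
  get(name, envir = vg_cache)
}

# decoder + DUS quality classifier trained on a small simulated corpus
vg_models <- function() {
  vg_fixture("models", train_pipeline_models(n_train = 5, seed = 2, duration = 20))
}

# small noiseless cohort with ground truth
vg_clean_cohort <- function() {
  vg_fixture("clean_cohort", simulate_records(
    synth_params(n_records = 3, seed = 11, snr_db = Inf, duration = 30,
                 noise_sd_weeks = 0)
  ))
}

# one rendered noiseless record + its truth
vg_clean_record <- function() {
  co <- vg_clean_cohort()
  list(record = co$record[[1]], truth = co$truth[[1]])
}
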