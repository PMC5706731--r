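# Shared, memoized scenario batches so multiple test files can reuse the
# same simulated conditions (the expensive part of the suite).

.batch_cache <- new.env(parent = emptyenv())

get_batch <- function(name, seeds = 1:5) {
  key <- paste0(name, "_", paste(seeds, collapse = "-"))
  if (!exists(key, envir = .batch_cache)) {
    assign(key, run_scenario(name, seeds = seeds, quick = TRUE),
           envir = .batch_cache)
  }
  get(key, envir = .batch_cache)
}

batch_mean <- function(name, metric, seeds = 1:5) {
  scenario_mean(get_batch(name, seeds), metric)
}
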