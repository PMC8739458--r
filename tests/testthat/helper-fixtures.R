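# Shared fixture builders. Everything is generated in code at test time.

small_config <- function(seed = 42, n_batches = 3, samples_per_batch = 10,
                         ...) {
  generator_config(seed = seed, n_batches = n_batches,
                   samples_per_batch = samples_per_batch, ...)
}

# One flat rule set covering the default compound panel.
basic_ruleset <- function(compounds = default_compounds()$name,
                          name = "test", version = "1", ...) {
  ruleset(dplyr::bind_rows(lapply(compounds, function(cn)
    compound_cutoffs(cn, ...))), name = name, version = version)
}

# A loaded in-memory datastore plus its generator manifest.
loaded_store <- function(config) {
  gen <- generate_batches(config)
  con <- init_schema(":memory:")
  for (pb in gen$batches) load_batch(pb, con)
  list(con = con, gen = gen)
}

# Strip storage artefacts so stored rows compare against parser output.
drop_keys <- function(rows) {
  rows$result_key <- NULL
  rows
}
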