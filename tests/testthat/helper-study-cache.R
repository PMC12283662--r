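# Default-condition simulated studies are expensive to build; memoize the
# assembled feature table per generator seed for reuse across test blocks.
.study_cache <- new.env(parent = emptyenv())

default_study_table <- function(seed) {
  key <- as.character(seed)
  if (is.null(.study_cache[[key]])) {
    recs <- simulate_study(sim_config(seed = seed))
    .study_cache[[key]] <- assemble_features(recs, verbose = FALSE)
  }
  .study_cache[[key]]
}
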