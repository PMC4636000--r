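# Shared simulated worlds and pipeline runs, built once per test session.
.world_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.world_cache[[key]])) .world_cache[[key]] <- force(expr)
  .world_cache[[key]]
}

# the main benchmark world used across module tests
main_world <- function() {
  cached("world", simulate_world(n_families = 3, leaves_per_family = 8,
                                 seed = 101))
}

main_reads <- function() {
  cached("reads", simulate_reads(main_world(), read_length_nt = 300,
                                 divergence = 0.05, n_reads = 120,
                                 seed = 102))
}

main_run <- function() {
  cached("run", {
    w <- main_world(); rs <- main_reads()
    suppressMessages(run_pipeline(w$profiles, w$reference,
                                  list(meta1 = rs$reads), w$taxonomy,
                                  ref_taxa = w$ref_taxa))
  })
}
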