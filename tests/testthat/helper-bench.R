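# The desk-scale benchmark world: 3 marker families over 8 species,
# 500 reads at 5% divergence, plus read sets at the three divergence bins
# used for the accuracy-vs-similarity stratification.
bench_world <- function() {
  cached("bench_world", simulate_world(n_families = 3,
                                       leaves_per_family = 8, seed = 2024))
}

bench_reads <- function() {
  cached("bench_reads", simulate_reads(bench_world(), read_length_nt = 300,
                                       divergence = 0.05, n_reads = 500,
                                       seed = 2025))
}

bench_run <- function() {
  cached("bench_run", {
    w <- bench_world()
    suppressMessages(run_pipeline(w$profiles, w$reference,
                                  list(bench = bench_reads()$reads),
                                  w$taxonomy, ref_taxa = w$ref_taxa))
  })
}

# divergence-stratified read sets (bin midpoints 2.5%, 12.5%, 27.5%)
bench_bins <- function() {
  cached("bench_bins", {
    w <- bench_world()
    list(div05 = simulate_reads(w, 300, 0.025, n_reads = 150, seed = 31),
         div15 = simulate_reads(w, 300, 0.125, n_reads = 150, seed = 32),
         div30 = simulate_reads(w, 300, 0.275, n_reads = 150, seed = 33))
  })
}

bench_bins_run <- function() {
  cached("bench_bins_run", {
    w <- bench_world()
    bins <- bench_bins()
    suppressMessages(run_pipeline(
      w$profiles, w$reference,
      lapply(bins, `[[`, "reads"), w$taxonomy, ref_taxa = w$ref_taxa))
  })
}
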