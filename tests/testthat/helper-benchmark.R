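# The full self-consistency benchmark is expensive; run it once per test
# session and share the result across acceptance test blocks.
benchmark_cache <- new.env(parent = emptyenv())

full_benchmark <- function() {
  if (is.null(benchmark_cache$bm)) {
    benchmark_cache$bm <- run_benchmark(
      seed = 1, phantoms = c("water", "slab_lung", "tumor_slab"),
      preset = desk_preset())
  }
  benchmark_cache$bm
}
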