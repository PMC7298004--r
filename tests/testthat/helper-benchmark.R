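# The reference cohort experiment is expensive (~2 min), so it is run at
# most once per test session and shared by the tests that need it.

.bench_cache <- new.env(parent = emptyenv())

bench_fixture <- function() {
  if (is.null(.bench_cache$b))
    .bench_cache$b <- swarm_benchmark(seed = 1)
  .bench_cache$b
}
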