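# Shared fixtures. The synthetic benchmark network is expensive enough to
# build once and reuse across test files.

.bench_cache <- new.env(parent = emptyenv())

bench <- function() {
  if (is.null(.bench_cache$b)) {
    gen <- generate_network(synthetic_spec(N = 1000L, seed = 2L))
    mats <- build_transition_matrices(gen$network)
    .bench_cache$b <- list(
      net = gen$network, panel = gen$panel, mats = mats,
      erdos = erdos_set(mats, gen$panel$fixed_red, gen$panel)
    )
  }
  .bench_cache$b
}

# Small random directed network (no self-loops, no duplicates) for
# property-style loops.
random_net <- function(n, n_edges, seed) {
  set.seed(seed)
  pairs <- expand.grid(source = seq_len(n), target = seq_len(n))
  pairs <- pairs[pairs$source != pairs$target, ]
  pick <- pairs[sample.int(nrow(pairs), n_edges), ]
  nm <- paste0("v", seq_len(n))
  infi_network(data.frame(source = nm[pick$source], target = nm[pick$target]),
               node_names = nm, quiet = TRUE)
}

expect_prob_vector <- function(p) {
  expect_true(all(p >= 0))
  expect_lt(abs(sum(p) - 1), 1e-12)
}
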