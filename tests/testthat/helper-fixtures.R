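# Shared fixtures, built in code.

# a small benchmark for pipeline unit tests (kept far below the full study
# size so the unit suite stays fast; the acceptance tests run the full size)
small_spec <- function(n = 300L) {
  benchmark_spec(n_compounds = n)
}

small_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_benchmark(42L, small_spec())
    cache
  }
})

# tiny random nets for Jacobian / training property tests
random_small_net <- function(seed) {
  withr::with_seed(seed, {
    sizes <- c(sample(2:4, 1), sample(2:5, 1), sample(1:3, 1))
    acts <- sample(c("sigmoid", "tanh", "linear"), 2, replace = TRUE)
    list(net = lmnet(sizes, acts, seed = seed),
         X = matrix(stats::rnorm(4 * sizes[1]), 4, sizes[1]))
  })
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "lmscreen")
}
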