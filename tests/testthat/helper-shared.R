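# Shared, lazily computed fixtures so expensive objects (the canonical
# synthetic data set and the tuned cross-term random forest) are built once
# per test run and reused across files.

.shared <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.shared$sim)) .shared$sim <- simulate_pcm_data(seed = 1)
  .shared$sim
}

shared_fit <- function() {
  if (is.null(.shared$fit)) {
    sim <- shared_sim()
    .shared$fit <- suppressWarnings(
      pcm(sim$activities, sim$compounds, sim$variants,
          model = 3, learner = "random_forest", seed = 1))
  }
  .shared$fit
}

# A small deterministic descriptor matrix for filter/PCA tests.
toy_matrix <- function(n = 20, p = 6, seed = 99) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("d", seq_len(p))))
  m
}
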