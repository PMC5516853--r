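# Shared fixtures and independent oracles, built in code at test time.

# Small deterministic expression matrix with informative dimnames.
tiny_matrix <- function(n_genes = 4, n_samples = 5, seed = 42) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

# Random symmetric zero-diagonal weight matrix plus a random ternary state.
random_instance <- function(n, seed) {
  set.seed(seed)
  w <- matrix(runif(n * n, -1, 1), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  ids <- sprintf("g%02d", seq_len(n))
  dimnames(w) <- list(ids, ids)
  h <- sample(c(-1L, 0L, 1L), n, replace = TRUE)
  names(h) <- ids
  list(W = w, H = h)
}

# Independent energy oracle: explicit nested-loop double sum, no matrix
# algebra shared with the implementation.
brute_force_energy <- function(h, w) {
  n <- length(h)
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- acc + h[[i]] * w[[i, j]] * h[[j]]
    }
  }
  -acc / 2
}

# Small arc dataset for unit tests (cheaper than the default design).
small_arc <- function(seed = 7, noise_sd = 0.3, ...) {
  simulate_arc_dataset(arc_design(n_genes = 60, n_stages = 4,
                                  replicates_per_stage = 6,
                                  n_modules = 4, noise_sd = noise_sd,
                                  seed = seed, ...))
}

# Normalise + discretise an arc dataset; returns list(z, states, ann, sim).
arc_states <- function(sim, threshold = 0.5) {
  z <- zscore_normalize(sim$expression)
  list(z = z, states = discretize(z, threshold), ann = sim$annotation,
       sim = sim)
}
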