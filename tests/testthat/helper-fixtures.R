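# Small fixtures shared across test files; everything is generated in code.

toy_block <- function(n = 3, p = 4, modality = "FTMIR", seed = 42) {
  set.seed(seed)
  spectral_block(modality,
                 grid = seq(2000, 1000, length.out = p),
                 X = matrix(rnorm(n * p), n, p),
                 sample_ids = sprintf("S%02d", seq_len(n)),
                 labels = rep_len(1:2, n))
}

# two well-separated Gaussian classes in p dimensions
separable_classes <- function(n_per = 30, p = 10, delta = 3, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = delta / sqrt(p)), n_per, p))
  list(X = X, labels = rep(1:2, each = n_per))
}

# small paired blocks for pipeline-scale tests
small_blocks <- function(seed = 1, n_per_class = c(9, 9, 8, 9, 9)) {
  simulate_blocks(n_per_class,
                  grids = make_grids(ftmir_n = 160, nir_n = 210),
                  seed = seed)
}
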