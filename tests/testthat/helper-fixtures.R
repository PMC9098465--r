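# Shared fixtures: small synthetic configurations and random matrices.

# a fast, small field design: 12 lines x 2 locations x 2 reps = 48 plots
tiny_config <- function(seed = 1, ...) {
  defaults <- list(n_lines = 12L, years = c("Y1", "Y2"),
                   replicates_per_line = 2L, n_bins = 300L,
                   n_metabolites = 10L, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# a random standardized matrix (divisor-n convention) via the package's own
# standardizer on random data
random_standardized <- function(n, m, seed = 1) {
  set.seed(seed)
  sp <- spectra_matrix(sprintf("s%03d", seq_len(n)), seq_len(m),
                       matrix(rnorm(n * m), n, m))
  standardize_features(sp)
}

# manual divisor-n standardization, independent of the package path
manual_standardize <- function(X) {
  mu <- colMeans(X)
  sdp <- sqrt(colMeans(sweep(X, 2, mu)^2))
  sweep(sweep(X, 2, mu), 2, sdp, "/")
}
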