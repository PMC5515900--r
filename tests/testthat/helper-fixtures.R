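# Shared fixture builders. Everything is generated in code; nothing is
# stored on disk.

# Known low-rank + sparse composition for recovery tests.
make_pcp_problem <- function(seed, m = 110, n = 73, rank = 2,
                             sparse_frac = 0.05, magnitude = 1) {
  set.seed(seed)
  A <- matrix(rnorm(m * rank), m, rank)
  B <- matrix(rnorm(n * rank), n, rank)
  L0 <- A %*% t(B)
  S0 <- matrix(0, m, n)
  idx <- sample(m * n, round(sparse_frac * m * n))
  S0[idx] <- magnitude * sample(c(-1, 1), length(idx), replace = TRUE)
  list(X = L0 + S0, L0 = L0, S0 = S0)
}

# Small band-power array with controllable per-channel values.
make_band_power <- function(n_windows = 4, fill = NULL) {
  v <- array(if (is.null(fill)) runif(5 * 12 * n_windows) else fill,
             dim = c(5, 12, n_windows),
             dimnames = list(names(cd_bands), cd_channels, NULL))
  v
}

# Tiny two-day feature dataset for structural ADI tests.
tiny_dataset <- function(seed = 1, n_days = 2, trials_per_day = 6, ...) {
  generate_feature_dataset(synthetic_config(
    n_days = n_days, trials_per_day = trials_per_day, seed = seed, ...))
}
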