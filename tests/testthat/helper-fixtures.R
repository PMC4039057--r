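# Small deterministic fixtures built in code.

# A tiny epoched recording with given or random data.
tiny_recording <- function(C = 4, E = 10, T = 300, fs = 250,
                           pre_stim_ms = floor(0.2 * T) * 1000 / fs,
                           data = NULL, labels = NULL, seed = 1, ...) {
  if (is.null(data)) data <- with_test_seed(seed, array(rnorm(C * E * T), c(C, E, T)))
  if (is.null(labels))
    labels <- rep(c("standard", "deviant"), length.out = E)
  epoched_recording(data, fs = fs, pre_stim_ms = pre_stim_ms, labels = labels,
                    ...)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# Small, fast simulator configuration for unit tests.
quick_cfg <- function(...) {
  defaults <- list(n_asd = 2, n_td = 3, C = 12, n_periocular = 3,
                   epochs_per_block = 60, seed = 7)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Brute-force sample entropy: direct O(N^2) template counting.
sampen_oracle <- function(x, m, r) {
  n <- length(x) - m
  B <- 0; A <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (max(abs(x[i + 0:(m - 1)] - x[j + 0:(m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(NaN)
  -log(A / B)
}
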