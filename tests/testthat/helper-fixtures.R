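# Shared fixtures: everything is generated in code at test time.

fixture_recording <- function(n_s = 2, fs = 256, seed = 7, channels = canonical_channels()) {
  withr::with_seed(seed, {
    n <- n_s * fs
    data <- matrix(rnorm(length(channels) * n), nrow = length(channels))
    new_recording(data, fs, channels, subject_id = "fix01", label = 1L)
  })
}

# small but realistic synthetic cohort for unit tests
tiny_cohort_config <- function(seed = 11L, duration_s = 40, ...) {
  cohort_config(n_dyslexic = 3L, n_control = 3L, duration_s = duration_s,
                seed = seed, ...)
}

tiny_feature_matrix <- function(seed = 11L, mode = "frequency_consistent", ...) {
  cohort_feature_matrix(tiny_cohort_config(seed = seed, ...), mode = mode)
}

# label-free random feature matrix for selector/model tests
random_feature_matrix <- function(n = 60, p = 6, seed = 5, labels = NULL) {
  withr::with_seed(seed, {
    vals <- matrix(rnorm(n * p), n, p)
    colnames(vals) <- paste0("f", seq_len(p))
    if (is.null(labels)) labels <- rep(c(0L, 1L), length.out = n)
    structure(list(values = vals, feature_names = colnames(vals),
                   labels = labels,
                   subject_ids = paste0("s", seq_len(n))),
              class = "feature_matrix")
  })
}

# one-sided periodogram band power (independent spectral oracle)
oracle_band_power <- function(x, band, fs) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))[seq_len(n %/% 2)]^2 / n
  f <- (seq_len(n %/% 2) - 1) * fs / n
  sum(sp[f >= band[1] & f <= band[2]])
}
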