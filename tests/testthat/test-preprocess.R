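test_that("bandpass matches its analytic frequency response", {
  fs <- 256
  t <- seq_len(8 * fs) / fs
  gains <- bandpass_gain(c(50, 100), low = 0.1, high = 70, fs = fs)
  # amplitude at the probe frequency by projection (integer cycles), which is
  # orthogonal to the slow edge transient of the 0.1 Hz high-pass stage
  amp_at <- function(x, f0) 2 * Mod(sum(x * exp(-2i * pi * f0 * t))) / length(x)
  for (i in seq_along(c(50, 100))) {
    f0 <- c(50, 100)[i]
    rec <- new_recording(matrix(sin(2 * pi * f0 * t), 1), fs, "Fp1")
    out <- bandpass(rec, 0.1, 70)
    ratio <- amp_at(out$data[1, ], f0) / amp_at(rec$data[1, ], f0)
    expect_equal(ratio, gains[i], tolerance = 0.02)
  }
  # equivalent RMS statements: in band within 5%, far out of band below 10%
  expect_gt(gains[1], 0.95)
  expect_lt(gains[2], 0.10)
})

test_that("bandpass removes DC, preserves zero, and validates corners", {
  rec <- new_recording(matrix(7, 1, 1024), 256, "Fp1")   # pure DC
  expect_lt(max(abs(bandpass(rec)$data)), 0.5)
  z <- new_recording(matrix(0, 2, 1024), 256, c("Fp1", "Fp2"))
  expect_equal(bandpass(z)$data, z$data)
  expect_error(bandpass(rec, 0.1, 128), "Nyquist")
  expect_error(bandpass(rec, 50, 10), "low < high")
})

test_that("moving average matches a direct convolution oracle", {
  fs <- 256
  # constant in, constant out
  rec <- new_recording(matrix(3.5, 1, 100), fs, "Fp1")
  expect_equal(moving_average(rec)$data[1, ], rep(3.5, 100))
  # interior impulse spreads to nine samples of 1/9
  x <- rep(0, 101); x[51] <- 1
  out <- moving_average(new_recording(matrix(x, 1), fs, "Fp1"), 9L)$data[1, ]
  expect_equal(out[47:55], rep(1 / 9, 9))
  expect_equal(sum(out != 0), 9)
  # alternating +1/-1: direct centered convolution with reflection padding
  x2 <- rep(c(1, -1), length.out = 60)
  out2 <- moving_average(new_recording(matrix(x2, 1), fs, "Fp1"), 9L)$data[1, ]
  w2 <- 4L
  xp <- c(x2[w2:1], x2, x2[60:(60 - w2 + 1)])
  oracle <- vapply(seq_len(60), function(i) mean(xp[i:(i + 8L)]), numeric(1))
  expect_equal(out2, oracle)
  expect_equal(abs(out2[10:50]), rep(1 / 9, 41))
  expect_error(moving_average(rec, 8L), "odd")
  expect_error(moving_average(rec, -3L), "odd|positive")
})

test_that("filters commute with channel permutation and preserve shape/labels", {
  rec <- fixture_recording(n_s = 2)
  perm <- withr::with_seed(3, sample(16))
  permute <- function(r) new_recording(r$data[perm, ], r$fs,
                                       r$channel_names[perm],
                                       subject_id = r$subject_id,
                                       label = r$label)
  for (op in list(function(r) bandpass(r, 1, 40), moving_average)) {
    a <- op(permute(rec))
    b <- permute(op(rec))
    expect_equal(a$data, b$data)
    expect_identical(dim(a$data), dim(rec$data))
    expect_identical(a$label, rec$label)
  }
})

test_that("ica_clean is a no-op on artifact-free data and respects the cap", {
  cfg <- tiny_cohort_config(blink_rate = 0, emg_rate = 0)
  rec <- bandpass(generate_subject(cfg, 1, 1L), 0.5, 70)
  strict <- artifact_criteria(ocular_corr_threshold = 0.95,
                              emg_power_ratio_threshold = 0.95)
  res <- ica_clean(rec, strict, seed = 4L)
  expect_identical(attr(res$report, "status"), "ok")
  expect_equal(sum(res$report$removed), 0)
  expect_equal(res$recording$data, rec$data)

  capped <- artifact_criteria(ocular_corr_threshold = 0.05,
                              emg_power_ratio_threshold = 0.05,
                              max_components_removed = 0L)
  res2 <- ica_clean(rec, capped, seed = 4L)
  expect_equal(res2$recording$data, rec$data)        # exact pass-through
  expect_gt(sum(res2$report$flag != "none"), 0)      # candidates still listed
})

test_that("ica_clean removes blink components and lowers frontal low-frequency power", {
  cfg <- tiny_cohort_config(blink_rate = 30, blink_amplitude = 150,
                            emg_rate = 0, seed = 21L)
  rec <- bandpass(generate_subject(cfg, 1, 1L), 0.5, 70)
  res <- ica_clean(rec, artifact_criteria(), seed = 9L)
  rep <- res$report
  expect_gte(sum(rep$flag == "ocular" & rep$removed), 1)
  p_before <- oracle_band_power(rec$data["Fp1", ], c(0.5, 4), rec$fs) +
    oracle_band_power(rec$data["Fp2", ], c(0.5, 4), rec$fs)
  p_after <- oracle_band_power(res$recording$data["Fp1", ], c(0.5, 4), rec$fs) +
    oracle_band_power(res$recording$data["Fp2", ], c(0.5, 4), rec$fs)
  expect_lt(p_after, p_before)
})

test_that("ica decomposition satisfies the mixing identity", {
  rec <- bandpass(generate_subject(tiny_cohort_config(), 2, 0L), 0.5, 70)
  dec <- eegscreen:::fastica_decompose(rec$data, seed = 2L)
  expect_true(dec$converged)
  recon <- dec$A %*% dec$S + dec$means
  expect_lt(max(abs(recon - rec$data)) / max(abs(rec$data)), 1e-6)
})

test_that("artifact_criteria validates its fields", {
  expect_error(artifact_criteria(ocular_corr_threshold = 1.2))
  expect_error(artifact_criteria(ocular_lowfreq_band = c(4, 0.5)))
  expect_error(artifact_criteria(max_components_removed = -1L))
})
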