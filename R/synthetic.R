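# Deterministic synthetic task-evoked EEG cohort generator: the stand-in
# for a private clinical dataset. Each subject is a sum of band-limited
# oscillations (band-pass filtered Gaussian noise) with class-dependent
# amplitudes, 1/f background noise, frontal blink transients and posterior
# EMG bursts. Everything is a pure function of (config, seed).

#' Synthetic cohort configuration
#'
#' Band amplitudes are microvolt RMS scales of the per-band narrowband
#' oscillations. `band_effect_d` sets the standardized class effect on a
#' band's amplitude: dyslexic subjects' band amplitude is shifted by
#' `d * s_tot` multiplicative units, where `s_tot` is the total SD of the
#' per-epoch amplitude multiplier (`sqrt(epoch_cv^2 + subject_cv^2)`), so
#' the configured `d` is approximately the epoch-level Cohen's d realized
#' on amplitude-tracking features. Default effect directions follow the
#' elevated low-frequency (theta/delta) activity reported for dyslexic
#' readers; magnitudes are free simulation parameters.
#'
#' `subject_cv` adds idiosyncratic per-subject band-power variability.
#' It defaults to 0: any nonzero value makes epochs within a subject
#' correlated, which is useful for demonstrating subject leakage under
#' epoch-level cross-validation but makes epoch-level significance tests
#' anti-conservative.
#'
#' @param n_dyslexic,n_control Class sizes (default 26/25).
#' @param duration_s Recording length in seconds (340 s = 34 epochs).
#' @param fs Sampling rate in Hz.
#' @param band_amplitudes Named numeric vector of per-band uV RMS scales.
#' @param band_effect_d Named numeric vector of standardized class effects.
#' @param epoch_cv Coefficient of variation of the per-epoch amplitude
#'   multiplier.
#' @param subject_cv Idiosyncratic per-subject amplitude CV (see above).
#' @param pink_noise_scale 1/f background noise uV RMS.
#' @param blink_rate Blink events per minute on frontal channels.
#' @param blink_amplitude Blink peak amplitude in uV.
#' @param emg_rate EMG bursts per minute on posterior channels.
#' @param emg_amplitude EMG burst uV RMS.
#' @param epoch_length_s Epoch length used to modulate amplitudes.
#' @param seed Cohort seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_dyslexic = 26L, n_control = 25L,
                          duration_s = 340, fs = 256,
                          band_amplitudes = c(delta = 20, theta = 10,
                                              alpha = 10, beta = 5, gamma = 3),
                          band_effect_d = c(delta = 0.6, theta = 0.8,
                                            alpha = -0.3, beta = 0.2,
                                            gamma = 0),
                          epoch_cv = 0.2, subject_cv = 0,
                          pink_noise_scale = 5,
                          blink_rate = 10, blink_amplitude = 60,
                          emg_rate = 5, emg_amplitude = 20,
                          epoch_length_s = 10, seed = 1L) {
  stopifnot(n_dyslexic > 0L, n_control > 0L, fs > 0, duration_s > 0,
            blink_rate >= 0, emg_rate >= 0, epoch_cv >= 0, subject_cv >= 0,
            all(is.finite(band_effect_d)))
  defs <- band_definitions()
  stopifnot(all(names(band_amplitudes) %in% defs$band),
            all(names(band_effect_d) %in% defs$band))
  active <- names(band_amplitudes)[band_amplitudes > 0]
  bad <- defs$band[defs$band %in% active &
                     defs$high >= fs / 2]
  if (length(bad))
    stop("config error: band(s) above Nyquist at fs=", fs, ": ",
         paste(bad, collapse = ", "))
  structure(list(n_dyslexic = as.integer(n_dyslexic),
                 n_control = as.integer(n_control),
                 duration_s = duration_s, fs = fs,
                 band_amplitudes = band_amplitudes,
                 band_effect_d = band_effect_d,
                 epoch_cv = epoch_cv, subject_cv = subject_cv,
                 pink_noise_scale = pink_noise_scale,
                 blink_rate = blink_rate, blink_amplitude = blink_amplitude,
                 emg_rate = emg_rate, emg_amplitude = emg_amplitude,
                 epoch_length_s = epoch_length_s, seed = as.integer(seed)),
            class = "cohort_config")
}

# random-phase spectral synthesis: real signal with the given one-sided
# magnitude profile, normalised to unit RMS
spectral_noise_vec <- function(n, mag) {
  nf <- length(mag)                      # n %/% 2 positive-frequency bins
  ph <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = mag, argument = ph)
  full <- c(0 + 0i, spec, Conj(rev(spec[seq_len(nf - 1L)])))
  x <- Re(fft(full[seq_len(n)], inverse = TRUE)) / n
  r <- sqrt(mean(x^2))
  if (r == 0) x else x / r
}

# 1/f-power background noise, unit RMS
pink_noise_vec <- function(n, fs) {
  f <- seq_len(n %/% 2) * fs / n
  spectral_noise_vec(n, 1 / sqrt(pmax(f, 0.5)))
}

# band-limited Gaussian-like noise (ideal band-pass of white noise), unit RMS
narrowband_noise_vec <- function(n, fs, low, high) {
  f <- seq_len(n %/% 2) * fs / n
  spectral_noise_vec(n, as.numeric(f >= low & f <= high))
}

#' Generate one synthetic subject
#'
#' Fully determined by `(seed, subject_index)`; the class label selects
#' the band-amplitude shift.
#'
#' @param config A [cohort_config()].
#' @param subject_index Integer subject index (used in seeding).
#' @param class_label 1 (dyslexic) or 0 (non-dyslexic).
#' @param seed Cohort seed; defaults to `config$seed`.
#' @return An `eeg_recording` with the canonical 16 channels.
#' @export
generate_subject <- function(config, subject_index, class_label,
                             seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"), class_label %in% c(0L, 1L))
  chans <- canonical_channels()
  nc <- length(chans)
  n <- as.integer(round(config$duration_s * config$fs))
  fs <- config$fs
  spe <- as.integer(round(config$epoch_length_s * fs))
  n_ep <- ceiling(n / spe)
  defs <- band_definitions()
  s_tot <- sqrt(config$epoch_cv^2 + config$subject_cv^2)

  with_seed(derive_seed(seed, "subject", subject_index), {
    data <- matrix(0, nc, n)
    for (b in names(config$band_amplitudes)) {
      amp <- config$band_amplitudes[[b]]
      if (amp <= 0) next
      dd <- if (b %in% names(config$band_effect_d)) config$band_effect_d[[b]] else 0
      lohi <- defs[defs$band == b, ]
      subj_mult <- 1 + config$subject_cv * rnorm(1) +
        (if (class_label == 1L) dd * s_tot else 0)
      ep_mult <- pmax(subj_mult + config$epoch_cv * rnorm(n_ep), 0.05)
      gain <- rep(ep_mult, each = spe)[seq_len(n)]
      for (ch in seq_len(nc)) {
        nb <- narrowband_noise_vec(n, fs, lohi$low, lohi$high)
        data[ch, ] <- data[ch, ] + amp * gain * nb
      }
    }
    if (config$pink_noise_scale > 0) {
      for (ch in seq_len(nc))
        data[ch, ] <- data[ch, ] +
          config$pink_noise_scale * pink_noise_vec(n, fs)
    }
    if (config$blink_rate > 0 && config$blink_amplitude > 0) {
      w <- stats::setNames(rep(0.02, nc), chans)
      w[c("Fp1", "Fp2")] <- 1; w[c("F3", "F4", "F7", "F8")] <- 0.4
      w[c("C3", "C4")] <- 0.1
      n_blinks <- stats::rpois(1, config$blink_rate * config$duration_s / 60)
      if (n_blinks > 0) {
        centers <- sort(runif(n_blinks, 1, config$duration_s - 1))
        tgrid <- seq_len(n) / fs
        for (tc in centers) {
          a <- config$blink_amplitude * runif(1, 0.8, 1.2)
          sel <- which(abs(tgrid - tc) < 0.5)
          pulse <- a * exp(-0.5 * ((tgrid[sel] - tc) / 0.08)^2)
          data[, sel] <- data[, sel] + outer(unname(w), pulse)
        }
      }
    }
    if (config$emg_rate > 0 && config$emg_amplitude > 0) {
      w <- stats::setNames(rep(0.05, nc), chans)
      w[c("O1", "O2")] <- 1; w[c("T5", "T6")] <- 0.8; w[c("P3", "P4")] <- 0.6
      n_bursts <- stats::rpois(1, config$emg_rate * config$duration_s / 60)
      if (n_bursts > 0) {
        burst_len <- as.integer(0.5 * fs)
        env <- 0.5 * (1 - cos(2 * pi * seq_len(burst_len) / (burst_len + 1)))
        starts <- sort(sample.int(n - burst_len, n_bursts))
        hi <- min(70, fs / 2 - 1)
        for (s0 in starts) {
          noise <- narrowband_noise_vec(burst_len, fs, 30, hi) *
            config$emg_amplitude * env
          sel <- s0:(s0 + burst_len - 1L)
          data[, sel] <- data[, sel] + outer(unname(w), noise)
        }
      }
    }
    new_recording(data, fs, chans,
                  subject_id = sprintf("%s%02d",
                                       if (class_label == 1L) "dys" else "ctl",
                                       subject_index),
                  label = as.integer(class_label))
  })
}

cohort_labels <- function(config) {
  c(rep(1L, config$n_dyslexic), rep(0L, config$n_control))
}

#' Generate the full synthetic cohort
#'
#' @param config A [cohort_config()].
#' @return List with `recordings` (list of `eeg_recording`) and `manifest`
#'   (data frame: `subject_id`, `label`, `seed`).
#' @export
generate_cohort <- function(config) {
  labels <- cohort_labels(config)
  recs <- lapply(seq_along(labels), function(i)
    generate_subject(config, i, labels[i]))
  manifest <- data.frame(
    subject_id = vapply(recs, function(r) r$subject_id, ""),
    label = labels, seed = config$seed)
  list(recordings = recs, manifest = manifest)
}

#' Stream a synthetic cohort into a feature matrix
#'
#' Generates subjects one at a time, optionally preprocesses them
#' (band-pass, moving average, ICA artifact removal), epochs them, runs
#' the wavelet band decomposition and binds the per-epoch features. Memory
#' use stays at one recording regardless of cohort size.
#'
#' @param config A [cohort_config()].
#' @param bands Band set for the features.
#' @param mode Coefficient-to-band mapping, see [map_bands()].
#' @param preprocess Apply the preprocessing chain before epoching.
#' @param criteria [artifact_criteria()] used when `preprocess = TRUE`.
#' @param entropy_bins Histogram bins for the entropy descriptor.
#' @return A `feature_matrix` covering all subjects.
#' @export
cohort_feature_matrix <- function(config,
                                  bands = c("delta", "theta", "alpha", "beta"),
                                  mode = "table3_literal",
                                  preprocess = FALSE,
                                  criteria = artifact_criteria(),
                                  entropy_bins = 16L) {
  labels <- cohort_labels(config)
  parts <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    rec <- generate_subject(config, i, labels[i])
    if (preprocess) {
      rec <- bandpass(rec, 0.1, min(70, config$fs / 2 - 1))
      rec <- moving_average(rec)
      rec <- ica_clean(rec, criteria,
                       seed = derive_seed(config$seed, "ica", i))$recording
    }
    bc <- decompose_epochs(epoch_recording(rec, config$epoch_length_s),
                           bands = bands, mode = mode)
    parts[[i]] <- build_feature_matrix(bc, entropy_bins = entropy_bins)
  }
  structure(list(
    values = do.call(rbind, lapply(parts, `[[`, "values")),
    feature_names = parts[[1]]$feature_names,
    labels = unlist(lapply(parts, `[[`, "labels")),
    subject_ids = unlist(lapply(parts, `[[`, "subject_ids"))),
    class = "feature_matrix")
}
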