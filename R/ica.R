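# Seeded FastICA (fixed-point, logcosh negentropy) with automated
# ocular/EMG component rejection. Replaces the visual component screening
# used in clinical practice with thresholded, reproducible criteria.

#' Artifact rejection criteria
#'
#' Thresholds controlling automated ICA component rejection. A component is
#' flagged ocular when the absolute correlation between its time course and
#' a frontal low-frequency proxy (mean of Fp1/Fp2 band-passed to
#' `ocular_lowfreq_band`) exceeds `ocular_corr_threshold`. It is flagged
#' EMG when its spectral power share inside `emg_highfreq_band` exceeds
#' `emg_power_ratio_threshold` and its mixing-vector energy is
#' posterior-dominant (more than half on T5/T6/P3/P4/O1/O2).
#'
#' @param ocular_corr_threshold Correlation threshold in (0,1).
#' @param ocular_lowfreq_band Hz pair for the ocular proxy band.
#' @param emg_highfreq_band Hz pair for the EMG power band.
#' @param emg_power_ratio_threshold Power-share threshold (> 0).
#' @param max_components_removed Cap on removed components.
#' @return A list of class `artifact_criteria`.
#' @export
artifact_criteria <- function(ocular_corr_threshold = 0.7,
                              ocular_lowfreq_band = c(0.5, 4),
                              emg_highfreq_band = c(30, 70),
                              emg_power_ratio_threshold = 0.6,
                              max_components_removed = 4L) {
  stopifnot(ocular_corr_threshold > 0, ocular_corr_threshold < 1,
            emg_power_ratio_threshold > 0,
            max_components_removed >= 0L,
            length(ocular_lowfreq_band) == 2L,
            length(emg_highfreq_band) == 2L,
            ocular_lowfreq_band[1] < ocular_lowfreq_band[2],
            emg_highfreq_band[1] < emg_highfreq_band[2])
  structure(list(ocular_corr_threshold = ocular_corr_threshold,
                 ocular_lowfreq_band = ocular_lowfreq_band,
                 emg_highfreq_band = emg_highfreq_band,
                 emg_power_ratio_threshold = emg_power_ratio_threshold,
                 max_components_removed = as.integer(max_components_removed)),
            class = "artifact_criteria")
}

# Fixed-point (logcosh) ICA with deflation on a channels x samples matrix.
# Deflation extracts the most non-Gaussian directions one at a time; this
# matters here because EEG-like data can contain a near-Gaussian subspace
# in which the symmetric iteration has no stable fixed point. Components
# in that subspace are statistically interchangeable, so stalling there is
# completed with an arbitrary orthonormal basis (flagged per component).
# Returns list(S = sources, A = mixing, means, converged, comp_converged).
fastica_decompose <- function(X, seed, max_iter = 200L, tol = 1e-5) {
  nc <- nrow(X); ns <- ncol(X)
  means <- rowMeans(X)
  Xc <- X - means
  cv <- Xc %*% t(Xc) / ns
  eg <- eigen(cv, symmetric = TRUE)
  if (min(eg$values) < 1e-12 * max(eg$values))
    return(list(S = NULL, A = NULL, means = means, converged = FALSE,
                comp_converged = logical(0)))
  K <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)    # whitening
  Z <- K %*% Xc
  W <- matrix(0, nc, nc)
  comp_converged <- logical(nc)
  with_seed(seed, {
    for (i in seq_len(nc)) {
      w <- rnorm(nc)
      w <- w / sqrt(sum(w^2))
      for (it in seq_len(max_iter)) {
        wz <- drop(w %*% Z)
        g <- tanh(wz)
        w1 <- drop(Z %*% g) / ns - mean(1 - g^2) * w
        if (i > 1L) {                    # Gram-Schmidt against found rows
          prev <- W[seq_len(i - 1L), , drop = FALSE]
          w1 <- w1 - drop(t(prev) %*% (prev %*% w1))
        }
        nrm <- sqrt(sum(w1^2))
        if (nrm < 1e-12) break
        w1 <- w1 / nrm
        conv <- abs(abs(sum(w1 * w)) - 1) < tol
        w <- w1
        if (conv) { comp_converged[i] <- TRUE; break }
      }
      W[i, ] <- w
    }
  })
  unmix <- W %*% K                       # sources = unmix %*% Xc
  list(S = unmix %*% Xc, A = solve(unmix), means = means, converged = TRUE,
       comp_converged = comp_converged)
}

# fraction of periodogram power inside a band
band_power_fraction <- function(x, band, fs) {
  n <- length(x)
  sp <- Mod(fft(x - mean(x)))[seq_len(n %/% 2)]^2
  f <- (seq_len(n %/% 2) - 1) * fs / n
  tot <- sum(sp)
  if (tot == 0) return(0)
  sum(sp[f >= band[1] & f <= band[2]]) / tot
}

#' ICA-based ocular/EMG artifact removal
#'
#' Decomposes a (band-passed) recording into as many independent components
#' as channels using seeded fixed-point ICA, scores each component against
#' the ocular and EMG criteria in `criteria`, removes at most
#' `max_components_removed` flagged components (worst scores first), and
#' reconstructs the signal from the remaining components. If ICA fails to
#' converge the input is passed through unchanged with a warning and the
#' report status records the failure.
#'
#' @param rec An `eeg_recording` (16 canonical channels recommended).
#' @param criteria An [artifact_criteria()] object.
#' @param seed Integer seed for the ICA initialisation.
#' @return A list with elements `recording` (cleaned `eeg_recording`) and
#'   `report` (data frame of per-component scores and flags, plus a
#'   `status` attribute: `"ok"` or `"not_converged"`).
#' @export
ica_clean <- function(rec, criteria = artifact_criteria(), seed = 1L) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(criteria, "artifact_criteria"))
  nc <- nrow(rec$data)
  if (ncol(rec$data) < 20L * nc) stop("too few samples for ICA decomposition")
  dec <- fastica_decompose(rec$data, seed = seed)
  if (!dec$converged) {
    warning("ICA failed to converge; recording passed through unchanged")
    rep0 <- data.frame(component = integer(0), ocular_score = numeric(0),
                       emg_score = numeric(0), posterior_share = numeric(0),
                       flag = character(0), removed = logical(0))
    attr(rep0, "status") <- "not_converged"
    return(list(recording = rec, report = rep0))
  }
  S <- dec$S; A <- dec$A

  frontal <- which(rec$channel_names %in% c("Fp1", "Fp2"))
  posterior <- which(rec$channel_names %in% c("T5", "T6", "P3", "P4", "O1", "O2"))
  olb <- criteria$ocular_lowfreq_band
  proxy <- if (length(frontal)) {
    colMeans(rec$data[frontal, , drop = FALSE])
  } else rep(0, ncol(rec$data))
  if (stats::sd(proxy) > 0)
    proxy <- bandpass_vec(proxy, olb[1], min(olb[2], rec$fs / 2 - 1), rec$fs)

  ocular <- vapply(seq_len(nc), function(i) {
    if (stats::sd(S[i, ]) == 0 || stats::sd(proxy) == 0) return(0)
    abs(cor(S[i, ], proxy))
  }, numeric(1))
  emg <- vapply(seq_len(nc), function(i) {
    band_power_fraction(S[i, ], c(criteria$emg_highfreq_band[1],
                                  min(criteria$emg_highfreq_band[2], rec$fs / 2)),
                        rec$fs)
  }, numeric(1))
  post_share <- vapply(seq_len(nc), function(i) {
    tot <- sum(A[, i]^2)
    if (tot == 0) return(0)
    sum(A[posterior, i]^2) / tot
  }, numeric(1))

  is_ocular <- ocular > criteria$ocular_corr_threshold
  is_emg <- emg > criteria$emg_power_ratio_threshold & post_share > 0.5
  flag <- ifelse(is_ocular, "ocular", ifelse(is_emg, "emg", "none"))
  score <- pmax(ocular * is_ocular, emg * is_emg)
  cand <- which(flag != "none")
  cand <- cand[order(-score[cand], cand)]
  removed_idx <- head(cand, criteria$max_components_removed)

  report <- data.frame(component = seq_len(nc), ocular_score = ocular,
                       emg_score = emg, posterior_share = post_share,
                       flag = flag, removed = seq_len(nc) %in% removed_idx,
                       converged = dec$comp_converged)
  attr(report, "status") <- "ok"

  if (length(removed_idx) == 0L) {
    # reconstruct from all components: identity up to numerical error,
    # but return the input exactly to honour the no-op contract
    return(list(recording = rec, report = report))
  }
  keep <- setdiff(seq_len(nc), removed_idx)
  clean <- A[, keep, drop = FALSE] %*% S[keep, , drop = FALSE] + dec$means
  out <- new_recording(clean, rec$fs, rec$channel_names,
                       subject_id = rec$subject_id, label = rec$label)
  list(recording = out, report = report)
}
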