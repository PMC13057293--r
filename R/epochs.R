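#' Cut a recording into fixed-length non-overlapping epochs
#'
#' Segments the recording into consecutive, disjoint windows of
#' `epoch_length_s` seconds (default 10 s). A trailing remainder shorter
#' than one epoch is discarded. The subject label propagates to every
#' epoch.
#'
#' @param rec An `eeg_recording`.
#' @param epoch_length_s Epoch length in seconds.
#' @return An `eeg_epochs` object: list with `epochs` (epoch x channel x
#'   sample array), `subject_id`, `label`, `fs`, `channel_names`,
#'   `epoch_length_s`.
#' @export
epoch_recording <- function(rec, epoch_length_s = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  spe <- as.integer(round(epoch_length_s * rec$fs))
  n <- ncol(rec$data)
  if (n < spe)
    stop("recording too short: ", n / rec$fs, " s < one epoch of ",
         epoch_length_s, " s")
  k <- n %/% spe
  nc <- nrow(rec$data)
  ep <- array(0, dim = c(k, nc, spe))
  for (e in seq_len(k))
    ep[e, , ] <- rec$data[, ((e - 1L) * spe + 1L):(e * spe)]
  structure(list(subject_id = rec$subject_id, label = rec$label, fs = rec$fs,
                 channel_names = rec$channel_names, epochs = ep,
                 epoch_length_s = epoch_length_s),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<eeg_epochs> %s  label=%s  %d epochs x %d ch x %d samples (%g s @ %g Hz)\n",
              x$subject_id, ifelse(is.na(x$label), "NA", x$label),
              d[1], d[2], d[3], x$epoch_length_s, x$fs))
  invisible(x)
}

#' Wavelet band decomposition of an epoch set
#'
#' Runs [dwt_decompose()] and [map_bands()] on every epoch-channel signal
#' of an epoch set.
#'
#' @param epochs An `eeg_epochs` object.
#' @param bands Bands to retain (canonical order enforced).
#' @param mode Coefficient-to-band mapping mode, see [map_bands()].
#' @param wavelet,level Wavelet transform parameters.
#' @return A `band_coefficients` object: list with `coeffs` (per band, an
#'   epoch x channel x coefficient array), `subject_id`, `label`,
#'   `channel_names`, `mapping_mode`.
#' @export
decompose_epochs <- function(epochs, bands = c("delta", "theta", "alpha", "beta"),
                             mode = c("table3_literal", "frequency_consistent"),
                             wavelet = "db4", level = 6L) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  mode <- match.arg(mode)
  canon_bands <- band_definitions()$band
  bands <- canon_bands[canon_bands %in% bands]
  d <- dim(epochs$epochs)
  # resolve band -> coefficient sets once; the epoch loop only concatenates
  sets <- resolve_band_sets(mode, epochs$fs, level)[bands]
  first <- dwt_decompose(epochs$epochs[1, 1, ], wavelet, level)
  lens <- vapply(sets, function(s)
    sum(vapply(first[s], length, integer(1))), integer(1))
  coeffs <- lapply(lens, function(L) array(0, dim = c(d[1], d[2], L)))
  for (e in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      co <- dwt_decompose(epochs$epochs[e, ch, ], wavelet, level)
      for (b in bands)
        coeffs[[b]][e, ch, ] <- unlist(co[sets[[b]]], use.names = FALSE)
    }
  }
  structure(list(subject_id = epochs$subject_id, label = epochs$label,
                 channel_names = epochs$channel_names, coeffs = coeffs,
                 mapping_mode = mode),
            class = "band_coefficients")
}
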