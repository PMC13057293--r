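#' Canonical 16-channel montage
#'
#' The retained 10-20 channel set, in the fixed order used throughout the
#' package. Midline electrodes (Fz, Cz, Pz) are excluded.
#'
#' @return Character vector of 16 channel names.
#' @export
canonical_channels <- function() {
  c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "T3", "T4",
    "T5", "T6", "P3", "P4", "O1", "O2", "C3", "C4")
}

# Montage naming dialects: modern 10-10 names for the temporal row.
.channel_aliases <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")

normalize_channel_name <- function(x) {
  x <- gsub("\\s+", "", x)
  # strip common EDF label prefixes such as "EEG Fp1-A1A2"
  x <- sub("^EEG", "", x, ignore.case = TRUE)
  x <- sub("-.*$", "", x)
  canon <- canonical_channels()
  idx <- match(toupper(x), toupper(c(canon, names(.channel_aliases))))
  out <- c(canon, unname(.channel_aliases))[idx]
  ifelse(is.na(out), x, out)
}

#' Construct an EEG recording
#'
#' A recording holds one subject's multichannel EEG as a channels x samples
#' matrix of amplitudes in microvolts, together with the sampling rate,
#' channel names, and an optional binary class label (1 = dyslexic,
#' 0 = non-dyslexic).
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per data row.
#' @param subject_id Subject identifier string.
#' @param label Binary class label (0/1) or `NA`.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(data, fs, channel_names,
                          subject_id = "subject", label = NA_integer_) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1L)
  stopifnot(is.numeric(data), length(fs) == 1L, fs > 0)
  if (nrow(data) != length(channel_names))
    stop("data row count (", nrow(data), ") must equal number of channel names (",
         length(channel_names), ")")
  if (!is.na(label) && !label %in% c(0L, 1L))
    stop("label must be 0, 1 or NA")
  rownames(data) <- channel_names
  structure(
    list(subject_id = as.character(subject_id),
         label = if (is.na(label)) NA_integer_ else as.integer(label),
         fs = as.numeric(fs),
         channel_names = as.character(channel_names),
         data = data),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s  label=%s  %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, ifelse(is.na(x$label), "NA", x$label),
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

#' Restrict a recording to the canonical 16-channel set
#'
#' Matches channel names case-insensitively, ignoring whitespace and common
#' EDF label decorations, with aliases for the modern temporal-row names
#' (T7/T3, T8/T4, P7/T5, P8/T6). Midline (Fz, Cz, Pz) and any other extra
#' channels are dropped and the output rows follow the canonical order, so
#' downstream feature indices are reproducible.
#'
#' @param rec An `eeg_recording`.
#' @return An `eeg_recording` with exactly the 16 retained channels.
#' @export
select_channels <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  have <- normalize_channel_name(rec$channel_names)
  canon <- canonical_channels()
  idx <- match(canon, have)
  if (anyNA(idx))
    stop("missing required channel(s): ", paste(canon[is.na(idx)], collapse = ", "))
  new_recording(rec$data[idx, , drop = FALSE], rec$fs, canon,
                subject_id = rec$subject_id, label = rec$label)
}
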