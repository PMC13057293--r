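# Classic EDF (European Data Format) reader/writer. Continuous unannotated
# recordings only: one data record per second, 16-bit samples, physical
# dimension microvolts. EDF+ annotations and BDF are out of scope.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = "-")
}

# format a number into <= width ASCII chars such that as.numeric() round-trips
.edf_num <- function(x, width = 8L) {
  for (d in seq(7L, 1L)) {
    s <- formatC(x, format = "g", digits = d, width = -1)
    if (nchar(s) <= width) return(s)
  }
  stop("cannot format ", x, " into ", width, " characters")
}

#' Write a recording to an EDF file
#'
#' Writes classic EDF with one data record per second and a symmetric
#' per-channel physical range, so samples are quantized to 16 bits of the
#' recorded range. The subject id is stored in the patient-identification
#' field and the class label (when present) as `label=<0|1>` in the
#' recording-identification field, which [read_edf()] parses back.
#'
#' @param rec An `eeg_recording` with an integer sampling rate and a whole
#'   number of seconds of data.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!all(is.finite(rec$data))) stop("validation error: non-finite samples in data")
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(fs)
  ns <- nrow(rec$data)
  if (ncol(rec$data) %% fs != 0L)
    stop("EDF writer requires a whole number of seconds (got ",
         ncol(rec$data), " samples at ", fs, " Hz)")
  n_rec <- ncol(rec$data) %/% fs

  pmax <- vapply(seq_len(ns), function(i) {
    m <- max(abs(rec$data[i, ]))
    if (m == 0) m <- 1
    pm <- as.numeric(.edf_num(m))
    while (pm < m) pm <- as.numeric(.edf_num(pm * (1 + 1e-5)))
    pm
  }, numeric(1))
  dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(rec$subject_id, 80),
    .edf_pad(if (is.na(rec$label)) "" else paste0("label=", rec$label), 80),
    .edf_pad("01.01.26", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256L + ns * 256L, 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_pad("1", 8), .edf_pad(ns, 4))
  sig <- paste0(
    paste(vapply(rec$channel_names, .edf_pad, "", width = 16), collapse = ""),
    paste(rep(.edf_pad("", 80), ns), collapse = ""),
    paste(rep(.edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(-pmax, function(p) .edf_pad(.edf_num(p), 8), ""), collapse = ""),
    paste(vapply(pmax, function(p) .edf_pad(.edf_num(p), 8), ""), collapse = ""),
    paste(rep(.edf_pad(-dig_max, 8), ns), collapse = ""),
    paste(rep(.edf_pad(dig_max, 8), ns), collapse = ""),
    paste(rep(.edf_pad("", 80), ns), collapse = ""),
    paste(rep(.edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(.edf_pad("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)

  scale <- pmax / dig_max
  dig <- matrix(0L, nrow = ns, ncol = ncol(rec$data))
  for (i in seq_len(ns))
    dig[i, ] <- as.integer(round(rec$data[i, ] / scale[i]))
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Reads classic EDF, converting samples to physical units (microvolts).
#' All signals must share one sampling rate; files with per-channel rates
#' are rejected as unsupported.
#'
#' @param path Path to an EDF file.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    out <- readChar(con, n, useBytes = TRUE)
    if (length(out) == 0L || nchar(out, type = "bytes") < n)
      stop("corrupt EDF: truncated header in ", path)
    out
  }
  trim <- function(x) gsub("^\\s+|\\s+$", "", x)
  version <- trim(rd(8))
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  patient <- trim(rd(80))
  recording_field <- trim(rd(80))
  rd(8); rd(8)                                   # start date/time, unused
  header_bytes <- as.integer(trim(rd(8)))
  rd(44)
  n_rec <- as.integer(trim(rd(8)))
  rec_dur <- as.numeric(trim(rd(8)))
  ns <- as.integer(trim(rd(4)))
  if (is.na(ns) || ns < 1L) stop("corrupt EDF: no signals")
  if (is.na(header_bytes) || header_bytes != 256L + ns * 256L)
    stop("corrupt EDF: inconsistent header size")
  fld <- function(w) vapply(seq_len(ns), function(i) trim(rd(w)), "")
  labels <- fld(16); fld(80); fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  if (anyNA(c(pmin, pmax, dmin, dmax, spr)) || any(dmax <= dmin))
    stop("corrupt EDF: bad signal header fields")
  if (length(unique(spr)) != 1L)
    stop("unsupported EDF: per-channel sampling rates differ")
  fs <- spr[1] / rec_dur

  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2L,
                 endian = "little", signed = TRUE)
  if (length(raw) < n_rec * sum(spr))
    stop("corrupt EDF: data shorter than header declares")
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  arr <- array(raw, dim = c(spr[1], ns, n_rec))
  for (i in seq_len(ns)) {
    d <- as.vector(arr[, i, ])
    data[i, ] <- (d - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i]) + pmin[i]
  }
  label <- NA_integer_
  m <- regmatches(recording_field, regexec("label=([01])", recording_field))[[1]]
  if (length(m) == 2L) label <- as.integer(m[2])
  new_recording(data, fs, labels,
                subject_id = if (nzchar(patient)) patient else "subject",
                label = label)
}
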