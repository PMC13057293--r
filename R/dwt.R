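# Periodized multilevel DWT with the Daubechies-4 (four vanishing moments,
# 8-tap) wavelet. The periodized transform is exactly orthogonal, so
# reconstruction and Parseval energy conservation hold to machine
# precision at every level.

# db4 analysis low-pass filter (8 taps, orthonormal: sum h = sqrt(2))
.db4_lo <- c(0.230377813308855230, 0.714846570552541500,
             0.630880767929590400, -0.027983769416983850,
             -0.187034811718881140, 0.030841381835986965,
             0.032883011666982945, -0.010597401784997278)

wavelet_filters <- function(wavelet = "db4") {
  if (!identical(wavelet, "db4"))
    stop("only the db4 wavelet is supported")
  g <- .db4_lo
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1)     # quadrature mirror
  list(g = g, h = h, length = L)
}

#' Multilevel discrete wavelet decomposition
#'
#' Decomposes a signal with the periodized db4 DWT at the requested level,
#' returning the approximation set `A<level>` and detail sets
#' `D<level> ... D1`. The transform is orthogonal:
#' [dwt_reconstruct()] inverts it to machine precision and total
#' coefficient energy equals signal energy.
#'
#' @param x Numeric vector (one epoch of one channel).
#' @param wavelet Wavelet name; only `"db4"`.
#' @param level Decomposition depth (default 6).
#' @return Named list `A6, D6, D5, ..., D1` (for `level = 6`) of
#'   coefficient vectors, with attributes `level` and `n`.
#' @export
dwt_decompose <- function(x, wavelet = "db4", level = 6L) {
  flt <- wavelet_filters(wavelet)
  level <- as.integer(level)
  if (level < 1L) stop("level must be >= 1")
  if (length(x) < 2^level)
    stop("signal too short for a level-", level, " decomposition")
  if (!all(is.finite(x))) stop("non-finite values in signal")
  details <- vector("list", level)
  cur <- as.numeric(x)
  for (j in seq_len(level)) {
    if (length(cur) %% 2L == 1L) cur <- c(cur, cur[length(cur)])
    st <- cpp_dwt_step(cur, flt$g, flt$h)
    details[[j]] <- st$detail
    cur <- st$approx
  }
  out <- c(list(cur), rev(details))
  names(out) <- c(paste0("A", level), paste0("D", level:1))
  attr(out, "level") <- level
  attr(out, "n") <- length(x)
  out
}

#' Reconstruct a signal from its wavelet decomposition
#'
#' Inverts [dwt_decompose()]. Coefficient sets may be zeroed beforehand to
#' isolate sub-band contributions.
#'
#' @param coeffs Output of [dwt_decompose()].
#' @return Numeric vector of the original length.
#' @export
dwt_reconstruct <- function(coeffs) {
  flt <- wavelet_filters("db4")
  level <- attr(coeffs, "level")
  n <- attr(coeffs, "n")
  cur <- coeffs[[paste0("A", level)]]
  for (j in level:1) {
    cur <- cpp_idwt_step(cur, coeffs[[paste0("D", j)]], flt$g, flt$h)
  }
  cur[seq_len(n)]
}

band_definitions <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
             low = c(0.5, 4, 8, 13, 30),
             high = c(4, 8, 13, 30, 60),
             stringsAsFactors = FALSE)
}

# dyadic frequency interval of each level-6 coefficient set at rate fs
.coeff_intervals <- function(fs, level = 6L) {
  sets <- c(paste0("A", level), paste0("D", level:1))
  lows <- c(0, fs / 2^(level:1 + 1))
  highs <- c(fs / 2^(level + 1), fs / 2^(level:1))
  data.frame(set = sets, low = lows, high = highs, stringsAsFactors = FALSE)
}

#' Map wavelet coefficient sets to EEG frequency bands
#'
#' Two mappings are available. `"table3_literal"` follows the printed
#' level-to-band ladder (delta=A6, theta=D6, alpha=D5, beta=D4, gamma=D3),
#' which corresponds to a 512 Hz dyadic grid. `"frequency_consistent"`
#' assigns each band the coefficient set(s) whose dyadic interval at the
#' actual sampling rate best overlaps the band's nominal Hz range; at
#' 256 Hz this gives delta = A6+D6, theta = D5, alpha = D4, beta = D3,
#' gamma = D2.
#'
#' @param coeffs Output of [dwt_decompose()] at level 6.
#' @param mode `"table3_literal"` (default) or `"frequency_consistent"`.
#' @param fs Sampling rate in Hz (used by the frequency-consistent mode).
#' @param bands Character vector of bands to keep, in canonical order.
#' @return Named list of band coefficient vectors, attribute `mapping_mode`.
#' @export
map_bands <- function(coeffs, mode = c("table3_literal", "frequency_consistent"),
                      fs = 256,
                      bands = c("delta", "theta", "alpha", "beta")) {
  mode <- match.arg(mode)
  level <- attr(coeffs, "level")
  if (is.null(level) || level != 6L)
    stop("map_bands expects a level-6 decomposition")
  bands <- match.arg(bands, band_definitions()$band, several.ok = TRUE)
  assign_sets <- resolve_band_sets(mode, fs, level)
  out <- lapply(bands, function(b) {
    unlist(lapply(assign_sets[[b]], function(s) coeffs[[s]]), use.names = FALSE)
  })
  names(out) <- bands
  attr(out, "mapping_mode") <- mode
  out
}

# band -> coefficient-set names for a given mapping mode and sampling rate
resolve_band_sets <- function(mode, fs, level = 6L) {
  if (mode == "table3_literal")
    return(list(delta = "A6", theta = "D6", alpha = "D5", beta = "D4",
                gamma = "D3"))
  defs <- band_definitions()
  iv <- .coeff_intervals(fs, level)
  sel <- lapply(seq_len(nrow(defs)), function(i) {
    ov <- pmin(iv$high, defs$high[i]) - pmax(iv$low, defs$low[i])
    width <- iv$high - iv$low
    # keep every set mostly inside the band; else the single best overlap
    inside <- which(ov > 0.5 * width)
    if (length(inside) == 0L) inside <- which.max(ov)
    iv$set[inside]
  })
  names(sel) <- defs$band
  sel
}
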