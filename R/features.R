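# Ten statistical descriptors per band-channel coefficient vector, and
# assembly of the epochs x features matrix. All moments use population
# (1/N) normalisation; kurtosis is non-excess (Gaussian -> 3).

statistic_names <- function() {
  c("mean", "median", "variance", "std", "skewness", "kurtosis",
    "iqr", "mad", "rms", "entropy")
}

#' Ten statistical descriptors of a coefficient vector
#'
#' Computes, in fixed order: mean, median, population variance, population
#' standard deviation, skewness, non-excess kurtosis, interquartile range
#' (linear-interpolation quartiles), mean absolute deviation about the
#' mean, root-mean-square, and Shannon entropy (base 2) of the equal-width
#' histogram of the values over `entropy_bins` bins spanning
#' `[min(x), max(x)]`. Skewness and kurtosis are defined as 0 for
#' zero-variance input; a constant vector has zero entropy.
#'
#' @param x Non-empty finite numeric vector.
#' @param entropy_bins Number of histogram bins for the entropy estimate.
#' @return Named numeric vector of length 10.
#' @export
compute_statistics <- function(x, entropy_bins = 16L) {
  if (length(x) == 0L) stop("empty input vector")
  if (!all(is.finite(x))) stop("non-finite values in input")
  n <- length(x)
  m <- sum(x) / n
  v <- sum((x - m)^2) / n
  s <- sqrt(v)
  if (s > 0) {
    skew <- sum((x - m)^3) / n / s^3
    kurt <- sum((x - m)^4) / n / s^4
  } else {
    skew <- 0
    kurt <- 0
  }
  xs <- sort.int(x, method = "quick")
  # type-7 quantile (linear interpolation of order statistics) from one sort
  q7 <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, n)] - xs[lo])
  }
  med <- q7(0.5)
  q <- c(q7(0.25), q7(0.75))
  madv <- sum(abs(x - m)) / n
  rms <- sqrt(sum(x^2) / n)
  rng <- c(xs[1], xs[n])
  ent <- if (rng[1] == rng[2]) 0 else {
    cnt <- tabulate(pmin(pmax(
      findInterval(x, seq(rng[1], rng[2], length.out = entropy_bins + 1L),
                   rightmost.closed = TRUE), 1L), entropy_bins),
      nbins = entropy_bins)
    p <- cnt[cnt > 0] / n
    -sum(p * log2(p))
  }
  c(mean = m, median = med, variance = v, std = s, skewness = skew,
    kurtosis = kurt, iqr = q[2] - q[1], mad = madv, rms = rms, entropy = ent)
}

#' Assemble the epochs x features matrix
#'
#' Binds the ten descriptors of every band-channel coefficient vector into
#' one row per epoch, across one or more subjects. Column order is
#' bands (canonical: delta, theta, alpha, beta, gamma) x channels
#' (canonical montage order) x statistics (order of
#' [compute_statistics()]); names follow `band.channel.statistic`.
#'
#' @param band_list A `band_coefficients` object or a list of them (one per
#'   subject), all sharing band set and channel order.
#' @param entropy_bins Histogram bins for the entropy descriptor.
#' @return A `feature_matrix`: list with `values` (numeric matrix),
#'   `feature_names`, `labels`, `subject_ids`.
#' @export
build_feature_matrix <- function(band_list, entropy_bins = 16L) {
  if (inherits(band_list, "band_coefficients")) band_list <- list(band_list)
  stopifnot(length(band_list) > 0L,
            all(vapply(band_list, inherits, TRUE, "band_coefficients")))
  bands0 <- names(band_list[[1]]$coeffs)
  chans0 <- band_list[[1]]$channel_names
  for (bc in band_list) {
    if (!identical(names(bc$coeffs), bands0))
      stop("inconsistent band sets across subjects")
    if (!identical(bc$channel_names, chans0))
      stop("inconsistent channel order across subjects")
  }
  stats_nm <- statistic_names()
  feature_names <- as.vector(vapply(bands0, function(b)
    vapply(chans0, function(ch) paste(b, ch, stats_nm, sep = "."),
           character(length(stats_nm))),
    matrix("", length(stats_nm), length(chans0))))

  rows <- lapply(band_list, function(bc) {
    ne <- dim(bc$coeffs[[1]])[1]
    vals <- matrix(0, nrow = ne, ncol = length(feature_names))
    col <- 1L
    for (b in bands0) {
      arr <- bc$coeffs[[b]]
      for (ch in seq_along(chans0)) {
        for (e in seq_len(ne))
          vals[e, col:(col + 9L)] <-
            compute_statistics(arr[e, ch, ], entropy_bins)
        col <- col + 10L
      }
    }
    list(vals = vals,
         labels = rep(bc$label, ne),
         ids = rep(bc$subject_id, ne))
  })
  values <- do.call(rbind, lapply(rows, `[[`, "vals"))
  colnames(values) <- feature_names
  structure(list(values = values, feature_names = feature_names,
                 labels = unlist(lapply(rows, `[[`, "labels")),
                 subject_ids = unlist(lapply(rows, `[[`, "ids"))),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d epochs x %d features (%d subjects; labels: %s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$subject_ids)),
              paste(names(table(x$labels)), table(x$labels),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Subset the columns of a feature matrix
#'
#' @param fm A `feature_matrix`.
#' @param cols Integer indices or feature names.
#' @return A `feature_matrix` restricted to the requested features.
#' @export
subset_features <- function(fm, cols) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.character(cols)) cols <- match(cols, fm$feature_names)
  if (anyNA(cols)) stop("unknown feature name(s)")
  structure(list(values = fm$values[, cols, drop = FALSE],
                 feature_names = fm$feature_names[cols],
                 labels = fm$labels, subject_ids = fm$subject_ids),
            class = "feature_matrix")
}

#' Write / read a feature matrix as CSV
#'
#' The CSV carries one column per feature plus `label` and `subject_id`;
#' [read_feature_csv()] round-trips the object.
#'
#' @param fm A `feature_matrix`.
#' @param path CSV file path.
#' @return `write_feature_csv` returns `path` invisibly;
#'   `read_feature_csv` returns a `feature_matrix`.
#' @export
write_feature_csv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- as.data.frame(fm$values, check.names = FALSE)
  df$label <- fm$labels
  df$subject_id <- fm$subject_ids
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta <- c("label", "subject_id")
  stopifnot(all(meta %in% names(df)))
  vals <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  structure(list(values = vals, feature_names = colnames(vals),
                 labels = as.integer(df$label),
                 subject_ids = as.character(df$subject_id)),
            class = "feature_matrix")
}
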