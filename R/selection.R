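# Filter-based feature ranking: mRMR (greedy mutual-information difference)
# and ReliefF (k-nearest hits/misses), both implemented from scratch.

# equal-frequency discretization into at most n_bins bins. Features with
# few distinct values (e.g. binary) are used as categories directly; heavy
# ties collapse neighbouring bins.
discretize_ef <- function(x, n_bins = 10L) {
  ux <- sort(unique(x))
  if (length(ux) <= n_bins) return(match(x, ux))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1L), type = 7))
  interior <- br[-c(1L, length(br))]
  if (length(interior) == 0L) return(rep(1L, length(x)))
  findInterval(x, interior) + 1L
}

mi_from_table <- function(tab) {
  n <- sum(tab)
  pj <- tab / n
  px <- rowSums(pj)
  py <- colSums(pj)
  idx <- which(pj > 0, arr.ind = TRUE)
  sum(pj[idx] * log2(pj[idx] / (px[idx[, 1]] * py[idx[, 2]])))
}

#' Plug-in mutual information between a feature and labels
#'
#' Discretizes `x` into at most `n_bins` equal-frequency bins and computes
#' the empirical mutual information (base-2 log, `0 log 0 = 0`) between the
#' binned feature and the binary labels.
#'
#' @param x Numeric feature column.
#' @param y Binary labels (0/1), same length as `x`.
#' @param n_bins Discretization bins.
#' @return List with `value` (bits), `n_bins`, `n_samples`.
#' @export
estimate_mi <- function(x, y, n_bins = 10L) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (length(unique(y)) < 2L) stop("degenerate labels: y is constant")
  xb <- discretize_ef(x, n_bins)
  list(value = mi_from_table(table(xb, y)), n_bins = as.integer(n_bins),
       n_samples = length(x))
}

#' mRMR greedy feature ranking
#'
#' Greedy forward selection under the mutual-information-difference (MID)
#' criterion: the first feature maximizes relevance I(x; C); each further
#' feature maximizes I(x; C) minus the mean mutual information with the
#' already-selected set (or, with `scheme = "quotient"`, the ratio of the
#' two). Ties break towards the lower feature index.
#'
#' @param fm A `feature_matrix`.
#' @param k Number of features to rank.
#' @param n_bins Discretization bins for the MI estimates.
#' @param scheme `"difference"` (default) or `"quotient"`.
#' @return A `feature_ranking`: list with `method`, `order` (best first),
#'   `scores` (criterion value at selection), `names`, `params`.
#' @export
mrmr_rank <- function(fm, k, n_bins = 10L, scheme = c("difference", "quotient")) {
  stopifnot(inherits(fm, "feature_matrix"))
  scheme <- match.arg(scheme)
  p <- ncol(fm$values)
  if (k <= 0L) stop("k must be positive")
  if (k > p) stop("k exceeds feature count")
  if (min(table(fm$labels)) < 2L) stop("need >= 2 samples per class")
  disc <- apply(fm$values, 2L, discretize_ef, n_bins = n_bins)
  rel <- vapply(seq_len(p), function(j)
    mi_from_table(table(disc[, j], fm$labels)), numeric(1))
  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(p)                 # sum over selected of I(xi; xj)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(p), selected)
    crit <- if (step == 1L) rel[cand] else {
      red <- red_sum[cand] / length(selected)
      if (scheme == "difference") rel[cand] - red
      else rel[cand] / (red + 1e-12)
    }
    best <- cand[which.max(crit)]        # which.max -> lowest index on ties
    selected <- c(selected, best)
    scores <- c(scores, max(crit))
    if (step < k) {
      for (j in setdiff(seq_len(p), selected))
        red_sum[j] <- red_sum[j] + mi_from_table(table(disc[, j], disc[, best]))
    }
  }
  structure(list(method = "mrmr", order = selected, scores = scores,
                 names = fm$feature_names[selected],
                 params = list(n_bins = n_bins, scheme = scheme, k = k)),
            class = "feature_ranking")
}

#' ReliefF feature weighting
#'
#' Computes ReliefF weights on min-max scaled features with Manhattan
#' nearest-neighbour search. For each of `m` instances R, each feature's
#' weight decreases by the mean normalized difference to R's
#' `k_neighbors` nearest same-class hits and increases by the mean
#' difference to the nearest other-class misses (binary prior factor 1),
#' each contribution divided by `m`. With `m = "all"` (default) every
#' instance is visited once and the result is deterministic; an integer
#' `m < n` samples instances without replacement using `seed`.
#'
#' @param fm A `feature_matrix`.
#' @param k_neighbors Neighbours per class.
#' @param m `"all"` or number of sampled instances.
#' @param seed Seed for sampled mode.
#' @return A `feature_ranking` with weights in `[-1, 1]`, ordered by
#'   decreasing weight (ties towards lower index).
#' @export
relieff_weights <- function(fm, k_neighbors = 10L, m = "all", seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  y <- as.integer(fm$labels)
  if (any(table(y) <= k_neighbors))
    stop("each class needs more than k_neighbors samples")
  X <- fm$values
  rng <- apply(X, 2L, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1                   # constant feature: diffs are 0 anyway
  Xs <- sweep(sweep(X, 2L, rng[1, ]), 2L, span, "/")
  n <- nrow(Xs)
  idx <- if (identical(m, "all") || (is.numeric(m) && m >= n)) {
    seq_len(n) - 1L
  } else {
    with_seed(seed, sort(sample.int(n, m)) - 1L)
  }
  w <- cpp_relieff(Xs, y, as.integer(idx), as.integer(k_neighbors))
  ord <- order(-w, seq_along(w))
  structure(list(method = "relieff", order = ord, scores = w[ord],
                 names = fm$feature_names[ord],
                 params = list(k_neighbors = k_neighbors,
                               m = if (identical(m, "all")) "all" else m,
                               seed = seed),
                 weights = w),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> method=%s, %d features ranked\n",
              x$method, length(x$order)))
  k <- min(5L, length(x$order))
  for (i in seq_len(k))
    cat(sprintf("  %2d. %-28s %.4f\n", i, x$names[i], x$scores[i]))
  invisible(x)
}

#' Top-k cut of a feature ranking
#'
#' @param ranking A `feature_ranking`.
#' @param k Subset size (the study uses 10, 20 or 30).
#' @return List with `indices` and `names` of the k best features.
#' @export
select_top_k <- function(ranking, k) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (k <= 0L || k > length(ranking$order))
    stop("k must be in 1..", length(ranking$order))
  list(indices = ranking$order[seq_len(k)], names = ranking$names[seq_len(k)])
}

#' Serialize a ranking to CSV
#'
#' @param ranking A `feature_ranking`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ranking_csv <- function(ranking, path) {
  df <- data.frame(rank = seq_along(ranking$order),
                   feature_index = ranking$order,
                   feature_name = ranking$names,
                   score = ranking$scores,
                   method = ranking$method,
                   params = paste(names(ranking$params),
                                  unlist(lapply(ranking$params, paste,
                                                collapse = "/")),
                                  sep = "=", collapse = ";"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
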