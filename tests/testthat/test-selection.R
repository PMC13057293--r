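# independent oracles -------------------------------------------------------

oracle_mi_bits <- function(xb, y) {
  tab <- table(xb, y)
  n <- sum(tab)
  s <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    p <- tab[i, j] / n
    if (p > 0)
      s <- s + p * log2(p / ((sum(tab[i, ]) / n) * (sum(tab[, j]) / n)))
  }
  s
}

oracle_bin_ef <- function(x, n_bins = 10L) {
  ux <- sort(unique(x))
  if (length(ux) <= n_bins) return(match(x, ux))
  br <- unique(quantile(x, seq(0, 1, length.out = n_bins + 1L), type = 7))
  cuts <- br[-c(1L, length(br))]
  if (length(cuts) == 0L) return(rep(1L, length(x)))
  findInterval(x, cuts) + 1L
}

# exhaustive per-step greedy mRMR (difference scheme)
oracle_mrmr <- function(X, y, k, n_bins = 10L) {
  disc <- apply(X, 2L, oracle_bin_ef, n_bins = n_bins)
  p <- ncol(X)
  rel <- vapply(seq_len(p), function(j) oracle_mi_bits(disc[, j], y), 0)
  sel <- integer(0)
  for (step in seq_len(k)) {
    best <- -Inf; best_j <- NA_integer_
    for (j in setdiff(seq_len(p), sel)) {
      red <- if (length(sel) == 0) 0 else
        mean(vapply(sel, function(s) oracle_mi_bits(disc[, j], disc[, s]), 0))
      crit <- rel[j] - red
      if (crit > best + 1e-12) { best <- crit; best_j <- j }
    }
    sel <- c(sel, best_j)
  }
  sel
}

# naive full-pass ReliefF on range-scaled features
oracle_relieff <- function(X, y, k) {
  rng <- apply(X, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], .Machine$double.eps)
  span[rng[2, ] == rng[1, ]] <- 1
  Xs <- sweep(sweep(X, 2, rng[1, ]), 2, span, "/")
  n <- nrow(Xs); p <- ncol(Xs)
  w <- numeric(p)
  for (i in seq_len(n)) {
    d <- rowSums(abs(sweep(Xs, 2, Xs[i, ])))
    d[i] <- Inf
    hits <- which(y == y[i] & seq_len(n) != i)
    misses <- which(y != y[i])
    hits <- hits[order(d[hits], hits)][seq_len(k)]
    misses <- misses[order(d[misses], misses)][seq_len(k)]
    for (f in seq_len(p)) {
      w[f] <- w[f] - sum(abs(Xs[i, f] - Xs[hits, f])) / (n * k) +
        sum(abs(Xs[i, f] - Xs[misses, f])) / (n * k)
    }
  }
  w
}

# ---------------------------------------------------------------------------

test_that("mutual information matches hand evaluation of the plug-in formula", {
  y <- rep(c(0L, 1L), each = 50)
  expect_equal(estimate_mi(as.numeric(y), y)$value, 1.0)   # I(X;X) = H(X) = 1

  # joint counts [[30,10],[10,30]]
  x <- c(rep(0, 30), rep(1, 10), rep(0, 10), rep(1, 30))
  y2 <- rep(c(0L, 1L), each = 40)
  direct <- 2 * (0.375 * log2(0.375 / 0.25) + 0.125 * log2(0.125 / 0.25))
  expect_equal(estimate_mi(x, y2)$value, direct)
  expect_equal(oracle_mi_bits(x, y2), direct)

  withr::with_seed(1, {
    noise <- runif(4000)
    yb <- rep(c(0L, 1L), 2000)
    mi <- estimate_mi(noise, yb)
    expect_lt(mi$value, 0.01)                    # small-sample bias bound
    expect_gte(mi$value, 0)
  })
  expect_error(estimate_mi(1:10, rep(1L, 10)), "constant")
})

test_that("mRMR equals the exhaustive brute-force greedy oracle", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      n <- 40; p <- 6
      y <- rep(c(0L, 1L), each = n / 2)
      X <- matrix(rnorm(n * p), n, p)
      X[, 2] <- y + rnorm(n, sd = 0.5)           # informative
      X[, 5] <- X[, 2] + rnorm(n, sd = 0.3)      # redundant-ish
      fm <- random_feature_matrix(n, p)
      fm$values <- X
      fm$labels <- y
      rk <- mrmr_rank(fm, k = 3)
      expect_identical(rk$order, oracle_mrmr(X, y, 3))
    }
  })
})

test_that("mRMR prefers weakly-informative novel features over exact duplicates", {
  withr::with_seed(7, {
    n <- 200
    y <- rep(c(0L, 1L), each = n / 2)
    A <- as.numeric(xor(y, rbinom(n, 1, 0.05)))   # strong, near-label
    B <- as.numeric(xor(y, rbinom(n, 1, 0.30)))   # weaker, independent errors
    fm <- random_feature_matrix(n, 3)
    fm$values <- cbind(A = A, Adup = A, B = B)
    fm$feature_names <- colnames(fm$values)
    fm$labels <- y
    rk <- mrmr_rank(fm, k = 3)
    expect_identical(rk$order[1], 1L)             # k=1: max relevance, tie -> lower index
    # the duplicate is fully redundant (I(Adup; A) = H(A) >= I(Adup; C)),
    # so the weakly informative but novel B must rank ahead of it
    expect_identical(fm$feature_names[rk$order[2]], "B")
    expect_identical(rk$order, c(1L, 3L, 2L))
  })
  expect_error(mrmr_rank(random_feature_matrix(), k = 0), "positive")
  expect_error(mrmr_rank(random_feature_matrix(n = 20, p = 4), k = 9), "exceeds")
})

test_that("ReliefF equals the naive full-pass oracle", {
  withr::with_seed(8, {
    for (rep in 1:4) {
      n <- 30 + 10 * rep; p <- 5
      y <- rep(c(0L, 1L), length.out = n)
      X <- matrix(rnorm(n * p), n, p)
      X[, 1] <- X[, 1] + 1.2 * y
      fm <- random_feature_matrix(n, p)
      fm$values <- X
      fm$labels <- y
      rk <- relieff_weights(fm, k_neighbors = 5L)
      expect_equal(rk$weights, oracle_relieff(X, y, 5L), tolerance = 1e-12)
      expect_true(all(rk$weights >= -1 & rk$weights <= 1))
      expect_identical(rk$order, order(-rk$weights, seq_along(rk$weights)))
    }
  })
})

test_that("ReliefF hand-executable cases and invariances", {
  # perfectly separating feature on an 8-sample table
  y <- rep(c(0L, 1L), each = 4)
  withr::with_seed(3, {
    X <- cbind(sep = as.numeric(y), n1 = runif(8), n2 = runif(8),
               const = rep(2.5, 8))
  })
  fm <- random_feature_matrix(8, 4)
  fm$values <- X
  fm$feature_names <- colnames(X)
  fm$labels <- y
  rk <- relieff_weights(fm, k_neighbors = 2L)
  w <- rk$weights
  expect_identical(which.max(w), 1L)
  expect_gt(w[1], 0)
  # hand execution: all hit diffs 0, all miss diffs 1 -> weight exactly 1
  expect_equal(w[1], 1)
  expect_equal(w[4], 0)                           # constant feature

  # full-pass result invariant under permutation of sample order
  perm <- withr::with_seed(9, sample(8))
  fm2 <- fm
  fm2$values <- fm$values[perm, ]
  fm2$labels <- fm$labels[perm]
  expect_equal(relieff_weights(fm2, k_neighbors = 2L)$weights, w)

  expect_error(relieff_weights(fm, k_neighbors = 4L), "k_neighbors")
})

test_that("pure-noise features get ReliefF weight near zero in expectation", {
  ws <- vapply(1:8, function(s) {
    fm <- random_feature_matrix(n = 80, p = 3, seed = 100 + s)
    relieff_weights(fm, k_neighbors = 8L)$weights[2]
  }, numeric(1))
  expect_lt(abs(mean(ws)), 0.03)
})

test_that("select_top_k cuts prefixes and validates k", {
  fm <- tiny_feature_matrix()
  rk <- relieff_weights(fm, k_neighbors = 5L)
  top10 <- select_top_k(rk, 10L)
  top20 <- select_top_k(rk, 20L)
  top30 <- select_top_k(rk, 30L)
  expect_identical(top10$indices, top20$indices[1:10])
  expect_identical(top20$indices, top30$indices[1:20])
  expect_length(unique(top10$names), 10L)
  expect_identical(select_top_k(rk, length(rk$order))$indices, rk$order)
  expect_error(select_top_k(rk, 0L), "k must be")
  expect_error(select_top_k(rk, length(rk$order) + 1L), "k must be")
  # names resolve against the feature matrix
  expect_identical(top10$names, fm$feature_names[top10$indices])
})

test_that("rankings serialize to CSV", {
  fm <- random_feature_matrix(n = 40, p = 5)
  rk <- mrmr_rank(fm, k = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ranking_csv(rk, path)
  df <- read.csv(path)
  expect_identical(df$feature_index, rk$order)
  expect_identical(df$method[1], "mrmr")
})
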