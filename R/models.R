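# Classifier specifications: the proposed deep network (4 hidden blocks of
# fully-connected -> batch-norm -> ReLU -> dropout), the shallow variant
# (3 blocks), and classical baselines. The neural nets are trained with
# Nadam, batch size 16, learning rate 1e-3, up to 30 epochs with early
# stopping on a held-out validation split.

#' Classifier specification
#'
#' @param kind `"dnn"`, `"snn"`, or one of the classical baselines
#'   `"lda"`, `"qda"`, `"logistic"`, `"gaussian_nb"`, `"knn"`.
#' @param hidden_sizes Hidden-layer widths; defaults to 256-128-64-32 for
#'   the DNN and 128-64-32 for the SNN.
#' @param dropout Dropout rate in each hidden block.
#' @param batch_size,learning_rate,max_epochs Nadam training parameters.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement); 0 disables early stopping.
#' @param val_fraction Fraction of the training split held out for early
#'   stopping.
#' @param seed Integer seed controlling weight initialisation and batch
#'   shuffling.
#' @param params Extra parameters for classical models (e.g. `k` for kNN,
#'   `lambda` for ridge logistic regression).
#' @return A `model_spec` object.
#' @export
model_spec <- function(kind = "dnn", hidden_sizes = NULL, dropout = 0.5,
                       batch_size = 16L, learning_rate = 0.001,
                       max_epochs = 30L, patience = 5L, val_fraction = 0.1,
                       seed = 1L, params = list()) {
  kinds <- c("dnn", "snn", "lda", "qda", "logistic", "gaussian_nb", "knn")
  if (!kind %in% kinds)
    stop("unknown model kind '", kind, "'; expected one of: ",
         paste(kinds, collapse = ", "))
  if (is.null(hidden_sizes))
    hidden_sizes <- switch(kind, dnn = c(256L, 128L, 64L, 32L),
                           snn = c(128L, 64L, 32L), integer(0))
  if (kind == "dnn" && length(hidden_sizes) != 4L)
    stop("the deep network uses exactly 4 hidden blocks")
  if (kind == "snn" && length(hidden_sizes) != 3L)
    stop("the shallow network uses exactly 3 hidden blocks")
  stopifnot(dropout >= 0, dropout < 1, learning_rate > 0)
  structure(list(kind = kind, hidden_sizes = as.integer(hidden_sizes),
                 dropout = dropout, batch_size = as.integer(batch_size),
                 optimizer = "nadam", learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), val_fraction = val_fraction,
                 seed = as.integer(seed), params = params),
            class = "model_spec")
}

#' Instantiate a trainable classifier
#'
#' @param spec A [model_spec()].
#' @param input_dim Number of input features.
#' @return An `eeg_model` (untrained); fit with [fit_model()].
#' @export
build_model <- function(spec, input_dim) {
  stopifnot(inherits(spec, "model_spec"), input_dim >= 1L)
  structure(list(spec = spec, input_dim = as.integer(input_dim), fitted = NULL),
            class = "eeg_model")
}

#' Fit a classifier
#'
#' @param model An `eeg_model` from [build_model()].
#' @param X Numeric matrix (samples x features), `ncol(X) == input_dim`.
#' @param y Binary labels (0/1).
#' @return The fitted `eeg_model`.
#' @export
fit_model <- function(model, X, y) {
  stopifnot(inherits(model, "eeg_model"), ncol(X) == model$input_dim)
  y <- as.integer(y)
  spec <- model$spec
  model$fitted <- switch(
    spec$kind,
    dnn = ,
    snn = mlp_fit(X, y, spec),
    lda = fit_lda(X, y, qda = FALSE),
    qda = fit_lda(X, y, qda = TRUE),
    logistic = fit_ridge_logistic(X, y, spec$params),
    gaussian_nb = fit_gnb(X, y),
    knn = list(X = X, y = y,
               k = if (is.null(spec$params$k)) 10L else spec$params$k))
  model
}

#' Class-1 probabilities from a fitted classifier
#'
#' @param model A fitted `eeg_model`.
#' @param X Numeric matrix of samples to score.
#' @return Numeric vector of probabilities for the positive (dyslexic)
#'   class.
#' @export
predict_model <- function(model, X) {
  stopifnot(inherits(model, "eeg_model"))
  if (is.null(model$fitted)) stop("model has not been fitted")
  f <- model$fitted
  switch(model$spec$kind,
         dnn = ,
         snn = mlp_predict(f, X),
         lda = ,
         qda = {
           post <- predict(f$fit, X[, f$keep, drop = FALSE])$posterior
           if ("1" %in% colnames(post)) post[, "1"] else rep(0, nrow(X))
         },
         logistic = as.numeric(predict(f, X, type = "response",
                                       s = f$lambda_used)),
         gaussian_nb = gnb_predict(f, X),
         knn = knn_predict(f, X))
}

# ---- classical baselines (plumbing around standard estimators) ----------

fit_lda <- function(X, y, qda = FALSE) {
  keep <- which(apply(X, 2L, stats::sd) > 1e-10)
  if (length(keep) == 0L) stop("all features constant")
  # collinearity warnings are expected: several descriptors are functionally
  # related (std = sqrt(variance), rms^2 = variance + mean^2)
  fit <- if (qda) MASS::qda(X[, keep, drop = FALSE], grouping = factor(y))
  else suppressWarnings(MASS::lda(X[, keep, drop = FALSE], grouping = factor(y)))
  list(fit = fit, keep = keep)
}

fit_ridge_logistic <- function(X, y, params) {
  lambda <- if (is.null(params$lambda)) 1e-3 else params$lambda
  fit <- glmnet::glmnet(X, factor(y), family = "binomial", alpha = 0,
                        lambda = lambda, standardize = TRUE)
  fit$lambda_used <- lambda
  fit
}

fit_gnb <- function(X, y) {
  cls <- sort(unique(y))
  stats_by <- lapply(cls, function(c0) {
    Xi <- X[y == c0, , drop = FALSE]
    list(mu = colMeans(Xi), v = pmax(apply(Xi, 2L, var), 1e-9),
         logprior = log(nrow(Xi) / nrow(X)))
  })
  list(classes = cls, stats = stats_by)
}

gnb_predict <- function(f, X) {
  ll <- vapply(f$stats, function(s) {
    rowSums(-0.5 * (log(2 * pi * rep(s$v, each = nrow(X))) +
                      sweep(X, 2L, s$mu)^2 / rep(s$v, each = nrow(X)))) +
      s$logprior
  }, numeric(nrow(X)))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1L)
  p1 <- 1 / (1 + exp(ll[, 1] - ll[, 2]))
  if (!2 %in% seq_along(f$classes)) rep(0, nrow(X)) else p1
}

knn_predict <- function(f, X) {
  tr <- f$X
  k <- min(f$k, nrow(tr))
  # squared Euclidean distances via the expansion trick
  d2 <- outer(rowSums(X^2), rowSums(tr^2), "+") - 2 * X %*% t(tr)
  vapply(seq_len(nrow(X)), function(i) {
    nb <- order(d2[i, ], seq_len(ncol(d2)))[seq_len(k)]
    mean(f$y[nb])
  }, numeric(1))
}
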