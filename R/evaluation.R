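# Stratified 10-fold cross-validation protocol and the metric suite:
# accuracy, class-weighted precision/recall/F1, AUC, sensitivity,
# specificity, per-fold confusion counts, average and maximum aggregates.

#' Stratified fold assignment
#'
#' Shuffles indices within each class (seeded) and deals them round-robin,
#' so per-fold class proportions differ from the global proportions by at
#' most one sample.
#'
#' @param labels Binary labels.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..n_folds) per sample.
#' @export
stratified_folds <- function(labels, n_folds = 10L, seed = 1L) {
  if (any(table(labels) < n_folds))
    stop("each class needs at least n_folds samples")
  folds <- integer(length(labels))
  with_seed(seed, {
    for (c0 in unique(labels)) {
      idx <- sample(which(labels == c0))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Classification metrics from a confusion matrix
#'
#' Computes accuracy, sensitivity (recall of the positive/dyslexic class),
#' specificity, class-weighted precision/recall/F1, and, when per-sample
#' scores are supplied, the rank-statistic (Mann-Whitney) AUC. Metrics
#' whose denominator is empty (no positives or no negatives) are reported
#' as `NA` rather than 0.
#'
#' @param confusion Named list or vector with `TP`, `TN`, `FP`, `FN`
#'   (positive class = dyslexic = 1).
#' @param scores Optional class-1 scores for the evaluated samples.
#' @param labels True labels aligned with `scores`.
#' @return Named list of metrics (proportions in `[0, 1]`).
#' @export
compute_metrics <- function(confusion, scores = NULL, labels = NULL) {
  tp <- confusion[["TP"]]; tn <- confusion[["TN"]]
  fp <- confusion[["FP"]]; fn <- confusion[["FN"]]
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion matrix")
  np <- tp + fn; nn <- tn + fp
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- div(tp, np)
  spec <- div(tn, nn)
  prec1 <- div(tp, tp + fp)
  prec0 <- div(tn, tn + fn)
  w1 <- np / total; w0 <- nn / total
  wmean <- function(a, b) {
    if (w1 == 0) return(b)
    if (w0 == 0) return(a)
    if (is.na(a) || is.na(b)) return(NA_real_)
    w1 * a + w0 * b
  }
  precision <- wmean(prec1, prec0)
  recall <- wmean(sens, spec)           # equals accuracy when both defined
  f1c <- function(p, r) if (is.na(p) || is.na(r) || p + r == 0) NA_real_
  else 2 * p * r / (p + r)
  f1 <- wmean(f1c(prec1, sens), f1c(prec0, spec))
  auc <- NA_real_
  if (!is.null(scores) && !is.null(labels) && np > 0 && nn > 0) {
    r <- rank(scores)                    # mid-ranks handle ties -> 0.5 credit
    auc <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
  }
  list(accuracy = (tp + tn) / total, precision = precision, recall = recall,
       f1 = f1, auc = auc, sensitivity = sens, specificity = spec)
}

confusion_counts <- function(truth, predicted) {
  list(TP = sum(truth == 1 & predicted == 1),
       TN = sum(truth == 0 & predicted == 0),
       FP = sum(truth == 0 & predicted == 1),
       FN = sum(truth == 1 & predicted == 0))
}

#' Stratified k-fold cross-validation of one classifier
#'
#' Folds are stratified at epoch (segment) level; epochs of one subject
#' may therefore occur in both train and test folds, which matches the
#' protocol being emulated but can flatter generalization to unseen
#' subjects. `grouping = "subject"` switches to grouped folds (all epochs
#' of a subject share a fold) to expose that caveat.
#'
#' @param fm A `feature_matrix`.
#' @param spec A [model_spec()].
#' @param n_folds Number of folds (default 10).
#' @param seed Seed controlling fold assignment and per-fold model seeds.
#' @param grouping `"epoch"` (stratified, default) or `"subject"`.
#' @return An `eval_report`: list with `per_fold` (data frame),
#'   `aggregate` (`average` and `maximum` rows), `confusion` (per-fold
#'   counts), `config`.
#' @export
run_cv <- function(fm, spec, n_folds = 10L, seed = 1L,
                   grouping = c("epoch", "subject")) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(spec, "model_spec"))
  grouping <- match.arg(grouping)
  y <- as.integer(fm$labels)
  folds <- if (grouping == "epoch") {
    stratified_folds(y, n_folds, derive_seed(seed, "folds"))
  } else {
    subj <- unique(fm$subject_ids)
    slab <- y[match(subj, fm$subject_ids)]
    sf <- stratified_folds(slab, n_folds, derive_seed(seed, "folds"))
    sf[match(fm$subject_ids, subj)]
  }
  per_fold <- vector("list", n_folds)
  confusion <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L)
      stop("stratification error: training split of fold ", f,
           " contains a single class")
    sp <- spec
    sp$seed <- derive_seed(seed, "model", f)
    mdl <- build_model(sp, ncol(fm$values))
    mdl <- fit_model(mdl, fm$values[tr, , drop = FALSE], y[tr])
    prob <- predict_model(mdl, fm$values[!tr, , drop = FALSE])
    pred <- as.integer(prob > 0.5)
    cm <- confusion_counts(y[!tr], pred)
    confusion[[f]] <- cm
    per_fold[[f]] <- as.data.frame(compute_metrics(cm, prob, y[!tr]))
  }
  per_fold <- do.call(rbind, per_fold)
  per_fold$fold <- seq_len(n_folds)
  metric_cols <- setdiff(names(per_fold), "fold")
  aggregate <- rbind(
    average = vapply(per_fold[metric_cols], mean, numeric(1), na.rm = TRUE),
    maximum = vapply(per_fold[metric_cols], max, numeric(1), na.rm = TRUE))
  structure(list(per_fold = per_fold, aggregate = aggregate,
                 confusion = confusion,
                 config = list(spec = spec, n_folds = n_folds, seed = seed,
                               grouping = grouping,
                               n_features = ncol(fm$values))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, %d folds, %d features\n",
              x$config$spec$kind, x$config$n_folds, x$config$n_features))
  print(round(x$aggregate * c(rep(100, 4), 1, 100, 100)[col(x$aggregate)], 2))
  invisible(x)
}

band_feature_names <- function(fm, band) {
  fm$feature_names[startsWith(fm$feature_names, paste0(band, "."))]
}

#' Benchmark a grid of feature settings and models
#'
#' Evaluates each configuration (a feature setting plus a model spec)
#' under the cross-validation protocol and returns the reports with a tidy
#' summary table mirroring the study's result layout.
#'
#' @param fm The full `feature_matrix`.
#' @param configs List of configurations; each a list with `name`,
#'   `features` (`"combined"`, a band name, or a list
#'   `list(method = "mrmr"|"relieff", k = <int>)`), and `spec` (a
#'   [model_spec()]).
#' @param n_folds,seed Passed to [run_cv()].
#' @return List with `reports` (named list of `eval_report`s) and
#'   `summary` (data frame: one Average and one Maximum row per config).
#' @export
benchmark_suite <- function(fm, configs, n_folds = 10L, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  reports <- list()
  rows <- list()
  for (cfg in configs) {
    sub <- if (identical(cfg$features, "combined")) fm
    else if (is.character(cfg$features)) {
      nms <- band_feature_names(fm, cfg$features)
      if (length(nms) == 0L) stop("unknown feature setting: ", cfg$features)
      subset_features(fm, nms)
    } else {
      rk <- if (cfg$features$method == "mrmr") {
        mrmr_rank(fm, cfg$features$k)
      } else {
        relieff_weights(fm, seed = derive_seed(seed, "relieff"))
      }
      subset_features(fm, select_top_k(rk, cfg$features$k)$indices)
    }
    rep <- run_cv(sub, cfg$spec, n_folds = n_folds, seed = seed)
    reports[[cfg$name]] <- rep
    for (agg in c("average", "maximum")) {
      rows[[paste(cfg$name, agg)]] <- data.frame(
        setting = cfg$name, model = cfg$spec$kind, aggregate = agg,
        t(rep$aggregate[agg, ]))
    }
  }
  list(reports = reports, summary = do.call(rbind, c(rows, make.row.names = FALSE)))
}
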