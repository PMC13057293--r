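#' Per-feature effect sizes and FDR-corrected significance
#'
#' For every feature, compares the two classes with Welch's two-sample
#' t-test (two-sided), computes Cohen's d as the standardized mean
#' difference (dyslexic minus non-dyslexic) over the pooled population SD,
#' and adjusts p-values across all features with the Benjamini-Hochberg
#' step-up rule. Features with zero variance in both classes get d = 0 and
#' p = 1 and are flagged as degenerate.
#'
#' @param fm A `feature_matrix` with both classes present (>= 2 samples
#'   each).
#' @param alpha Significance level for the FDR-adjusted calls.
#' @return A `feature_stats` data frame: `feature`, `band`, `cohens_d`,
#'   `p_raw`, `p_fdr`, `significant`, `degenerate`; attribute
#'   `band_counts` holds per-band significant-feature counts.
#' @export
feature_group_stats <- function(fm, alpha = 0.05) {
  stopifnot(inherits(fm, "feature_matrix"))
  y <- as.integer(fm$labels)
  if (length(unique(y)) < 2L || any(table(y) < 2L))
    stop("both classes must be present with >= 2 samples each")
  i1 <- y == 1L; i0 <- y == 0L
  n1 <- sum(i1); n0 <- sum(i0)
  p <- ncol(fm$values)
  d <- numeric(p); praw <- numeric(p); degen <- logical(p)
  for (j in seq_len(p)) {
    x1 <- fm$values[i1, j]; x0 <- fm$values[i0, j]
    v1 <- stats::var(x1); v0 <- stats::var(x0)
    if (v1 < 1e-300 && v0 < 1e-300) {
      d[j] <- 0; praw[j] <- 1; degen[j] <- TRUE
      next
    }
    # pooled population SD, consistent with the 1/N feature normalisation
    sp <- sqrt((n1 * v1 * (n1 - 1) / n1 + n0 * v0 * (n0 - 1) / n0) / (n1 + n0))
    d[j] <- (mean(x1) - mean(x0)) / sp
    # Welch t statistic and Satterthwaite df
    se2 <- v1 / n1 + v0 / n0
    tstat <- (mean(x1) - mean(x0)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
    praw[j] <- 2 * pt(-abs(tstat), df)
  }
  pfdr <- p.adjust(praw, method = "BH")
  band <- sub("\\..*$", "", fm$feature_names)
  out <- data.frame(feature = fm$feature_names, band = band, cohens_d = d,
                    p_raw = praw, p_fdr = pfdr,
                    significant = pfdr < alpha, degenerate = degen,
                    stringsAsFactors = FALSE)
  attr(out, "band_counts") <- tapply(out$significant, out$band, sum)
  attr(out, "alpha") <- alpha
  class(out) <- c("feature_stats", "data.frame")
  out
}
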