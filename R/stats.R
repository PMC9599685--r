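#' Kolmogorov-Smirnov normality screen
#'
#' One-sample K-S statistic of the sample against a normal distribution
#' with the sample's own mean and standard deviation (Lilliefors-style
#' usage). The screen is reported only; downstream contrasts stay
#' nonparametric either way.
#'
#' @param x Numeric sample, `n >= 4`, non-constant.
#' @return List with `statistic`, `p_value`, `n`.
#' @export
ks_normality <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 4) stop("need at least 4 observations")
  if (stats::sd(x) == 0) stop("constant sample: normality test undefined")
  res <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       n = length(x))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Midranks for ties; exact two-sided p by enumeration when
#' `n_a + n_b <= 12` and the pooled sample is tie-free, otherwise the
#' normal approximation with tie and continuity corrections.
#'
#' @param a,b Numeric samples (non-empty).
#' @param exact Force exact (`TRUE`) or approximate (`FALSE`) mode;
#'   default `NULL` applies the rule above.
#' @return List with `statistic` (Mann-Whitney U of `a`), `p_value`,
#'   `n_a`, `n_b`, `exact`.
#' @export
wilcoxon_ranksum <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  if (is.null(exact)) exact <- (length(a) + length(b) <= 12) && !ties
  if (exact && ties) {
    warning("ties present; falling back to the normal approximation")
    exact <- FALSE
  }
  res <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                             correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       n_a = length(a), n_b = length(b), exact = exact)
}

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' The paired alternative to [wilcoxon_ranksum()] for within-subject
#' contrasts: signed ranks of the subject-wise differences, exact when
#' few tie-free non-zero differences exist, otherwise the normal
#' approximation with corrections.
#'
#' @param a,b Aligned numeric samples of equal length.
#' @return List with `statistic` (V), `p_value`, `n`.
#' @export
wilcoxon_signedrank <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (all(a == b)) return(list(statistic = 0, p_value = 1, n = length(a)))
  res <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                             correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       n = length(a))
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks; two-sided p-value from the
#' t-approximation with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, `n >= 4`, non-constant.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: rank correlation undefined")
  res <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = FALSE))
  list(rho = unname(res$estimate), p_value = res$p.value, n = length(x))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, returned in the input order.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
fdr_bh <- function(p) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Edgewise two-group comparison of connectivity matrices
#'
#' Wilcoxon rank-sum per upper-triangle edge across subjects, BH-FDR over
#' all edges, with the sign of the group-mean difference recorded.
#'
#' @param a,b Lists of symmetric matrices (one per subject), identical
#'   channel sets.
#' @param alpha Significance level applied to adjusted p-values.
#' @param paired Use the Wilcoxon signed-rank test on subject-wise
#'   differences instead of the unpaired rank-sum test (requires equal,
#'   aligned cohorts). Off by default: the emulated workflow compares
#'   conditions with the unpaired test even in within-subject designs.
#' @return Data frame (chan_a, chan_b, statistic, p_raw, p_adjusted,
#'   direction) with attribute `significant` (logical vector).
#' @export
edgewise_compare <- function(a, b, alpha = 0.05, paired = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 subjects per cohort")
  if (paired && length(a) != length(b))
    stop("paired comparison requires equally sized, aligned cohorts")
  labs <- rownames(a[[1]]) %||% as.character(seq_len(nrow(a[[1]])))
  n_ch <- nrow(a[[1]])
  pairs <- which(upper.tri(matrix(0, n_ch, n_ch)), arr.ind = TRUE)
  va <- vapply(a, function(m) m[pairs], numeric(nrow(pairs)))
  vb <- vapply(b, function(m) m[pairs], numeric(nrow(pairs)))
  stat <- p <- dir <- numeric(nrow(pairs))
  for (e in seq_len(nrow(pairs))) {
    res <- if (paired) wilcoxon_signedrank(va[e, ], vb[e, ])
           else wilcoxon_ranksum(va[e, ], vb[e, ])
    stat[e] <- res$statistic
    p[e] <- res$p_value
    dir[e] <- sign(mean(va[e, ]) - mean(vb[e, ]))
  }
  out <- data.frame(chan_a = labs[pairs[, 1]], chan_b = labs[pairs[, 2]],
                    statistic = stat, p_raw = p, p_adjusted = fdr_bh(p),
                    direction = dir)
  attr(out, "significant") <- out$p_adjusted < alpha
  out
}

#' Nodewise two-group comparison
#'
#' Wilcoxon rank-sum per node across subjects with BH-FDR over nodes.
#'
#' @param a,b Subjects x nodes numeric matrices.
#' @param alpha Significance level on adjusted p-values.
#' @param paired Use the signed-rank test on aligned cohorts.
#' @return Data frame (channel, statistic, p_raw, p_adjusted, direction)
#'   with attribute `significant`.
#' @export
nodewise_compare <- function(a, b, alpha = 0.05, paired = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("need at least 2 subjects per cohort")
  if (ncol(a) != ncol(b)) stop("cohorts have different node sets")
  if (paired && nrow(a) != nrow(b))
    stop("paired comparison requires equally sized, aligned cohorts")
  labs <- colnames(a) %||% as.character(seq_len(ncol(a)))
  stat <- p <- dir <- numeric(ncol(a))
  for (j in seq_len(ncol(a))) {
    res <- if (paired) wilcoxon_signedrank(a[, j], b[, j])
           else wilcoxon_ranksum(a[, j], b[, j])
    stat[j] <- res$statistic
    p[j] <- res$p_value
    dir[j] <- sign(mean(a[, j]) - mean(b[, j]))
  }
  out <- data.frame(channel = labs, statistic = stat, p_raw = p,
                    p_adjusted = fdr_bh(p), direction = dir)
  attr(out, "significant") <- out$p_adjusted < alpha
  out
}

#' Correlate per-subject features with shooting performance
#'
#' Spearman correlation of each feature column against the subjects' mean
#' ring scores, BH-FDR across the feature family.
#'
#' @param features Subjects x features matrix or data frame; row names (if
#'   present) are matched against `names(scores)`.
#' @param scores Named (or aligned) vector of mean scores per subject.
#' @param alpha Significance level on adjusted p-values.
#' @return Data frame (feature, rho, p_raw, p_adjusted, n) with attribute
#'   `significant`.
#' @export
correlate_with_performance <- function(features, scores, alpha = 0.05) {
  features <- as.matrix(features)
  if (nrow(features) != length(scores))
    stop("features and scores cover different numbers of subjects")
  if (!is.null(rownames(features)) && !is.null(names(scores))) {
    if (!setequal(rownames(features), names(scores)))
      stop("subject ids of features and scores do not match")
    scores <- scores[rownames(features)]
  }
  if (nrow(features) < 5) stop("need at least 5 subjects")
  labs <- colnames(features) %||% as.character(seq_len(ncol(features)))
  rho <- p <- numeric(ncol(features))
  for (j in seq_len(ncol(features))) {
    res <- spearman_cor(features[, j], scores)
    rho[j] <- res$rho
    p[j] <- res$p_value
  }
  out <- data.frame(feature = labs, rho = rho, p_raw = p,
                    p_adjusted = fdr_bh(p), n = nrow(features))
  attr(out, "significant") <- out$p_adjusted < alpha
  out
}
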