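#' Bootstrap test of a positive mean score
#'
#' Resamples the per-word scores with replacement (`n_boot` samples) to build
#' a bootstrap distribution of the mean, and returns the one-sided p-value
#' against the null hypothesis that the mean is zero: the proportion of
#' bootstrap means at or below zero, with a +1/(n+1) continuity correction so
#' that p is never exactly zero.
#'
#' @param per_word_scores numeric vector of per-word scores (e.g.
#'   correlations at one lag).
#' @param n_boot number of bootstrap samples.
#' @param seed integer seed.
#' @param one_sided if `FALSE`, a two-sided p-value is returned.
#' @return scalar p-value.
#' @export
bootstrap_mean_test <- function(per_word_scores, n_boot = 5000, seed = 1L,
                                one_sided = TRUE) {
  x <- per_word_scores[!is.na(per_word_scores)]
  if (length(x) < 2) stop("need >= 2 scores")
  if (stats::sd(x) == 0)
    message("all scores identical; degenerate bootstrap distribution")
  with_seed(seed, {
    bm <- vapply(seq_len(n_boot), function(i)
      mean(x[sample.int(length(x), replace = TRUE)]), numeric(1))
    p <- (1 + sum(bm <= 0)) / (n_boot + 1)
    if (!one_sided) p <- min(1, 2 * min(p, (1 + sum(bm >= 0)) / (n_boot + 1)))
    p
  })
}

#' Benjamini-Hochberg FDR control over lags
#'
#' Step-up procedure over the supplied p-values (one per lag; 321 by default
#' in the full analysis), flagging those significant at false-discovery-rate
#' level `q`.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param q FDR level.
#' @return logical vector of significance flags.
#' @export
fdr_bh <- function(pvals, q = 0.01) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Paired permutation test on per-word differences
#'
#' Sign-flip permutation: each per-word difference has its sign flipped with
#' probability 1/2 in every permutation, the mean difference forming the null
#' distribution. One-sided p = proportion of null means at or above the
#' observed mean, with +1/(n+1) continuity.
#'
#' @param diffs per-word differences (condition A minus condition B).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param one_sided one- (default) or two-sided.
#' @return scalar p-value.
#' @export
paired_permutation <- function(diffs, n_perm = 10000, seed = 1L,
                               one_sided = TRUE) {
  d <- diffs[!is.na(diffs)]
  if (length(d) < 2) stop("need >= 2 differences")
  obs <- mean(d)
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i)
      mean(d * sample(c(-1, 1), length(d), replace = TRUE)), numeric(1))
    p <- (1 + sum(null >= obs)) / (n_perm + 1)
    if (!one_sided)
      p <- min(1, 2 * min(p, (1 + sum(null <= obs)) / (n_perm + 1)))
    p
  })
}

#' Paired t-tests with Bonferroni correction across lags
#'
#' For each lag (column pair), a paired t-test on the per-word difference of
#' the two score sets, with the significance level Bonferroni-adjusted by the
#' lag count.
#'
#' @param a,b matrices (words x lags) or vectors of per-word scores under the
#'   two conditions, aligned by word.
#' @param alpha family-wise significance level.
#' @param alternative passed to [stats::t.test()].
#' @return a `significance_result`: data.frame with per-lag `p`,
#'   `p_bonferroni` and `significant`.
#' @export
paired_t_bonferroni <- function(a, b, alpha = 0.05,
                                alternative = "two.sided") {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("a and b must align by word and lag")
  n_lags <- ncol(a)
  p <- vapply(seq_len(n_lags), function(j) {
    d <- a[, j] - b[, j]
    d <- d[!is.na(d)]
    if (stats::sd(d) == 0) {
      if (mean(d) == 0) return(1)
      message("zero-variance nonzero differences; p -> 0 limit")
      return(0)
    }
    stats::t.test(a[, j], b[, j], paired = TRUE,
                  alternative = alternative)$p.value
  }, numeric(1))
  padj <- pmin(1, p * n_lags)
  structure(data.frame(lag = seq_len(n_lags), p = p, p_bonferroni = padj,
                       significant = padj <= alpha),
            class = c("significance_result", "data.frame"),
            procedure = "t", correction = sprintf("Bonferroni alpha=%g", alpha))
}

#' Per-lag bootstrap significance for an encoding result
#'
#' Applies [bootstrap_mean_test()] to the per-word correlations of one
#' variant at every lag, then [fdr_bh()] across lags.
#'
#' @param enc a `zs_encoding`.
#' @param variant which variant's scores to test.
#' @param n_boot bootstrap samples per lag.
#' @param q FDR level.
#' @param seed integer seed.
#' @return a `significance_result` data.frame: `lag_ms`, `p`, `significant`.
#' @export
encoding_significance <- function(enc, variant = "actual", n_boot = 5000,
                                  q = 0.01, seed = 1L) {
  sc <- enc$scores[enc$scores$variant == variant, ]
  lags <- sort(unique(sc$lag_ms))
  p <- vapply(seq_along(lags), function(i)
    bootstrap_mean_test(sc$r[sc$lag_ms == lags[i]], n_boot = n_boot,
                        seed = seed + i), numeric(1))
  structure(data.frame(lag_ms = lags, p = p, significant = fdr_bh(p, q)),
            class = c("significance_result", "data.frame"),
            procedure = "bootstrap", correction = sprintf("FDR q=%g", q),
            n_resamples = n_boot, seed = seed)
}
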