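#' Fit an ordinary-least-squares map from embeddings to electrode patterns
#'
#' One multivariate OLS fit with intercept: each electrode's activity is
#' regressed on the embedding dimensions over the training words. Exactly the
#' normal-equations solution; a rank-deficient design is an error.
#'
#' @param train_X numeric matrix, training words x embedding dims.
#' @param train_Y numeric matrix, training words x electrodes.
#' @return a `linear_map`: list with `weights` ((dim+1) x electrodes, first
#'   row the intercept).
#' @export
fit_ols <- function(train_X, train_Y) {
  train_X <- as.matrix(unclass(train_X)); train_Y <- as.matrix(train_Y)
  if (nrow(train_X) != nrow(train_Y)) stop("X and Y rows must align")
  if (nrow(train_X) <= ncol(train_X) + 1)
    stop("need more training rows than embedding dims + 1")
  D <- cbind(`(intercept)` = 1, train_X)
  qd <- qr(D)
  if (qd$rank < ncol(D))
    stop(sprintf("singular design: rank %d < %d columns", qd$rank, ncol(D)))
  w <- qr.coef(qd, train_Y)
  structure(list(weights = w), class = "linear_map")
}

#' @export
predict.linear_map <- function(object, newdata, ...) {
  cbind(1, as.matrix(unclass(newdata))) %*% object$weights
}

#' Score zero-shot predictions by per-word pattern correlation
#'
#' For each held-out word, the Pearson correlation between the predicted and
#' the observed electrode pattern (across electrodes). Words whose observed
#' pattern has zero variance are dropped with a message.
#'
#' @param map a `linear_map` from [fit_ols()].
#' @param test_X held-out embedding rows.
#' @param test_Y held-out brain-embedding rows.
#' @return list with `per_word_r` (one r per retained word) and `mean_r`.
#' @export
score_zero_shot <- function(map, test_X, test_Y) {
  if (ncol(test_Y) < 2)
    stop("pattern correlation needs >= 2 electrodes")
  pred <- predict(map, test_X)
  r <- vapply(seq_len(nrow(test_Y)), function(i)
    pearson(pred[i, ], test_Y[i, ]), numeric(1))
  if (anyNA(r)) {
    message(sprintf("dropped %d word(s) with zero-variance observed pattern",
                    sum(is.na(r))))
  }
  list(per_word_r = r, mean_r = mean(r, na.rm = TRUE))
}

#' Replace test embeddings by their nearest training embeddings
#'
#' The memorisation control: each held-out word's embedding is substituted by
#' the training embedding with maximal cosine similarity (ties broken toward
#' the earliest training row). If the zero-shot map merely memorises the
#' training set, this substitution costs nothing; precise interpolation shows
#' up as a drop in performance.
#'
#' @param train_X training embedding rows.
#' @param test_X test embedding rows.
#' @return list with `X` (substituted test rows) and `index` (chosen training
#'   row per test row).
#' @export
nearest_train_control <- function(train_X, test_X) {
  train_X <- as.matrix(unclass(train_X)); test_X <- as.matrix(unclass(test_X))
  if (!nrow(train_X)) stop("empty training set")
  sim <- cosine_sim(test_X, train_X)
  idx <- apply(sim, 1, which.max)          # which.max takes the earliest tie
  list(X = train_X[idx, , drop = FALSE], index = idx)
}

#' Zero-shot encoding analysis
#'
#' The central fitting routine: at every lag, and for every cross-validation
#' fold, an OLS map from embeddings to electrode patterns is estimated on the
#' training folds (word types disjoint from the test fold) and evaluated on
#' the held-out fold by per-word pattern correlation. Three variants are
#' available: `actual` (the genuine test embeddings), `nearest` (each test
#' embedding replaced by its most cosine-similar training embedding), and
#' `shuffled` (test-fold word-to-embedding assignment permuted; averaged over
#' `n_shuffle` permutations).
#'
#' @param table an [embedding_table()] whose rows align with the fold
#'   specification's events.
#' @param brain named list mapping lag (character ms) to a words x electrodes
#'   matrix, rows aligned the same way (e.g. from [epoch_lags()] or
#'   [oracle_brain_embeddings()]).
#' @param fs a `fold_spec`.
#' @param variants subset of `c("actual", "nearest", "shuffled")`.
#' @param n_shuffle permutations averaged for the shuffled variant.
#' @param seed integer seed (shuffled variant only).
#' @param nearest_from where the nearest-neighbour control draws candidates:
#'   the conservative `"train"` default or the less conservative `"test"`.
#' @return an object of class `zs_encoding`: per-lag per-word correlations
#'   (`scores`, a long data.frame), per-lag summaries (`summary`), the lags,
#'   variants and embedding kind.
#' @export
zs_encode <- function(table, brain, fs,
                      variants = c("actual", "nearest", "shuffled"),
                      n_shuffle = 10, seed = 1L,
                      nearest_from = c("train", "test")) {
  variants <- match.arg(variants, several.ok = TRUE)
  nearest_from <- match.arg(nearest_from)
  assert_zero_shot(fs)
  ev <- fs$events
  if (nrow(table) != nrow(ev))
    stop("embedding rows must align with the fold events")
  lags <- as.numeric(names(brain))
  scores <- list()
  for (li in seq_along(brain)) {
    Y <- brain[[li]]
    if (nrow(Y) != nrow(ev)) stop("brain embedding rows must align with events")
    for (variant in variants) {
      r_all <- rep(NA_real_, nrow(ev))
      for (f in seq_len(fs$k) - 1L) {
        te <- which(ev$fold == f); tr <- which(ev$fold != f)
        Xtr <- unclass(table)[tr, , drop = FALSE]
        Ytr <- Y[tr, , drop = FALSE]
        map <- fit_ols(Xtr, Ytr)
        Xte <- unclass(table)[te, , drop = FALSE]
        if (variant == "actual") {
          r_all[te] <- score_zero_shot(map, Xte, Y[te, , drop = FALSE])$per_word_r
        } else if (variant == "nearest") {
          pool <- if (nearest_from == "train") Xtr else Xte
          if (nearest_from == "test") {
            # nearest other word within the test fold
            sim <- cosine_sim(Xte, Xte); diag(sim) <- -Inf
            sub <- Xte[apply(sim, 1, which.max), , drop = FALSE]
          } else sub <- nearest_train_control(Xtr, Xte)$X
          r_all[te] <- score_zero_shot(map, sub, Y[te, , drop = FALSE])$per_word_r
        } else {  # shuffled
          acc <- 0
          for (s in seq_len(n_shuffle)) {
            shuf <- shuffle_assignment(table, fs, f,
                                       seed = seed + 7919L * s + f)
            acc <- acc + score_zero_shot(map,
                                         unclass(shuf)[te, , drop = FALSE],
                                         Y[te, , drop = FALSE])$per_word_r
          }
          r_all[te] <- acc / n_shuffle
        }
      }
      scores[[length(scores) + 1L]] <-
        data.frame(lag_ms = lags[li], variant = variant,
                   word = ev$token, r = r_all, stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(rbind, scores)
  summ <- do.call(rbind, lapply(split(scores, scores[c("lag_ms", "variant")],
                                      drop = TRUE), function(d)
    data.frame(lag_ms = d$lag_ms[1], variant = d$variant[1],
               mean_r = mean(d$r, na.rm = TRUE),
               se_r = stats::sd(d$r, na.rm = TRUE) / sqrt(sum(!is.na(d$r))),
               n = sum(!is.na(d$r)), stringsAsFactors = FALSE)))
  summ <- summ[order(summ$variant, summ$lag_ms), ]
  rownames(summ) <- NULL
  structure(list(scores = scores, summary = summ, lags_ms = lags,
                 variants = variants, k = fs$k,
                 embedding_kind = attr(table, "kind")),
            class = "zs_encoding")
}

#' @export
print.zs_encoding <- function(x, ...) {
  cat("Zero-shot encoding model\n")
  cat(sprintf("  embedding kind: %s; %d folds; %d lag(s); variants: %s\n",
              x$embedding_kind, x$k, length(x$lags_ms),
              paste(x$variants, collapse = ", ")))
  act <- x$summary[x$summary$variant == x$variants[1], ]
  pk <- act[which.max(act$mean_r), ]
  cat(sprintf("  peak mean r (%s) = %.3f at lag %g ms\n",
              pk$variant, pk$mean_r, pk$lag_ms))
  invisible(x)
}

#' @export
summary.zs_encoding <- function(object, ...) {
  object$summary
}

#' @export
plot.zs_encoding <- function(x, ...) {
  s <- x$summary
  cols <- c(actual = "blue", nearest = "red", shuffled = "black")
  graphics::plot(NULL, xlim = range(s$lag_ms),
                 ylim = range(c(s$mean_r - s$se_r, s$mean_r + s$se_r)),
                 xlab = "lag (ms)", ylab = "mean pattern correlation (r)", ...)
  graphics::abline(h = 0, col = "grey70")
  for (v in unique(s$variant)) {
    d <- s[s$variant == v, ]
    graphics::lines(d$lag_ms, d$mean_r, col = cols[[v]] %||% "darkgreen")
    graphics::segments(d$lag_ms, d$mean_r - d$se_r, d$lag_ms,
                       d$mean_r + d$se_r,
                       col = grDevices::adjustcolor(cols[[v]] %||% "darkgreen",
                                                    0.4))
  }
  graphics::legend("topleft", legend = unique(s$variant),
                   col = cols[unique(s$variant)], lty = 1, bty = "n")
  invisible(x)
}

#' Write encoding results to TSV
#'
#' Per-word scores (`lag_ms`, `variant`, `word`, `r`) and, alongside, a
#' per-lag summary file (`<path>` with suffix `_summary.tsv`).
#' @param x a `zs_encoding`.
#' @param path output TSV path for the per-word scores.
#' @export
save_encoding <- function(x, path) {
  utils::write.table(x$scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$summary, sub("\\.tsv$", "_summary.tsv", path),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
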