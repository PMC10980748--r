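#' Bin the continuous signal for the decoder
#'
#' For each word event and electrode, the signal is averaged in `n_bins`
#' consecutive bins of `bin_ms` each (10 x 62.5 ms = 625 ms; 32 samples per
#' bin at 512 Hz), the whole binned window centred at onset + lag. Events
#' whose window leaves the recording are dropped with a warning.
#'
#' @param sig an `hfbb_signal`.
#' @param events data.frame with `onset_s` (stream time).
#' @param lag_ms centre lag of the binned window (ms).
#' @param n_bins,bin_ms bin count and width (ms).
#' @return list with `tensor` (words x electrodes x n_bins array) and `kept`
#'   (retained event row indices).
#' @export
bin_signal <- function(sig, events, lag_ms, n_bins = 10, bin_ms = 62.5) {
  fs <- sig$fs_hz
  Lb <- round(bin_ms * fs / 1000)
  Ltot <- n_bins * Lb
  off <- sig$onset_offset_s %||% 0
  centers <- floor((events$onset_s + off + lag_ms / 1000) * fs) + 1
  starts <- centers - floor(Ltot / 2)
  kept <- which(starts >= 1 & starts + Ltot - 1 <= ncol(sig$power))
  if (!length(kept)) stop("no events with complete binned windows")
  if (length(kept) < nrow(events))
    warning(sprintf("dropped %d event(s) with out-of-range windows",
                    nrow(events) - length(kept)))
  n_el <- nrow(sig$power)
  arr <- array(0, c(length(kept), n_el, n_bins))
  for (i in seq_along(kept)) {
    s0 <- starts[kept[i]]
    for (b in seq_len(n_bins)) {
      ix <- (s0 + (b - 1) * Lb):(s0 + b * Lb - 1)
      arr[i, , b] <- rowMeans(sig$power[, ix, drop = FALSE])
    }
  }
  list(tensor = arr, kept = kept, n_bins = n_bins, bin_ms = bin_ms,
       samples_per_bin = Lb)
}

#' Decoder configuration
#'
#' The default network is the smallest architecture honouring a convolutional
#' decoder trained with MSE and early stopping: a 1-D convolution over the
#' time bins (electrodes as input channels, `conv_channels` output channels,
#' kernel `conv_kernel`), flattened and passed through one hidden dense layer
#' to the embedding output. Optimised with Adam on minibatches; training
#' stops when the development-fold MSE fails to improve for `patience`
#' epochs.
#'
#' @param conv_channels,conv_kernel convolution width and kernel size.
#' @param hidden hidden dense layer size.
#' @param dropout dropout probability on the hidden layer during training.
#' @param activation `"relu"` (default) or `"linear"` hidden activations;
#'   the linear setting turns the network into a factored linear map, handy
#'   for parameter-recovery checks against analytic ground truth.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs,patience training length and early-stopping patience.
#' @param ensemble_size number of independently initialised members.
#' @return a `decoder_config` list.
#' @export
decoder_config <- function(conv_channels = 32, conv_kernel = 3, hidden = 128,
                           dropout = 0.2, lr = 1e-3, batch_size = 32,
                           max_epochs = 100, patience = 10,
                           ensemble_size = 6,
                           activation = c("relu", "linear")) {
  if (ensemble_size < 1) stop("ensemble_size must be >= 1")
  structure(list(conv_channels = conv_channels, conv_kernel = conv_kernel,
                 hidden = hidden, dropout = dropout, lr = lr,
                 batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience, ensemble_size = ensemble_size,
                 activation = match.arg(activation)),
            class = "decoder_config")
}

# ---- minimal conv-net engine (base R matrix ops) --------------------------

# im2col for a 1-D convolution over the bin axis: input n x E x B ->
# (n * P) x (E * K) with P = B - K + 1 output positions.
im2col <- function(x, k) {
  n <- dim(x)[1]; e <- dim(x)[2]; b <- dim(x)[3]
  p <- b - k + 1
  out <- matrix(0, n * p, e * k)
  for (pos in seq_len(p))
    for (o in seq_len(k))
      out[(pos - 1) * n + seq_len(n), (o - 1) * e + seq_len(e)] <-
        x[, , pos + o - 1]
  out
}

net_init <- function(e, b, out_dim, cfg) {
  p <- b - cfg$conv_kernel + 1
  flat <- p * cfg$conv_channels
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0,
                                                sqrt(2 / nin)), nin, nout)
  list(Wc = he(e * cfg$conv_kernel, cfg$conv_channels),
       bc = rep(0, cfg$conv_channels),
       W1 = he(flat, cfg$hidden), b1 = rep(0, cfg$hidden),
       W2 = he(cfg$hidden, out_dim) / sqrt(2), b2 = rep(0, out_dim),
       e = e, b = b, p = p, cfg = cfg)
}

net_forward <- function(net, x, train = FALSE) {
  n <- dim(x)[1]
  act <- if (identical(net$cfg$activation, "linear")) identity
         else function(z) pmax(z, 0)
  xc <- im2col(x, net$cfg$conv_kernel)              # (n*p) x (e*k)
  zc <- sweep(xc %*% net$Wc, 2, net$bc, `+`)        # (n*p) x C
  ac <- act(zc)
  flat <- matrix(0, n, net$p * net$cfg$conv_channels)
  for (pos in seq_len(net$p))
    flat[, (pos - 1) * net$cfg$conv_channels + seq_len(net$cfg$conv_channels)] <-
      ac[(pos - 1) * n + seq_len(n), ]
  z1 <- sweep(flat %*% net$W1, 2, net$b1, `+`)
  a1 <- act(z1)
  mask <- NULL
  if (train && net$cfg$dropout > 0) {
    mask <- matrix(stats::rbinom(length(a1), 1, 1 - net$cfg$dropout),
                   nrow(a1)) / (1 - net$cfg$dropout)
    a1 <- a1 * mask
  }
  out <- sweep(a1 %*% net$W2, 2, net$b2, `+`)
  list(out = out, cache = list(xc = xc, zc = zc, flat = flat, z1 = z1,
                               a1 = a1, mask = mask, n = n))
}

net_backward <- function(net, fw, dout) {
  ca <- fw$cache; n <- ca$n
  gW2 <- t(ca$a1) %*% dout; gb2 <- colSums(dout)
  lin <- identical(net$cfg$activation, "linear")
  da1 <- dout %*% t(net$W2)
  if (!is.null(ca$mask)) da1 <- da1 * ca$mask
  dz1 <- if (lin) da1 else da1 * (ca$z1 > 0)
  gW1 <- t(ca$flat) %*% dz1; gb1 <- colSums(dz1)
  dflat <- dz1 %*% t(net$W1)
  dac <- matrix(0, n * net$p, net$cfg$conv_channels)
  for (pos in seq_len(net$p))
    dac[(pos - 1) * n + seq_len(n), ] <-
      dflat[, (pos - 1) * net$cfg$conv_channels +
                seq_len(net$cfg$conv_channels)]
  dzc <- if (lin) dac else dac * (ca$zc > 0)
  gWc <- t(ca$xc) %*% dzc; gbc <- colSums(dzc)
  list(Wc = gWc, bc = gbc, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

adam_init <- function(net) {
  par <- c("Wc", "bc", "W1", "b1", "W2", "b2")
  list(m = lapply(net[par], function(p) p * 0),
       v = lapply(net[par], function(p) p * 0), t = 0)
}

adam_step <- function(net, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(st$m)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mh <- st$m[[nm]] / (1 - beta1^st$t)
    vh <- st$v[[nm]] / (1 - beta2^st$t)
    net[[nm]] <- net[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(net = net, st = st)
}

net_mse <- function(net, x, y) {
  mean((net_forward(net, x)$out - y)^2)
}

# ---------------------------------------------------------------------------

#' Train the neural-network decoder
#'
#' Trains the small convolutional network mapping binned electrode activity
#' to word embeddings by minimising mean squared error with Adam, monitoring
#' MSE on a held-out development fold and restoring the best weights when
#' the development error stops improving (early stopping). Deterministic for
#' a fixed seed and configuration.
#'
#' @param input words x electrodes x bins array (training + dev rows).
#' @param targets matrix of embedding targets aligned to `input` rows.
#' @param train_rows,dev_rows disjoint row index vectors.
#' @param config a [decoder_config()].
#' @param seed integer seed controlling initialisation, batch order, dropout.
#' @return a `word_decoder` with a `predict` method taking a new tensor.
#' @export
train_decoder <- function(input, targets, train_rows, dev_rows,
                          config = decoder_config(), seed = 1L) {
  if (length(intersect(train_rows, dev_rows)))
    stop("training and development rows must be disjoint")
  targets <- as.matrix(unclass(targets))
  with_seed(seed, {
    net <- net_init(dim(input)[2], dim(input)[3], ncol(targets), config)
    st <- adam_init(net)
    xtr <- input[train_rows, , , drop = FALSE]
    ytr <- targets[train_rows, , drop = FALSE]
    xdev <- input[dev_rows, , , drop = FALSE]
    ydev <- targets[dev_rows, , drop = FALSE]
    best <- list(net = net, mse = net_mse(net, xdev, ydev))
    stall <- 0
    n <- length(train_rows)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      for (b0 in seq(1, n, by = config$batch_size)) {
        ix <- ord[b0:min(b0 + config$batch_size - 1, n)]
        xb <- xtr[ix, , , drop = FALSE]
        yb <- ytr[ix, , drop = FALSE]
        fw <- net_forward(net, xb, train = TRUE)
        if (!all(is.finite(fw$out)))
          stop(paste("decoder diverged (non-finite loss); config:",
                     paste(names(config), unlist(config), sep = "=",
                           collapse = " ")))
        dout <- 2 * (fw$out - yb) / length(yb)
        grads <- net_backward(net, fw, dout)
        upd <- adam_step(net, grads, st, config$lr)
        net <- upd$net; st <- upd$st
      }
      dev_mse <- net_mse(net, xdev, ydev)
      if (dev_mse < best$mse - 1e-9) {
        best <- list(net = net, mse = dev_mse)
        stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= config$patience) break
      }
    }
    structure(list(net = best$net, dev_mse = best$mse, config = config,
                   seed = seed),
              class = "word_decoder")
  })
}

#' @export
predict.word_decoder <- function(object, newdata, ...) {
  net_forward(object$net, newdata)$out
}

#' Predict embeddings with every ensemble member
#'
#' Each independently initialised member's prediction is retained; no
#' premature averaging (the per-member softmax probabilities are averaged
#' downstream in [classify_and_auc()]).
#'
#' @param decoders list of `word_decoder`s trained on identical folds.
#' @param test_input words x electrodes x bins array.
#' @return list of per-member prediction matrices.
#' @export
ensemble_predict <- function(decoders, test_input) {
  lapply(decoders, function(d) predict(d, test_input))
}

# Single-positive ROC-AUC: the normalised rank of the positive's score among
# the negatives, counting ties half.
auc_single_positive <- function(score_pos, scores_neg) {
  (sum(score_pos > scores_neg) + 0.5 * sum(score_pos == scores_neg)) /
    length(scores_neg)
}

#' Cosine-softmax classification and per-label ROC-AUC
#'
#' For each ensemble member, cosine similarities between its predicted
#' embeddings and all candidate embeddings are turned into probabilities by a
#' softmax over candidates; the member probabilities are averaged. For each
#' label (candidate word), a one-vs-rest ROC-AUC is computed with the true
#' word as the single positive, so the AUC equals the normalised rank of the
#' true word's probability among the other test words' probabilities for
#' that label.
#'
#' @param predictions list of per-member prediction matrices (test words x
#'   dim), e.g. from [ensemble_predict()].
#' @param candidate_table candidate embeddings (one per label); by default
#'   the test fold's own embeddings.
#' @param labels integer vector mapping each test word (prediction row) to
#'   its candidate row.
#' @param temperature softmax temperature.
#' @return list with `per_label_auc` (one AUC per label), `mean_auc`, and
#'   the averaged probability matrix `probs` (test words x candidates).
#' @export
classify_and_auc <- function(predictions, candidate_table, labels,
                             temperature = 1) {
  cand <- as.matrix(unclass(candidate_table))
  probs <- 0
  for (pred in predictions) {
    pred <- as.matrix(pred)
    nrm <- sqrt(rowSums(pred^2))
    bad <- nrm == 0
    if (any(bad)) {
      message(sprintf("%d zero-norm prediction(s); uniform probabilities used",
                      sum(bad)))
      pred[bad, ] <- 0; nrm[bad] <- 1
    }
    sim <- (pred / nrm) %*% t(unit_rows(cand))
    sim[bad, ] <- 0
    z <- sim / temperature
    z <- z - apply(z, 1, max)
    p <- exp(z); p <- p / rowSums(p)
    probs <- probs + p
  }
  probs <- probs / length(predictions)
  per_label <- vapply(seq_len(nrow(cand)), function(j) {
    pos <- which(labels == j)
    if (length(pos) != 1) return(NA_real_)
    auc_single_positive(probs[pos, j], probs[-pos, j])
  }, numeric(1))
  list(per_label_auc = per_label,
       mean_auc = mean(per_label, na.rm = TRUE),
       probs = probs)
}

#' Zero-shot decoding analysis
#'
#' The reverse mapping: for each lag, and each test fold, an ensemble of
#' convolutional decoders is trained to predict word embeddings from binned
#' electrode activity on eight training folds, early-stopped on one
#' development fold, and evaluated on the held-out test fold by cosine-
#' softmax classification among the test fold's words, scored as per-label
#' ROC-AUC. The `shuffled` variant permutes the test fold's word-to-embedding
#' assignment before scoring.
#'
#' @param tensors named list mapping lag (character ms) to a words x
#'   electrodes x bins array aligned to `fs$events` (e.g. from [bin_signal()]
#'   or [oracle_decoder_input()]).
#' @param table embedding targets aligned to `fs$events` (typically the
#'   50-dim reduced table).
#' @param fs a `fold_spec`.
#' @param config a [decoder_config()].
#' @param variants subset of `c("actual", "shuffled")`.
#' @param test_folds 0-based fold indices to evaluate (default: all).
#' @param candidates `"fold"` restricts classification candidates to the test
#'   fold's words (the default evaluation strategy); `"all"` uses every
#'   selected word in the dataset.
#' @param seed integer seed.
#' @return an object of class `zs_decoding` with per-lag per-label AUCs
#'   (`scores`), per-lag summaries (`summary`), and metadata.
#' @export
zs_decode <- function(tensors, table, fs, config = decoder_config(),
                      variants = c("actual", "shuffled"),
                      test_folds = seq_len(fs$k) - 1L,
                      candidates = c("fold", "all"), seed = 1L) {
  variants <- match.arg(variants, several.ok = TRUE)
  candidates <- match.arg(candidates)
  assert_zero_shot(fs)
  ev <- fs$events
  tgt <- as.matrix(unclass(table))
  lags <- as.numeric(names(tensors))
  scores <- list()
  for (li in seq_along(tensors)) {
    arr <- tensors[[li]]
    for (f in test_folds) {
      te <- which(ev$fold == f)
      dev_fold <- setdiff(seq_len(fs$k) - 1L, f)
      dev_fold <- dev_fold[1 + (f %% length(dev_fold))]   # deterministic dev
      dv <- which(ev$fold == dev_fold)
      tr <- which(!(ev$fold %in% c(f, dev_fold)))
      members <- lapply(seq_len(config$ensemble_size), function(m)
        train_decoder(arr, tgt, tr, dv, config,
                      seed = seed + 104729L * m + 31L * f + li))
      preds <- ensemble_predict(members, arr[te, , , drop = FALSE])
      cand_rows <- if (candidates == "fold") te else seq_len(nrow(ev))
      cand <- tgt[cand_rows, , drop = FALSE]
      labels <- match(te, cand_rows)
      for (variant in variants) {
        lab <- labels
        if (variant == "shuffled")
          lab <- with_seed(seed + 293L * f + li,
                           labels[sample.int(length(labels))])
        res <- classify_and_auc(preds, cand, lab)
        scores[[length(scores) + 1L]] <-
          data.frame(lag_ms = lags[li], fold = f, variant = variant,
                     label = ev$token[te],
                     auc = res$per_label_auc[labels],
                     stringsAsFactors = FALSE)
      }
    }
  }
  scores <- do.call(rbind, scores)
  summ <- do.call(rbind, lapply(split(scores, scores[c("lag_ms", "variant")],
                                      drop = TRUE), function(d)
    data.frame(lag_ms = d$lag_ms[1], variant = d$variant[1],
               mean_auc = mean(d$auc, na.rm = TRUE),
               se_auc = stats::sd(d$auc, na.rm = TRUE) /
                 sqrt(sum(!is.na(d$auc))),
               n = sum(!is.na(d$auc)), stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  structure(list(scores = scores, summary = summ, lags_ms = lags,
                 variants = variants, config = config, k = fs$k),
            class = "zs_decoding")
}

#' @export
print.zs_decoding <- function(x, ...) {
  cat("Zero-shot decoding model\n")
  cat(sprintf("  %d-member ensemble; %d folds; %d lag(s)\n",
              x$config$ensemble_size, x$k, length(x$lags_ms)))
  act <- x$summary[x$summary$variant == "actual", ]
  if (nrow(act)) {
    pk <- act[which.max(act$mean_auc), ]
    cat(sprintf("  peak mean ROC-AUC = %.3f at lag %g ms\n",
                pk$mean_auc, pk$lag_ms))
  }
  invisible(x)
}

#' @export
summary.zs_decoding <- function(object, ...) object$summary

#' @export
plot.zs_decoding <- function(x, ...) {
  s <- x$summary
  cols <- c(actual = "purple", shuffled = "black")
  graphics::plot(NULL, xlim = range(s$lag_ms), ylim = c(0.3, 1),
                 xlab = "lag (ms)", ylab = "mean ROC-AUC", ...)
  graphics::abline(h = 0.5, col = "grey70")
  for (v in unique(s$variant)) {
    d <- s[s$variant == v, ]
    graphics::lines(d$lag_ms, d$mean_auc, col = cols[[v]] %||% "darkgreen")
  }
  graphics::legend("topleft", legend = unique(s$variant),
                   col = cols[unique(s$variant)], lty = 1, bty = "n")
  invisible(x)
}

#' Linear decoding variant
#'
#' A linear counterpart to the network decoder, matched to the encoding
#' analysis: OLS regression from the per-word electrode pattern (single
#' 200-ms window) to the embedding, nine training folds and one test fold
#' (no development fold), then cosine-softmax classification and per-label
#' ROC-AUC.
#'
#' @param brain words x electrodes matrix at one lag, aligned to `fs$events`.
#' @param table embedding targets aligned the same way.
#' @param fs a `fold_spec`.
#' @param variants subset of `c("actual", "shuffled")`.
#' @param seed integer seed (shuffled variant).
#' @return list with `scores` (per-fold per-label AUC data.frame) and
#'   `mean_auc` per variant.
#' @export
linear_decode_variant <- function(brain, table, fs,
                                  variants = c("actual", "shuffled"),
                                  seed = 1L) {
  variants <- match.arg(variants, several.ok = TRUE)
  assert_zero_shot(fs)
  ev <- fs$events
  tgt <- as.matrix(unclass(table))
  scores <- list()
  for (f in seq_len(fs$k) - 1L) {
    te <- which(ev$fold == f); tr <- which(ev$fold != f)
    map <- fit_ols(brain[tr, , drop = FALSE], tgt[tr, , drop = FALSE])
    pred <- predict(map, brain[te, , drop = FALSE])
    labels <- seq_along(te)
    for (variant in variants) {
      lab <- labels
      if (variant == "shuffled")
        lab <- with_seed(seed + f, labels[sample.int(length(labels))])
      res <- classify_and_auc(list(pred), tgt[te, , drop = FALSE], lab)
      scores[[length(scores) + 1L]] <-
        data.frame(fold = f, variant = variant, label = ev$token[te],
                   auc = res$per_label_auc[labels], stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(rbind, scores)
  mean_auc <- vapply(split(scores$auc, scores$variant), mean, numeric(1),
                     na.rm = TRUE)
  list(scores = scores, mean_auc = mean_auc)
}

#' Write decoding results to TSV
#'
#' Columns: lag_ms, fold, variant, label, auc.
#' @param x a `zs_decoding`.
#' @param path output path.
#' @export
save_decoding <- function(x, path) {
  utils::write.table(x$scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
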