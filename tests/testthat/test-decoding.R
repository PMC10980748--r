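test_that("bin_signal averages 32-sample bins at 512 Hz and matches the slice oracle", {
  fs <- 512
  x <- withr::with_seed(1, matrix(stats::rnorm(2 * fs * 12), 2))
  sig <- structure(list(power = x, fs_hz = fs, onset_offset_s = 0),
                   class = "hfbb_signal")
  events <- data.frame(onset_s = c(4.1, 7.33))
  bs <- bin_signal(sig, events, lag_ms = 100)
  expect_equal(bs$samples_per_bin, 32)
  expect_equal(dim(bs$tensor), c(2, 2, 10))
  Lb <- 32; Ltot <- 320
  for (i in 1:2) {
    c0 <- floor((events$onset_s[i] + 0.1) * fs) + 1
    s0 <- c0 - floor(Ltot / 2)
    for (b in 1:10) {
      oracle <- rowMeans(x[, (s0 + (b - 1) * Lb):(s0 + b * Lb - 1)])
      expect_equal(bs$tensor[i, , b], oracle)
    }
  }
  # constant signal: all bins equal
  cs <- structure(list(power = matrix(1.5, 2, fs * 12), fs_hz = fs,
                       onset_offset_s = 0), class = "hfbb_signal")
  bc <- bin_signal(cs, events, 0)
  expect_true(all(abs(bc$tensor - 1.5) < 1e-12))
  # out-of-range events dropped with a warning
  expect_warning(bin_signal(sig, rbind(events, data.frame(onset_s = 0.01)), 0),
                 "dropped")
})

test_that("decoder training reduces dev MSE and is deterministic by seed", {
  n <- 120; e <- 6; b <- 10; d <- 8
  x <- withr::with_seed(2, array(stats::rnorm(n * e * b), c(n, e, b)))
  W <- withr::with_seed(3, matrix(stats::rnorm(e * b * d, sd = 0.3), e * b))
  y <- matrix(apply(x, 1, c), n, byrow = TRUE) %*% W
  cfg <- decoder_config(ensemble_size = 1, max_epochs = 30, patience = 5,
                        conv_channels = 16, hidden = 48)
  dec <- train_decoder(x, y, 1:100, 101:120, cfg, seed = 4)
  init_mse <- withr::with_seed(4, {
    net <- neuroalign:::net_init(e, b, d, cfg)
    neuroalign:::net_mse(net, x[101:120, , ], y[101:120, ])
  })
  expect_lt(dec$dev_mse, init_mse)
  dec2 <- train_decoder(x, y, 1:100, 101:120, cfg, seed = 4)
  expect_identical(dec$net$W2, dec2$net$W2)
  dec3 <- train_decoder(x, y, 1:100, 101:120, cfg, seed = 5)
  expect_false(identical(dec$net$W2, dec3$net$W2))
  expect_error(train_decoder(x, y, 1:100, 90:120, cfg), "disjoint")
})

test_that("decoder recovers a zero-noise linear map to high accuracy", {
  n <- 220; e <- 5; b <- 10; d <- 6
  x <- withr::with_seed(5, array(stats::rnorm(n * e * b), c(n, e, b)))
  W <- withr::with_seed(6, matrix(stats::rnorm(e * b * d, sd = 0.2), e * b))
  y <- matrix(apply(x, 1, c), n, byrow = TRUE) %*% W
  cfg <- decoder_config(ensemble_size = 1, max_epochs = 400, patience = 60,
                        dropout = 0, lr = 5e-3, activation = "linear")
  dec <- train_decoder(x, y, 1:180, 181:200, cfg, seed = 7)
  test_mse <- mean((predict(dec, x[201:220, , ]) - y[201:220, ])^2)
  expect_lt(test_mse, 1e-3 * stats::var(as.vector(y)))
})

test_that("ensemble prediction keeps members separate until probability averaging", {
  n <- 40; e <- 4; b <- 10; d <- 5
  x <- withr::with_seed(8, array(stats::rnorm(n * e * b), c(n, e, b)))
  y <- withr::with_seed(9, matrix(stats::rnorm(n * d), n))
  cfg <- decoder_config(ensemble_size = 1, max_epochs = 3, patience = 2,
                        conv_channels = 8, hidden = 16)
  d1 <- train_decoder(x, y, 1:30, 31:40, cfg, seed = 1)
  d2 <- train_decoder(x, y, 1:30, 31:40, cfg, seed = 2)
  preds <- ensemble_predict(list(d1, d2), x[1:5, , ])
  expect_length(preds, 2)
  expect_false(identical(preds[[1]], preds[[2]]))
  # single member: passthrough of its prediction
  expect_identical(ensemble_predict(list(d1), x[1:5, , ])[[1]],
                   predict(d1, x[1:5, , ]))
})

test_that("cosine-softmax AUC: perfect predictions give 1, shuffled labels ~0.5", {
  d <- 12; n <- 30
  emb <- withr::with_seed(10, matrix(stats::rnorm(n * d), n))
  # predictions identical to the true embeddings: every label ranked first
  res <- classify_and_auc(list(emb), emb, seq_len(n))
  expect_equal(res$mean_auc, 1)
  expect_true(all(res$per_label_auc == 1))
  # shuffled labels: mean AUC near chance over repeats
  aucs <- vapply(1:30, function(s) {
    lab <- withr::with_seed(100 + s, sample.int(n))
    classify_and_auc(list(emb), emb, lab)$mean_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("per-label AUC equals the exhaustive rank oracle (single positive)", {
  d <- 6; n <- 15
  emb <- withr::with_seed(11, matrix(stats::rnorm(n * d), n))
  pred <- emb + withr::with_seed(12, matrix(stats::rnorm(n * d), n))
  res <- classify_and_auc(list(pred), emb, seq_len(n))
  for (j in seq_len(n)) {
    pos <- res$probs[j, j]; neg <- res$probs[-j, j]
    # exhaustive pair counting
    oracle <- (sum(outer(pos, neg, `>`)) + 0.5 * sum(outer(pos, neg, `==`))) /
      length(neg)
    expect_equal(res$per_label_auc[j], oracle)
    # normalised-rank identity
    expect_equal(res$per_label_auc[j],
                 (rank(c(pos, neg))[1] - 1) / length(neg))
  }
})

test_that("softmax is invariant to adding a constant to a word's logits", {
  sim <- withr::with_seed(13, matrix(stats::rnorm(8 * 8), 8))
  softmax_rows <- function(z) {
    z <- z - apply(z, 1, max); p <- exp(z); p / rowSums(p)
  }
  expect_equal(softmax_rows(sim), softmax_rows(sim + 5), tolerance = 1e-12)
})

test_that("zero-norm predictions fall back to uniform probabilities", {
  emb <- withr::with_seed(14, matrix(stats::rnorm(5 * 4), 5))
  pred <- emb; pred[2, ] <- 0
  expect_message(res <- classify_and_auc(list(pred), emb, 1:5), "zero-norm")
  expect_equal(res$probs[2, ], rep(0.2, 5))
})

test_that("linear decoding variant separates signal from shuffled labels", {
  # small noise keeps the electrode-pattern design full rank
  s <- tiny_setup(n_types = 60, embed_dim = 10, n_el = 14, noise_sd = 0.05,
                  k = 6)
  br <- oracle_brain_embeddings(s$fs$events, s$sel_table, s$gt, 200)
  res <- linear_decode_variant(br[[1]], s$sel_table, s$fs, seed = 3)
  expect_gt(res$mean_auc[["actual"]], 0.95)
  expect_lt(abs(res$mean_auc[["shuffled"]] - 0.5), 0.12)
})

test_that("zero-shot decoding with the network ensemble beats chance on clean data", {
  s <- tiny_setup(n_types = 50, embed_dim = 10, n_el = 10,
                  noise_sd = 0.05, k = 5)
  tens <- list("200" = oracle_decoder_input(s$fs$events, s$sel_table, s$gt,
                                            200, seed = 4))
  cfg <- decoder_config(ensemble_size = 2, max_epochs = 25, patience = 5,
                        conv_channels = 16, hidden = 48)
  dec <- zs_decode(tens, s$sel_table, s$fs, cfg,
                   variants = c("actual", "shuffled"), test_folds = c(0, 2),
                   seed = 6)
  sm <- summary(dec)
  expect_gt(sm$mean_auc[sm$variant == "actual"], 0.8)
  expect_lt(abs(sm$mean_auc[sm$variant == "shuffled"] - 0.5), 0.15)
  expect_output(print(dec), "ROC-AUC")
  f <- withr::local_tempfile(fileext = ".tsv")
  save_decoding(dec, f)
  expect_equal(names(utils::read.table(f, sep = "\t", header = TRUE)),
               c("lag_ms", "fold", "variant", "label", "auc"))
})
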