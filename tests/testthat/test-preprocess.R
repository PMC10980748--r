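test_that("despike replaces impulses, leaves clean samples bit-identical", {
  x <- rep(1, 200); x[50] <- 1e6
  noise <- withr::with_seed(1, stats::rnorm(200, sd = 0.01))
  sig <- rbind(x + noise, noise)
  rec <- toy_recording(sig)
  out <- despike(rec)
  expect_lt(abs(out$signal[1, 50] - 1), 0.2)
  expect_identical(out$signal[1, -50], sig[1, -50])
  expect_identical(out$signal[2, ], sig[2, ])   # no outliers: identity
  expect_equal(out$spike_flags[[1]], 50L)
})

test_that("despike flags injected spikes with a low false-positive rate", {
  n <- 20000
  x <- withr::with_seed(2, stats::rnorm(n))
  spikes <- seq(500, n, by = 997)
  x[spikes] <- x[spikes] + 40
  rec <- toy_recording(rbind(x))
  out <- despike(rec)
  expect_true(all(spikes %in% out$spike_flags[[1]]))
  fp <- setdiff(out$spike_flags[[1]], spikes)
  expect_lt(length(fp) / n, 0.01)
  # brute-force quantile check of the threshold definition
  md <- stats::median(x); iqr <- stats::IQR(x)
  expect_setequal(out$spike_flags[[1]],
                  which(x < md - 4 * iqr | x > md + 4 * iqr))
})

test_that("despike errors on an electrode with too few clean samples", {
  sig <- rbind(c(1, 2, 3, rep(NaN, 97)),
               withr::with_seed(9, stats::rnorm(100)))
  expect_error(despike(toy_recording(sig)), "electrode 1")
  # non-finite samples count as spikes and are imputed
  sig2 <- rbind(withr::with_seed(10, stats::rnorm(100)))
  sig2[1, 40] <- NaN
  out <- despike(toy_recording(sig2))
  expect_true(all(is.finite(out$signal)))
  expect_true(40 %in% out$spike_flags[[1]])
})

test_that("common average referencing matches the per-sample oracle", {
  sig <- withr::with_seed(3, matrix(stats::rnorm(5 * 50), 5))
  out <- common_average_reference(toy_recording(sig))
  expect_lt(max(abs(colMeans(out$signal))), 1e-12)
  oracle <- apply(sig, 2, function(col) col - mean(col))
  expect_equal(out$signal, oracle)
  # two identical electrodes cancel
  same <- rbind(sig[1, ], sig[1, ])
  expect_equal(common_average_reference(toy_recording(same))$signal,
               matrix(0, 2, 50))
  expect_error(common_average_reference(toy_recording(sig[1, , drop = FALSE])),
               ">= 2 electrodes")
})

test_that("hfbb excludes line-noise centres and tracks an AM envelope", {
  fs <- 512; tt <- (0:(fs * 8 - 1)) / fs
  # pure 120 Hz line: all nearby centres dropped, output nearly flat
  line <- sin(2 * pi * 120 * tt)
  broad <- withr::with_seed(4, stats::rnorm(length(tt)))
  rec <- toy_recording(rbind(line, broad), fs_hz = fs)
  out <- hfbb_power(rec)
  mid <- 200:(length(tt) - 200)
  # z-scoring forces unit variance; compare raw log-power spread instead
  raw_spread <- function(x) {
    p <- 0
    for (f in setdiff(seq(70, 200, 5), c(115, 120, 125, 175, 180, 185)))
      p <- p + neuroalign:::morlet_power(x, fs, f, 6)
    stats::sd(log(p / 21)[mid])
  }
  expect_lt(raw_spread(line), 0.3)
  expect_gt(raw_spread(broad), raw_spread(line))
  # z-invariant over the full recording
  expect_equal(rowMeans(out$power), c(0, 0), tolerance = 1e-6)
  expect_equal(apply(out$power, 1, stats::sd), c(1, 1), tolerance = 1e-6)
})

test_that("hfbb power recovers the squared envelope of an AM carrier", {
  fs <- 512; tt <- (0:(fs * 10 - 1)) / fs
  env <- 1 + 0.5 * sin(2 * pi * 0.7 * tt)
  x <- env * sin(2 * pi * 140 * tt)
  out <- hfbb_power(toy_recording(rbind(x, x + 1e-3), fs_hz = fs))
  sm <- smooth_zero_phase(out, kernel_ms = 50)
  mid <- 500:(length(tt) - 500)
  expect_gt(stats::cor(sm$power[1, mid], (env^2)[mid]), 0.9)
})

test_that("zero-phase Hamming smoothing is symmetric, unit-gain, and matches a two-pass oracle", {
  fs <- 200
  imp <- rep(0, 100); imp[50] <- 1
  sig <- structure(list(power = rbind(imp), fs_hz = fs, provenance = NULL),
                   class = "hfbb_signal")
  out <- smooth_zero_phase(sig, kernel_ms = 50)
  y <- out$power[1, ]
  expect_equal(length(y), 100)
  expect_equal(which.max(y), 50)
  win <- 40:60
  expect_equal(y[50 + (win - 50)], y[50 - (win - 50)], tolerance = 1e-12)
  # constant input passes unchanged (unit-sum kernel + reflect padding)
  cst <- structure(list(power = rbind(rep(3.5, 80)), fs_hz = fs),
                   class = "hfbb_signal")
  expect_equal(smooth_zero_phase(cst, 50)$power[1, ], rep(3.5, 80))
  # direct two-pass convolution oracle on a 100-sample toy
  x <- withr::with_seed(5, stats::rnorm(100))
  m <- round(50 * fs / 1000)
  h <- 0.54 - 0.46 * cos(2 * pi * (0:(m - 1)) / (m - 1)); h <- h / sum(h)
  pad <- function(v) c(rev(v[2:(1 + (m - 1) %/% 2)]), v,
                       rev(v[length(v) - seq_len(m - 1 - (m - 1) %/% 2)]))
  conv1 <- function(v) {
    vp <- pad(v)
    vapply(seq_along(v), function(i) sum(h * vp[i:(i + m - 1)]), numeric(1))
  }
  oracle <- rev(conv1(rev(conv1(x))))
  got <- smooth_zero_phase(structure(list(power = rbind(x), fs_hz = fs),
                                     class = "hfbb_signal"), 50)$power[1, ]
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("default lag grid has 321 points and epoching averages 102 samples at 512 Hz", {
  g <- lag_grid()
  expect_equal(g$n_lags, (4000 + 4000) / 25 + 1)
  expect_equal(g$n_lags, 321)
  expect_equal(floor(g$window_ms * 512 / 1000), 102)
  expect_error(lag_grid(0, 100, 33), "multiple")
})

test_that("epoch_lags equals a per-event slice-and-mean oracle", {
  fs <- 512
  x <- withr::with_seed(6, matrix(stats::rnorm(3 * fs * 20), 3))
  sig <- structure(list(power = x, fs_hz = fs, onset_offset_s = 0),
                   class = "hfbb_signal")
  events <- data.frame(onset_s = c(5.3, 9.71, 14.2))
  g <- lag_grid(-100, 100, 100, window_ms = 200)
  ep <- epoch_lags(sig, events, g)
  L <- floor(200 * fs / 1000)
  for (li in seq_along(g$lags_ms)) {
    for (i in seq_len(3)) {
      c0 <- floor((events$onset_s[i] + g$lags_ms[li] / 1000) * fs) + 1
      st <- c0 - floor(L / 2)
      oracle <- rowMeans(x[, st:(st + L - 1)])
      expect_equal(ep$embeddings[[li]][i, ], oracle)
    }
  }
  # constant signal: every entry equals the constant
  cs <- structure(list(power = matrix(2.25, 2, fs * 20), fs_hz = fs,
                       onset_offset_s = 0), class = "hfbb_signal")
  epc <- epoch_lags(cs, events, g)
  expect_true(all(abs(unlist(epc$embeddings) - 2.25) < 1e-12))
  # events whose windows leave the recording are dropped with a warning
  ev2 <- rbind(events, data.frame(onset_s = 0.05))
  expect_warning(ep2 <- epoch_lags(sig, ev2, g), "dropped 1")
  expect_equal(ep2$kept, 1:3)
  expect_error(epoch_lags(sig, data.frame(onset_s = -50), g), "no events")
})

test_that("preprocessing chain records its fixed stage order", {
  st <- tiny_stream(6, 10, 30, seed = 8)
  tab <- generate_contextual_table(st, 4, 10, seed = 9)
  gt <- ground_truth(matrix(stats::rnorm(8), 2), noise_sd = 0.05)
  rec <- generate_recording(st, tab, gt, seed = 3)
  sig <- preprocess_recording(rec)
  expect_equal(sig$provenance,
               c("despike", "car", "hfbb_power", "smooth_zero_phase"))
})
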