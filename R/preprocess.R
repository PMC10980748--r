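#' Lag grid for the alignment analyses
#'
#' Lags run from `start_ms` to `stop_ms` in `step_ms` increments; at each lag
#' the epoching stage averages activity in a `window_ms` window centred on
#' onset + lag. The defaults span -4 s to +4 s in 25-ms steps (321 lags) with
#' a 200-ms window.
#'
#' @param start_ms,stop_ms,step_ms lag range and increment (ms).
#' @param window_ms averaging window length (ms).
#' @return an object of class `lag_grid` with the lags in `$lags_ms`.
#' @export
lag_grid <- function(start_ms = -4000, stop_ms = 4000, step_ms = 25,
                     window_ms = 200) {
  if ((stop_ms - start_ms) %% step_ms != 0)
    stop("(stop_ms - start_ms) must be a multiple of step_ms")
  lags <- seq(start_ms, stop_ms, by = step_ms)
  structure(list(start_ms = start_ms, stop_ms = stop_ms, step_ms = step_ms,
                 window_ms = window_ms, lags_ms = lags,
                 n_lags = length(lags)),
            class = "lag_grid")
}

#' Remove impulsive artifacts by robust thresholding and cubic interpolation
#'
#' Per electrode, samples outside `median +/- k * IQR` are flagged as spikes
#' and replaced by a natural cubic spline interpolated through the retained
#' samples; all other samples are returned bit-identical.
#'
#' @param raw a `raw_recording`.
#' @param k threshold in IQR multiples above/below the median.
#' @return the despiked `raw_recording`, with a `spike_flags` element (list of
#'   per-electrode flagged sample indices).
#' @export
despike <- function(raw, k = 4) {
  sig <- raw$signal
  flags <- vector("list", nrow(sig))
  for (e in seq_len(nrow(sig))) {
    x <- sig[e, ]
    fin <- is.finite(x)
    if (sum(fin) < 4)
      stop(sprintf("electrode %d is entirely spikes (despike needs >= 4 clean samples)", e))
    md <- stats::median(x[fin])
    iqr <- stats::IQR(x[fin])
    bad <- which(!fin | x < md - k * iqr | x > md + k * iqr)
    flags[[e]] <- bad
    if (length(bad)) {
      good <- setdiff(seq_along(x), bad)
      if (length(good) < 4)
        stop(sprintf("electrode %d is entirely spikes (despike needs >= 4 clean samples)", e))
      sig[e, bad] <- stats::spline(good, x[good], xout = bad,
                                   method = "natural")$y
    }
  }
  raw$signal <- sig
  raw$spike_flags <- flags
  raw$provenance <- c(raw$provenance, "despike")
  raw
}

#' Common average referencing
#'
#' Subtracts the instantaneous across-electrode mean from every sample, so
#' that the across-electrode mean of the output is exactly zero at every
#' time point.
#'
#' @param raw a `raw_recording` with at least two electrodes.
#' @return the re-referenced `raw_recording`.
#' @export
common_average_reference <- function(raw) {
  if (nrow(raw$signal) < 2)
    stop("common average referencing needs >= 2 electrodes")
  raw$signal <- sweep(raw$signal, 2, colMeans(raw$signal))
  raw$provenance <- c(raw$provenance, "car")
  raw
}

# Complex Morlet wavelet transform of one channel at one centre frequency,
# via FFT convolution (circular; the recording's padding absorbs wrap-around).
morlet_power <- function(x, fs, f0, n_cycles) {
  n <- length(x)
  sigma_t <- n_cycles / (2 * pi * f0)
  half <- ceiling(4 * sigma_t * fs)
  tt <- (-half:half) / fs
  w <- exp(2i * pi * f0 * tt) * exp(-tt^2 / (2 * sigma_t^2))
  w <- w / sum(abs(w))
  nf <- stats::nextn(n + length(w) - 1, c(2, 3, 5))
  X <- stats::fft(c(x, rep(0, nf - n)))
  W <- stats::fft(c(w, rep(0, nf - length(w))))
  y <- stats::fft(X * W, inverse = TRUE) / nf
  Mod(y[(half + 1):(half + n)])^2
}

#' High-frequency broadband power via wavelet decomposition
#'
#' Computes per-electrode power with six-cycle complex Morlet wavelets at
#' centre frequencies spanning the 70-200 Hz band, drops centres within
#' `exclusion_halfwidth_hz` of the 60/120/180 Hz line-noise frequencies,
#' averages linear power across the retained centres, log-transforms, and
#' z-scores each electrode over the full recording.
#'
#' @param raw a `raw_recording`.
#' @param band_hz two-element band (Hz).
#' @param n_cycles wavelet cycles.
#' @param exclude_hz line-noise frequencies to avoid.
#' @param exclusion_halfwidth_hz half-width of each exclusion zone (Hz).
#' @param step_hz spacing of wavelet centre frequencies (Hz).
#' @return an `hfbb_signal`: list with `power` (electrodes x samples, log-z
#'   units), `fs_hz`, `electrode_meta`, `provenance`.
#' @export
hfbb_power <- function(raw, band_hz = c(70, 200), n_cycles = 6,
                       exclude_hz = c(60, 120, 180),
                       exclusion_halfwidth_hz = 5, step_hz = 5) {
  if (raw$fs_hz <= 2 * band_hz[2])
    stop("sampling rate must exceed twice the band's upper edge")
  centers <- seq(band_hz[1], band_hz[2], by = step_hz)
  keep <- vapply(centers, function(f)
    all(abs(f - exclude_hz) > exclusion_halfwidth_hz), logical(1))
  centers <- centers[keep]
  if (!length(centers)) stop("no wavelet centres retained in the band")
  pow <- matrix(0, nrow(raw$signal), ncol(raw$signal))
  for (e in seq_len(nrow(raw$signal))) {
    acc <- 0
    for (f in centers)
      acc <- acc + morlet_power(raw$signal[e, ], raw$fs_hz, f, n_cycles)
    lp <- log(acc / length(centers))
    pow[e, ] <- (lp - mean(lp)) / stats::sd(lp)
  }
  structure(list(power = pow, fs_hz = raw$fs_hz,
                 electrode_meta = raw$electrode_meta,
                 onset_offset_s = raw$onset_offset_s %||% 0,
                 provenance = c(raw$provenance, "hfbb_power")),
            class = "hfbb_signal")
}

# Convolve x with kernel h (odd-ish length) using reflect padding;
# output has the length of x.
conv_reflect <- function(x, h) {
  m <- length(h)
  lpad <- (m - 1) %/% 2
  rpad <- m - 1 - lpad
  xp <- c(rev(x[seq_len(lpad) + 1]), x, rev(x[length(x) - seq_len(rpad)]))
  y <- stats::filter(xp, rev(h), method = "convolution", sides = 1)
  as.numeric(y[(m - 1 + 1):(m - 1 + length(x))])
}

#' Zero-phase Hamming smoothing
#'
#' Convolves each electrode's power trace with a unit-sum Hamming kernel of
#' `kernel_ms` duration, forward and then in the reverse direction, so the
#' net filter has zero phase. Edges are reflect-padded; output length equals
#' input length.
#'
#' @param sig an `hfbb_signal`.
#' @param kernel_ms kernel duration (ms).
#' @return the smoothed `hfbb_signal`.
#' @export
smooth_zero_phase <- function(sig, kernel_ms = 50) {
  m <- max(3L, round(kernel_ms * sig$fs_hz / 1000))
  if (m >= ncol(sig$power)) stop("kernel longer than the recording")
  n <- seq_len(m) - 1
  h <- 0.54 - 0.46 * cos(2 * pi * n / (m - 1))
  h <- h / sum(h)
  sig$power <- t(apply(sig$power, 1, function(x)
    rev(conv_reflect(rev(conv_reflect(x, h)), h))))
  sig$provenance <- c(sig$provenance, "smooth_zero_phase")
  sig
}

#' Epoch the continuous signal into lagged brain embeddings
#'
#' At every lag of the grid, each word event contributes one row: the mean of
#' `floor(window_ms * fs / 1000)` consecutive samples (102 at 512 Hz for a
#' 200-ms window) centred at onset + lag, per electrode. Events whose window
#' falls outside the recording at any lag are dropped with a warning.
#'
#' @param sig an `hfbb_signal`.
#' @param events data.frame with an `onset_s` column (stream time; the
#'   recording's internal padding offset is applied automatically).
#' @param grid a [lag_grid()].
#' @return list with `embeddings` (named list lag -> words x electrodes
#'   matrix), `kept` (row indices of retained events), `grid`.
#' @export
epoch_lags <- function(sig, events, grid = lag_grid()) {
  fs <- sig$fs_hz
  L <- floor(grid$window_ms * fs / 1000)
  n_s <- ncol(sig$power)
  off <- sig$onset_offset_s %||% 0
  center_at <- function(lag_ms)
    floor((events$onset_s + off + lag_ms / 1000) * fs) + 1
  first <- center_at(min(grid$lags_ms)) - floor(L / 2)
  last <- center_at(max(grid$lags_ms)) - floor(L / 2) + L - 1
  kept <- which(first >= 1 & last <= n_s)
  if (!length(kept)) stop("no events with complete windows at all lags")
  if (length(kept) < nrow(events))
    warning(sprintf("dropped %d event(s) with out-of-range windows",
                    nrow(events) - length(kept)))
  emb <- lapply(grid$lags_ms, function(l) {
    starts <- center_at(l)[kept] - floor(L / 2)
    m <- matrix(0, length(starts), nrow(sig$power))
    for (i in seq_along(starts))
      m[i, ] <- rowMeans(sig$power[, starts[i]:(starts[i] + L - 1),
                                   drop = FALSE])
    m
  })
  names(emb) <- as.character(grid$lags_ms)
  list(embeddings = emb, kept = kept, grid = grid)
}

#' Run the full preprocessing chain
#'
#' despike -> common average reference -> wavelet HFBB power -> zero-phase
#' Hamming smoothing, in the fixed order recorded in the output's provenance.
#'
#' @param raw a `raw_recording`.
#' @param despike_k IQR multiple for despiking.
#' @param kernel_ms smoothing kernel (ms).
#' @param ... passed to [hfbb_power()].
#' @return an `hfbb_signal`.
#' @export
preprocess_recording <- function(raw, despike_k = 4, kernel_ms = 50, ...) {
  raw <- despike(raw, k = despike_k)
  raw <- common_average_reference(raw)
  sig <- hfbb_power(raw, ...)
  smooth_zero_phase(sig, kernel_ms = kernel_ms)
}
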