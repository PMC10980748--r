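#' Ground truth for the synthetic recording generator
#'
#' Bundles the latent quantities that the simulator uses and that downstream
#' recovery tests compare against: a fixed linear map from embedding space to
#' electrode space, a lag-domain response kernel describing how the
#' high-frequency response unfolds around word onset, and nuisance parameters
#' (broadband noise, line-noise sinusoids, impulsive artifact spikes).
#'
#' The response kernel is a Gaussian peaking `peak_lag_ms` after word onset
#' (unit height at the peak) with an optional second pre-onset Gaussian at
#' -500 ms scaled by `pre_onset_gain`, mimicking anticipatory activity.
#'
#' @param map_matrix numeric matrix, electrodes x embedding dimensions; the
#'   latent linear code. With `normalize_map = TRUE` (default) nonzero rows
#'   are scaled to unit norm so every electrode has a comparable dynamic
#'   range; zero rows (silent electrodes) stay zero.
#' @param peak_lag_ms lag of the response peak relative to word onset (ms).
#' @param width_ms standard deviation of the Gaussian response kernel (ms).
#' @param pre_onset_gain relative height of the pre-onset component at -500 ms
#'   (0 disables it).
#' @param noise_sd standard deviation of additive white noise on the raw
#'   signal (same units as the carrier, whose RMS is 1).
#' @param carrier_band two-element Hz interval for the broadband carrier.
#' @param line_noise_amps length-3 amplitudes of 60/120/180 Hz sinusoids.
#' @param spike_rate artifact spikes per minute.
#' @param normalize_map scale nonzero map rows to unit norm.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(map_matrix,
                         peak_lag_ms = 200,
                         width_ms = 150,
                         pre_onset_gain = 0,
                         noise_sd = 0,
                         carrier_band = c(70, 200),
                         line_noise_amps = c(0, 0, 0),
                         spike_rate = 0,
                         normalize_map = TRUE) {
  map_matrix <- as.matrix(map_matrix)
  if (!all(is.finite(map_matrix))) stop("map_matrix must be finite")
  stopifnot_scalar_num(noise_sd, "noise_sd", min = 0)
  stopifnot_scalar_num(pre_onset_gain, "pre_onset_gain", min = 0)
  stopifnot_scalar_num(spike_rate, "spike_rate", min = 0)
  if (length(carrier_band) != 2L || carrier_band[1] >= carrier_band[2])
    stop("carrier_band must be an increasing Hz interval")
  if (length(line_noise_amps) != 3L) stop("line_noise_amps must have length 3")
  if (isTRUE(normalize_map)) {
    nrm <- sqrt(rowSums(map_matrix^2))
    pos <- nrm > 0
    map_matrix[pos, ] <- map_matrix[pos, , drop = FALSE] / nrm[pos]
  }
  structure(list(
    map_matrix = map_matrix,
    peak_lag_ms = peak_lag_ms,
    width_ms = width_ms,
    pre_onset_gain = pre_onset_gain,
    noise_sd = noise_sd,
    carrier_band = as.numeric(carrier_band),
    line_noise_amps = as.numeric(line_noise_amps),
    spike_rate = spike_rate
  ), class = "ground_truth")
}

#' Evaluate the lag-domain response kernel of a ground truth
#'
#' Unit height at `peak_lag_ms` by construction; the optional pre-onset
#' Gaussian sits at -500 ms.
#'
#' @param gt a [ground_truth()].
#' @param lag_ms numeric vector of lags in ms.
#' @return numeric vector of kernel weights.
#' @export
response_kernel <- function(gt, lag_ms) {
  g <- function(l) {
    exp(-(l - gt$peak_lag_ms)^2 / (2 * gt$width_ms^2)) +
      gt$pre_onset_gain * exp(-(l + 500)^2 / (2 * gt$width_ms^2))
  }
  g(lag_ms) / g(gt$peak_lag_ms)
}

#' Generate a synthetic token stream
#'
#' Emulates a transcript of continuous speech: `n_tokens` word occurrences
#' drawn from `n_types` distinct word types with Zipf-weighted frequencies,
#' at strictly increasing onsets in `(0, duration_s)`. Every type is forced
#' to occur at least once (the first `n_types` draws cover the inventory
#' before Zipf sampling fills the rest), so unique-instance selection always
#' retains exactly `n_types` events. Onsets are uniform order statistics
#' thinned to a minimum inter-word gap of 100 ms.
#'
#' @param n_types number of distinct word types (>= 2).
#' @param n_tokens total number of occurrences (>= n_types).
#' @param duration_s stream duration in seconds.
#' @param zipf_s Zipf exponent for type frequencies.
#' @param seed integer seed; identical seeds give identical streams.
#' @param min_gap_s minimum spacing between consecutive onsets (seconds).
#' @return a `token_stream`: a data.frame of events (`token`, `onset_s`,
#'   `type_id`, `occurrence_idx`) with the generator parameters as attributes.
#' @export
generate_stream <- function(n_types, n_tokens, duration_s, zipf_s = 1.1,
                            seed = 1L, min_gap_s = 0.1) {
  if (n_types < 2) stop("n_types must be >= 2")
  if (n_tokens < n_types)
    stop("n_tokens < n_types: cannot cover all types")
  stopifnot_scalar_num(duration_s, "duration_s", min = .Machine$double.eps)
  if ((n_tokens - 1) * min_gap_s >= duration_s)
    stop("duration too short for the requested token count at the minimum gap")
  with_seed(seed, {
    types <- sprintf("w%04d", seq_len(n_types))
    w <- (seq_len(n_types))^(-zipf_s)
    idx <- c(sample(seq_len(n_types)),
             if (n_tokens > n_types)
               sample(seq_len(n_types), n_tokens - n_types, replace = TRUE,
                      prob = w))
    idx <- idx[sample.int(n_tokens)]
    # uniform order statistics, then enforce the minimum gap by spreading the
    # leftover duration over sorted uniforms
    slack <- duration_s - (n_tokens - 1) * min_gap_s
    u <- sort(stats::runif(n_tokens, 0, slack))
    onsets <- u + (seq_len(n_tokens) - 1) * min_gap_s
    occ <- stats::ave(idx, idx, FUN = seq_along)
    ev <- data.frame(token = types[idx],
                     onset_s = onsets,
                     type_id = idx,
                     occurrence_idx = occ,
                     stringsAsFactors = FALSE)
    structure(ev, class = c("token_stream", "data.frame"),
              n_types = n_types, zipf_s = zipf_s, seed = seed,
              duration_s = duration_s)
  })
}

#' Generate per-occurrence contextual embeddings with cone geometry
#'
#' Each word type gets a random unit base vector; each occurrence's embedding
#' is the base vector rotated, within the plane spanned by the base vector and
#' a random orthogonal direction, by an angle drawn uniformly on
#' `[0, cone_angle_deg]`. Occurrences of a type therefore occupy a cone around
#' the type's base direction, tight for small angles (the static-embedding
#' limit at 0) and wide at 90 degrees. All rows are unit norm.
#'
#' @param stream a [generate_stream()] token stream.
#' @param embed_dim embedding dimensionality (>= 2).
#' @param cone_angle_deg maximal within-type rotation in degrees, in [0, 90].
#' @param seed integer seed.
#' @return an [embedding_table()] of kind `"contextual"`, rows aligned to the
#'   stream's events.
#' @export
generate_contextual_table <- function(stream, embed_dim = 50,
                                      cone_angle_deg = 20, seed = 1L) {
  if (embed_dim < 2) stop("embed_dim must be >= 2")
  if (cone_angle_deg < 0 || cone_angle_deg > 90)
    stop("cone_angle_deg must lie in [0, 90]")
  n_types <- attr(stream, "n_types")
  with_seed(seed, {
    base <- unit_rows(matrix(stats::rnorm(n_types * embed_dim),
                             nrow = n_types))
    n <- nrow(stream)
    m <- matrix(0, n, embed_dim)
    for (i in seq_len(n)) {
      b <- base[stream$type_id[i], ]
      d <- stats::rnorm(embed_dim)
      d <- d - sum(d * b) * b           # orthogonalise against the base
      d <- d / sqrt(sum(d^2))
      ang <- stats::runif(1, 0, cone_angle_deg) * pi / 180
      m[i, ] <- cos(ang) * b + sin(ang) * d
    }
    embedding_table(m, kind = "contextual",
                    provenance = list(source = "synthetic-cone",
                                      cone_angle_deg = cone_angle_deg,
                                      seed = seed))
  })
}

#' Synthesize a raw multielectrode recording from the latent linear code
#'
#' Each electrode carries a broadband carrier (a sum of fixed-frequency
#' sinusoids with random phases spanning the carrier band, RMS 1). The
#' carrier's amplitude envelope is `1 + gain * (W_e . x_i)` time-locked to
#' each word onset and shaped by the response kernel, so the high-frequency
#' broadband power recovered by the preprocessing chain encodes the latent
#' map applied to the word's embedding. White noise, 60/120/180 Hz line-noise
#' sinusoids, and impulsive artifact spikes (indices recorded in the output
#' metadata for despike testing) are added on top. Overlapping word responses
#' superpose additively.
#'
#' @param stream a token stream.
#' @param table an embedding table aligned to the stream.
#' @param gt a [ground_truth()].
#' @param fs_hz sampling rate; must exceed twice the carrier band's upper edge.
#' @param seed integer seed.
#' @param gain modulation depth of the word response relative to the unit
#'   baseline envelope.
#' @param regions optional character vector of per-electrode region labels
#'   (recycled); defaults to `"IFG"`.
#' @return a `raw_recording`: list with `signal` (electrodes x samples),
#'   `fs_hz`, `electrode_meta` (data.frame: electrode, participant, region)
#'   and `spike_index` metadata.
#' @export
generate_recording <- function(stream, table, gt, fs_hz = 512, seed = 1L,
                               gain = 0.6, regions = "IFG") {
  if (fs_hz <= 2 * gt$carrier_band[2])
    stop("fs_hz must exceed twice the carrier band's upper edge")
  n_el <- nrow(gt$map_matrix)
  dur <- attr(stream, "duration_s") + 2      # 1 s padding either side
  n_s <- ceiling(dur * fs_hz)
  tt <- (seq_len(n_s) - 1) / fs_hz - 1       # time axis; onset 0 at sample fs+1
  drive <- as.matrix(table) %*% t(gt$map_matrix)   # words x electrodes
  with_seed(seed, {
    # Carrier design. Frequencies: one coarse grid with exactly 10 Hz
    # separation, shared by all electrodes; every beat frequency is then a
    # multiple of 10 Hz, which completes whole cycles inside a 200-ms epoch
    # window and averages to ~0, so the baseline envelope is flat at the
    # epoch scale (closely spaced frequencies would beat slowly and
    # masquerade as word responses). Phases: random per frequency, rotated
    # by 2*pi*e/E across electrodes so the carriers sum to zero over the
    # array and common average referencing removes only the word-driven
    # deviations, not a chance common-mode carrier.
    grid <- seq(gt$carrier_band[1] + 6, gt$carrier_band[2] - 6, by = 10)
    grid <- grid[abs(grid - 120) > 7 & abs(grid - 180) > 7]
    k <- length(grid)
    freqs <- grid + stats::runif(1, -2.5, 2.5)
    ph0 <- stats::runif(k, 0, 2 * pi)
    sig <- matrix(0, n_el, n_s)
    # envelope per electrode: unit baseline plus kernel-shaped word responses
    env <- matrix(1, n_el, n_s)
    half <- ceiling((abs(gt$peak_lag_ms) + 500 + 4 * gt$width_ms) / 1000 * fs_hz)
    for (i in seq_len(nrow(stream))) {
      c0 <- floor((stream$onset_s[i] + 1) * fs_hz) + 1
      lo <- max(1L, c0 - half); hi <- min(n_s, c0 + half)
      lag_ms <- (tt[lo:hi] - stream$onset_s[i]) * 1000
      kw <- response_kernel(gt, lag_ms)
      env[, lo:hi] <- env[, lo:hi] +
        gain * outer(drive[i, ], kw)
    }
    env <- pmax(env, 0.05)                   # amplitude stays positive
    for (e in seq_len(n_el)) {
      ph <- ph0 + 2 * pi * (e - 1) / n_el
      carrier <- sqrt(2 / k) *
        colSums(sin(outer(2 * pi * freqs, tt) + ph))
      sig[e, ] <- env[e, ] * carrier
    }
    if (gt$noise_sd > 0)
      sig <- sig + matrix(stats::rnorm(n_el * n_s, sd = gt$noise_sd), n_el)
    ln <- gt$line_noise_amps
    for (j in seq_along(ln)) if (ln[j] > 0) {
      wave <- ln[j] * sin(2 * pi * (60 * j) * tt + stats::runif(1, 0, 2 * pi))
      sig <- sig + matrix(rep(wave, each = n_el), n_el)
    }
    spike_index <- NULL
    if (gt$spike_rate > 0) {
      n_spk <- stats::rpois(1, gt$spike_rate * dur / 60)
      if (n_spk > 0) {
        el <- sample.int(n_el, n_spk, replace = TRUE)
        at <- sample.int(n_s, n_spk)
        amp <- stats::rnorm(n_spk, 30, 3) * sample(c(-1, 1), n_spk, TRUE)
        for (s in seq_len(n_spk)) sig[el[s], at[s]] <- sig[el[s], at[s]] + amp[s]
        spike_index <- data.frame(electrode = el, sample = at)
      }
    }
    meta <- data.frame(electrode = seq_len(n_el),
                       participant = 1L,
                       region = rep_len(regions, n_el),
                       stringsAsFactors = FALSE)
    structure(list(signal = sig, fs_hz = fs_hz, electrode_meta = meta,
                   spike_index = spike_index, onset_offset_s = 1,
                   seed = seed),
              class = "raw_recording")
  })
}

#' Analytic brain embeddings implied by the ground truth
#'
#' Bypasses signal synthesis: at each lag, the expected per-word electrode
#' pattern is the response kernel evaluated at that lag times the embedding
#' mapped through the latent linear code, plus optional Gaussian noise. Used
#' to test the alignment stages quickly and to validate the full
#' synthesis-plus-preprocessing chain against its analytic target.
#'
#' @param stream a token stream (or any data.frame of events).
#' @param table embedding table aligned row-wise to the events.
#' @param gt a [ground_truth()].
#' @param lag_grid a [lag_grid()] or numeric vector of lags in ms.
#' @param seed integer seed (only consumed when `gt$noise_sd > 0`).
#' @return named list mapping each lag (as character ms) to a words x
#'   electrodes matrix.
#' @export
oracle_brain_embeddings <- function(stream, table, gt, lag_grid, seed = 1L) {
  lags <- if (inherits(lag_grid, "lag_grid")) lag_grid$lags_ms else lag_grid
  drive <- as.matrix(table) %*% t(gt$map_matrix)
  with_seed(seed, {
    out <- lapply(lags, function(l) {
      m <- response_kernel(gt, l) * drive
      if (gt$noise_sd > 0)
        m <- m + matrix(stats::rnorm(length(m), sd = gt$noise_sd),
                        nrow = nrow(m))
      m
    })
    names(out) <- as.character(lags)
    out
  })
}

#' Analytic decoder-input tensor implied by the ground truth
#'
#' Builds the words x electrodes x bins array the decoder consumes directly
#' from the latent code: bin `b` centred at `lag_ms + (b - (n_bins+1)/2) *
#' bin_ms` carries the kernel-weighted mapped embedding plus noise.
#'
#' @inheritParams oracle_brain_embeddings
#' @param lag_ms centre lag of the binned window (ms).
#' @param n_bins,bin_ms bin count and width (ms).
#' @return numeric array, words x electrodes x n_bins.
#' @export
oracle_decoder_input <- function(stream, table, gt, lag_ms,
                                 n_bins = 10, bin_ms = 62.5, seed = 1L) {
  centers <- lag_ms + (seq_len(n_bins) - (n_bins + 1) / 2) * bin_ms
  drive <- as.matrix(table) %*% t(gt$map_matrix)
  n <- nrow(drive); e <- ncol(drive)
  with_seed(seed, {
    arr <- array(0, c(n, e, n_bins))
    for (b in seq_len(n_bins)) {
      m <- response_kernel(gt, centers[b]) * drive
      if (gt$noise_sd > 0)
        m <- m + matrix(stats::rnorm(length(m), sd = gt$noise_sd), nrow = n)
      arr[, , b] <- m
    }
    arr
  })
}

#' Write a token stream's events to TSV
#'
#' Columns: token, onset_s, type_id, occurrence_idx.
#' @param stream a token stream.
#' @param path output path.
#' @export
save_stream <- function(stream, path) {
  utils::write.table(as.data.frame(stream), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a raw recording as TSV
#'
#' Plain-text container: a header of commented metadata lines (`# fs_hz`,
#' per-electrode participant and region) followed by the electrodes x samples
#' signal matrix, one electrode per row.
#' @param rec a `raw_recording`.
#' @param path file path.
#' @return `load_recording` returns a `raw_recording` (spike metadata is not
#'   persisted).
#' @export
save_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz\t%.10g", rec$fs_hz), con)
  writeLines(sprintf("# electrode\t%d\t%s\t%s", rec$electrode_meta$electrode,
                     as.character(rec$electrode_meta$participant),
                     rec$electrode_meta$region), con)
  utils::write.table(rec$signal, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname save_recording
#' @export
load_recording <- function(path) {
  hdr <- character()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  fs <- as.numeric(strsplit(hdr[1], "\t")[[1]][2])
  el <- do.call(rbind, lapply(hdr[-1], function(h) {
    p <- strsplit(h, "\t")[[1]]
    data.frame(electrode = as.integer(p[2]), participant = p[3],
               region = p[4], stringsAsFactors = FALSE)
  }))
  sig <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
  dimnames(sig) <- NULL
  structure(list(signal = sig, fs_hz = fs, electrode_meta = el,
                 spike_index = NULL, onset_offset_s = 1),
            class = "raw_recording")
}
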