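# Small fixtures shared across test files; everything generated in code.

tiny_stream <- function(n_types = 30, n_tokens = 80, duration_s = 120,
                        seed = 11) {
  generate_stream(n_types, n_tokens, duration_s, seed = seed)
}

tiny_setup <- function(n_types = 30, embed_dim = 12, n_el = 8,
                       cone = 15, noise_sd = 0, seed = 11, k = 5) {
  st <- tiny_stream(n_types = n_types, n_tokens = n_types * 2 + 20,
                    duration_s = 200, seed = seed)
  tab <- generate_contextual_table(st, embed_dim, cone, seed = seed + 1)
  W <- withr::with_seed(seed + 5, matrix(stats::rnorm(n_el * embed_dim), n_el))
  gt <- ground_truth(W, noise_sd = noise_sd)
  sel <- select_unique_instances(st, seed = seed + 2)
  fs <- make_folds(sel, k = k)
  list(stream = st, table = tab, gt = gt, sel = sel, fs = fs,
       sel_table = tab[sel$row_idx, , drop = FALSE])
}

# Constant-signal recording helper for preprocessing unit tests.
toy_recording <- function(signal, fs_hz = 512) {
  structure(list(signal = signal, fs_hz = fs_hz,
                 electrode_meta = data.frame(
                   electrode = seq_len(nrow(signal)), participant = 1L,
                   region = "IFG"),
                 spike_index = NULL, onset_offset_s = 0),
            class = "raw_recording")
}
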