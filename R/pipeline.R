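#' Default pipeline configuration
#'
#' A plain named list validated by [run_pipeline()]; can also be read from a
#' YAML file (pass the path instead of a list). All seeds are explicit.
#'
#' @param seed master seed; stage seeds are derived deterministically.
#' @param n_types,n_tokens,duration_s,zipf_s,embed_dim,cone_angle_deg
#'   synthetic-data parameters.
#' @param n_electrodes electrode count of the simulated array.
#' @param noise_sd,fs_hz signal parameters.
#' @param lag_start_ms,lag_stop_ms,lag_step_ms,window_ms lag grid.
#' @param k number of cross-validation folds.
#' @param variants encoding variants to run.
#' @param region electrode region filter (`"all"` or a region label such as
#'   `"IFG"`, `"precentral"`, `"postcentral"`).
#' @param n_boot,fdr_q inference parameters.
#' @param use_oracle if `TRUE`, brain embeddings come from the analytic
#'   ground-truth shortcut instead of full signal synthesis + preprocessing
#'   (fast; the default for exploratory runs).
#' @return a named list.
#' @export
pipeline_config <- function(seed = 1L, n_types = 120, n_tokens = 400,
                            duration_s = 600, zipf_s = 1.1, embed_dim = 50,
                            cone_angle_deg = 20, n_electrodes = 20,
                            noise_sd = 0.5, fs_hz = 512,
                            lag_start_ms = -500, lag_stop_ms = 500,
                            lag_step_ms = 100, window_ms = 200, k = 10,
                            variants = c("actual", "nearest", "shuffled"),
                            region = "all", n_boot = 1000, fdr_q = 0.01,
                            use_oracle = TRUE) {
  as.list(environment())
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  defaults <- pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  config <- utils::modifyList(defaults, config)
  if (is.null(config$seed)) stop("config must carry an explicit seed")
  config
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> embed -> fold -> encode -> stats ->
#' report from one configuration, writing each stage's output as TSV into an
#' immutable run directory together with a manifest (configuration, seeds,
#' package version) sufficient to reproduce the run. Deterministic stages
#' reproduce byte-identically for a fixed configuration.
#'
#' @param config a list from [pipeline_config()] (or a YAML file path).
#' @param dir run directory to create (must not already contain a manifest).
#' @return invisibly, a list with the run directory, the `zs_encoding`
#'   object and the significance table.
#' @export
run_pipeline <- function(config = pipeline_config(), dir = tempfile("run")) {
  config <- validate_config(config)
  if (file.exists(file.path(dir, "manifest.yaml")))
    stop("run directory already contains a manifest; runs are immutable")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  sd0 <- config$seed
  stream <- stage("simulate", generate_stream(config$n_types, config$n_tokens,
                                              config$duration_s,
                                              config$zipf_s, seed = sd0))
  table <- stage("simulate",
                 generate_contextual_table(stream, config$embed_dim,
                                           config$cone_angle_deg,
                                           seed = sd0 + 1L))
  gt <- ground_truth(matrix(with_seed(sd0 + 2L,
                                      stats::rnorm(config$n_electrodes *
                                                   config$embed_dim)),
                            config$n_electrodes),
                     noise_sd = config$noise_sd)
  grid <- lag_grid(config$lag_start_ms, config$lag_stop_ms,
                   config$lag_step_ms, config$window_ms)
  sel <- stage("fold", select_unique_instances(stream, seed = sd0 + 3L))
  fs <- stage("fold", make_folds(sel, k = config$k))
  save_stream(stream, file.path(dir, "events.tsv"))
  save_table(table, file.path(dir, "embeddings.tsv"))
  save_folds(fs, file.path(dir, "folds.tsv"))
  sel_table <- table[sel$row_idx, , drop = FALSE]
  el_keep <- seq_len(config$n_electrodes)
  brain <- if (isTRUE(config$use_oracle)) {
    stage("preprocess",
          oracle_brain_embeddings(fs$events, sel_table, gt, grid,
                                  seed = sd0 + 4L))
  } else {
    rec <- stage("simulate", generate_recording(stream, table, gt,
                                                fs_hz = config$fs_hz,
                                                seed = sd0 + 4L))
    if (config$region != "all") {
      el_keep <- which(rec$electrode_meta$region == config$region)
      if (!length(el_keep))
        stop(sprintf("region filter '%s' matches no electrodes",
                     config$region))
      rec$signal <- rec$signal[el_keep, , drop = FALSE]
      rec$electrode_meta <- rec$electrode_meta[el_keep, , drop = FALSE]
    }
    sig <- stage("preprocess", preprocess_recording(rec))
    ep <- stage("preprocess", epoch_lags(sig, fs$events, grid))
    fs$events <- fs$events[ep$kept, , drop = FALSE]
    sel_table <- sel_table[ep$kept, , drop = FALSE]
    ep$embeddings
  }
  enc <- stage("encode", zs_encode(sel_table, brain, fs,
                                   variants = config$variants,
                                   seed = sd0 + 5L))
  save_encoding(enc, file.path(dir, "encoding.tsv"))
  sig_tab <- stage("stats", encoding_significance(enc, n_boot = config$n_boot,
                                                  q = config$fdr_q,
                                                  seed = sd0 + 6L))
  utils::write.table(sig_tab, file.path(dir, "significance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("neuroalign")),
                   r_version = R.version.string,
                   config = config,
                   electrodes_used = length(el_keep),
                   stages = c("simulate", "fold", "preprocess", "encode",
                              "stats"))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(list(dir = dir, encoding = enc, significance = sig_tab))
}

#' Summarise a completed pipeline run
#'
#' Reads the per-lag encoding summary and significance table back from a run
#' directory and returns the merged per-lag report (mean correlation,
#' standard error computed as SD over words divided by sqrt(n), significance
#' flags). Warns and returns partial output when stages are missing.
#'
#' @param dir a run directory produced by [run_pipeline()].
#' @return data.frame: `lag_ms`, `variant`, `mean_r`, `se_r`, `n`,
#'   `significant` (NA for variants without a significance test).
#' @export
pipeline_report <- function(dir) {
  sp <- file.path(dir, "encoding_summary.tsv")
  if (!file.exists(sp)) stop(sprintf("missing encoding summary in %s", dir))
  summ <- utils::read.table(sp, sep = "\t", header = TRUE)
  gp <- file.path(dir, "significance.tsv")
  if (file.exists(gp)) {
    sig <- utils::read.table(gp, sep = "\t", header = TRUE)
    summ$significant <- ifelse(summ$variant == "actual",
                               sig$significant[match(summ$lag_ms, sig$lag_ms)],
                               NA)
  } else {
    warning("incomplete run: no significance table; partial report")
    summ$significant <- NA
  }
  summ
}
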