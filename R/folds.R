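#' Select one occurrence per word type
#'
#' For each distinct word type in the stream, one occurrence is chosen
#' uniformly at random among that type's occurrences; the selected events are
#' returned sorted by onset. This is the zero-shot selection step: downstream
#' folds partition word *types*, so no type can appear on both sides of a
#' train/test split.
#'
#' @param stream a token stream (data.frame with `token`, `onset_s`,
#'   `type_id`).
#' @param seed integer seed.
#' @return data.frame of selected events (one row per type), sorted by onset,
#'   with a `row_idx` column pointing back into the stream.
#' @export
select_unique_instances <- function(stream, seed = 1L) {
  if (!nrow(stream)) stop("empty stream")
  with_seed(seed, {
    picked <- vapply(split(seq_len(nrow(stream)), stream$type_id),
                     function(ix) ix[sample.int(length(ix), 1)],
                     integer(1))
    sel <- stream[picked, , drop = FALSE]
    sel$row_idx <- picked
    sel <- sel[order(sel$onset_s), , drop = FALSE]
    rownames(sel) <- NULL
    as.data.frame(sel)
  })
}

#' Partition selected events into contiguous folds
#'
#' The onset-sorted unique-word events are split into `k` contiguous blocks
#' of near-equal size (any remainder goes to the earliest folds). Because
#' each block is a contiguous stretch of stimulus time, the training set for
#' a middle test fold consists of the two flanking contiguous sections.
#'
#' @param selected output of [select_unique_instances()].
#' @param k number of folds.
#' @return a `fold_spec`: list with `events` (the selected events plus a
#'   `fold` column, 0-based fold index), `k`.
#' @export
make_folds <- function(selected, k = 10) {
  if (k <= 0) stop("k must be positive")
  n <- nrow(selected)
  if (n < k) stop("fewer selected events than folds")
  base <- n %/% k
  sizes <- rep(base, k)
  if (n %% k) sizes[seq_len(n %% k)] <- base + 1
  ev <- selected[order(selected$onset_s), , drop = FALSE]
  ev$fold <- rep(seq_len(k) - 1L, times = sizes)
  rownames(ev) <- NULL
  structure(list(events = ev, k = k), class = "fold_spec")
}

#' Assert the zero-shot property of a fold specification
#'
#' Verifies that every word type occurs in exactly one fold, that folds are
#' contiguous in stimulus time, and that fold sizes differ by at most one.
#' Called by the analysis runners before every fit, not only at construction.
#'
#' @param fs a `fold_spec`.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
assert_zero_shot <- function(fs) {
  ev <- fs$events
  tab <- table(ev$token, ev$fold)
  if (any(rowSums(tab > 0) != 1))
    stop("zero-shot violation: a word type appears in more than one fold")
  ord <- ev$fold[order(ev$onset_s)]
  if (is.unsorted(ord))
    stop("folds are not contiguous in stimulus time")
  sz <- table(ev$fold)
  if (max(sz) - min(sz) > 1) stop("fold sizes differ by more than 1")
  invisible(TRUE)
}

#' Shuffle the embedding assignment of a test fold
#'
#' Replaces the embedding rows of the given test fold by a random permutation
#' of themselves (training rows untouched), breaking the word-to-embedding
#' correspondence while preserving the embedding multiset — the chance-level
#' control. Words are matched with *mismatching* embeddings: permutations
#' with fixed points are rejected (a self-match would leak the true pairing
#' into the control), so for folds of two or more words the permutation is a
#' uniform random derangement; a single-row fold can only map to itself.
#'
#' @param table an [embedding_table()] whose rows align with `fs$events`.
#' @param fs a `fold_spec`.
#' @param fold 0-based fold index to shuffle.
#' @param seed integer seed.
#' @return the permuted `embedding_table`; the permutation applied is
#'   attached as attribute `shuffle_perm`.
#' @export
shuffle_assignment <- function(table, fs, fold, seed = 1L) {
  ix <- which(fs$events$fold == fold)
  if (!length(ix)) stop("fold has no events")
  with_seed(seed, {
    n <- length(ix)
    perm <- sample.int(n)
    if (n > 1) while (any(perm == seq_len(n))) perm <- sample.int(n)
    out <- unclass(table)
    out[ix, ] <- out[ix[perm], , drop = FALSE]
    out <- embedding_table(out, kind = attr(table, "kind"),
                           provenance = attr(table, "provenance"))
    attr(out, "shuffle_perm") <- perm
    out
  })
}

#' Write a fold specification to TSV
#'
#' Columns: token, onset_s, fold.
#' @param fs a `fold_spec`.
#' @param path output path.
#' @export
save_folds <- function(fs, path) {
  utils::write.table(fs$events[, c("token", "onset_s", "fold")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
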