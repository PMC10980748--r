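#' Construct an embedding table
#'
#' A words x dimensions numeric matrix tagged with its family: contextual
#' (per-occurrence vectors from a deep language model), static (one vector
#' per word type), symbolic (binary linguistic features), or pseudo
#' (concatenations of static vectors emulating context). Rows are aligned to
#' the word-event table they were extracted for.
#'
#' @param matrix numeric matrix, words x dimensions.
#' @param kind one of `"contextual"`, `"static"`, `"symbolic"`, `"pseudo"`.
#' @param provenance list of free-form provenance fields (source name,
#'   fold-isolation flag, etc.).
#' @return an `embedding_table` (a numeric matrix with attributes).
#' @export
embedding_table <- function(matrix, kind, provenance = list()) {
  kind <- match.arg(kind, c("contextual", "static", "symbolic", "pseudo"))
  m <- as.matrix(matrix)
  if (anyNA(m)) stop("embedding table must not contain NA")
  if (kind == "symbolic" && !all(m %in% c(0, 1)))
    stop("symbolic embeddings must be binary before reduction")
  structure(m, kind = kind, provenance = provenance,
            class = c("embedding_table", class(m)))
}

#' @export
`[.embedding_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, kind = attr(x, "kind"),
                     provenance = attr(x, "provenance"),
                     class = class(x))
  out
}

#' Reduce an embedding table with PCA
#'
#' Principal axes are fit on `fit_rows` only (leakage-safe by default: pass
#' the training rows of the current cross-validation split, or all rows for a
#' global fit) and all rows are projected onto the leading `n_components`
#' axes, ordered by decreasing explained variance.
#'
#' @param table an [embedding_table()].
#' @param n_components target dimensionality.
#' @param fit_rows integer row indices used to fit the axes (default: all).
#' @return the reduced `embedding_table` (same kind); explained variances are
#'   attached as attribute `explained_variance`.
#' @export
pca_reduce <- function(table, n_components = 50, fit_rows = seq_len(nrow(table))) {
  m <- unclass(table)
  if (n_components > min(ncol(m), length(fit_rows)))
    stop("n_components exceeds min(dim, |fit_rows|)")
  fit <- m[fit_rows, , drop = FALSE]
  pc <- stats::prcomp(fit, center = TRUE, scale. = FALSE)
  rk <- sum(pc$sdev > pc$sdev[1] * 1e-10)
  if (rk < n_components)
    stop(sprintf("fit set has rank %d < n_components = %d", rk, n_components))
  proj <- sweep(m, 2, pc$center) %*% pc$rotation[, seq_len(n_components),
                                                 drop = FALSE]
  out <- embedding_table(proj, kind = attr(table, "kind"),
                         provenance = c(attr(table, "provenance"),
                                        list(pca_components = n_components)))
  attr(out, "explained_variance") <- pc$sdev[seq_len(n_components)]^2
  out
}

#' Default symbolic feature inventory
#'
#' 75 binary features per token: 11 coarse part-of-speech tags, a stopword
#' flag, 16 word-shape classes (case/digit/punctuation patterns; the last is
#' a reserved "other" class), 19 prefixes and 28 suffixes. Group sizes are
#' enforced exactly. Any component can be overridden, e.g. to supply a custom
#' lexicon; a YAML inventory file can be loaded with [yaml::read_yaml()] and
#' spliced in.
#'
#' @param pos_tags,stopword_lexicon,shape_classes,prefix_list,suffix_list
#'   optional overrides for each group.
#' @return a `symbolic_inventory` list.
#' @export
symbolic_inventory <- function(pos_tags = NULL, stopword_lexicon = NULL,
                               shape_classes = NULL, prefix_list = NULL,
                               suffix_list = NULL) {
  pos_tags <- pos_tags %||% c("NOUN", "VERB", "ADJ", "ADV", "PRON", "DET",
                              "ADP", "CONJ", "NUM", "PRT", "X")
  stopword_lexicon <- stopword_lexicon %||% c(
    "a", "an", "the", "and", "or", "but", "if", "then", "so", "of", "at",
    "by", "for", "with", "about", "to", "from", "in", "out", "on", "off",
    "up", "down", "is", "am", "are", "was", "were", "be", "been", "being",
    "have", "has", "had", "do", "does", "did", "i", "you", "he", "she",
    "it", "we", "they", "this", "that", "these", "those", "not", "no",
    "as", "than", "too", "very", "can", "will", "just", "my", "your",
    "his", "her", "its", "our", "their", "what", "which", "who", "whom")
  shape_classes <- shape_classes %||% c(
    "lower", "upper", "title", "mixed", "digits", "lower_digit",
    "upper_digit", "title_digit", "hyphenated", "apostrophe", "punct",
    "single_lower", "single_upper", "short_lower", "long_lower", "other")
  prefix_list <- prefix_list %||% c(
    "un", "re", "in", "im", "dis", "en", "non", "over", "mis", "sub",
    "pre", "inter", "fore", "de", "trans", "super", "semi", "anti", "under")
  suffix_list <- suffix_list %||% c(
    "s", "es", "ed", "ing", "ly", "er", "or", "ion", "tion", "ation",
    "ible", "able", "al", "ial", "y", "ness", "ity", "ment", "ic", "ous",
    "eous", "ious", "en", "ive", "ative", "ful", "less", "est")
  inv <- list(pos_tags = pos_tags, stopword_lexicon = tolower(stopword_lexicon),
              shape_classes = shape_classes, prefix_list = prefix_list,
              suffix_list = suffix_list)
  sizes <- c(length(inv$pos_tags), 1L, length(inv$shape_classes),
             length(inv$prefix_list), length(inv$suffix_list))
  if (!identical(sizes, c(11L, 1L, 16L, 19L, 28L)))
    stop(sprintf("inventory group sizes must be 11/1/16/19/28, got %s",
                 paste(sizes, collapse = "/")))
  structure(inv, class = "symbolic_inventory")
}

# Crude heuristic part-of-speech adapter, used when no tagging column is
# supplied; a real analysis should pass tags from an external tagger.
heuristic_pos <- function(tokens, inv) {
  t <- tolower(tokens)
  tag <- rep("X", length(t))
  tag[grepl("^[0-9]+$", t)] <- "NUM"
  tag[t %in% c("i", "you", "he", "she", "it", "we", "they", "me", "him",
               "her", "us", "them", "who", "whom")] <- "PRON"
  tag[t %in% c("a", "an", "the", "this", "that", "these", "those")] <- "DET"
  tag[t %in% c("in", "on", "at", "by", "for", "with", "from", "to", "of",
               "over", "under")] <- "ADP"
  tag[t %in% c("and", "or", "but", "nor", "so", "yet")] <- "CONJ"
  tag[t %in% c("not", "off", "up", "out")] <- "PRT"
  tag[grepl("ly$", t) & tag == "X"] <- "ADV"
  tag[grepl("(ing|ed|ise|ize|ate)$", t) & tag == "X"] <- "VERB"
  tag[grepl("(ous|ful|ible|able|ive|ic|al)$", t) & tag == "X"] <- "ADJ"
  tag[tag == "X" & grepl("^[a-z']+$", t)] <- "NOUN"
  factor(tag, levels = inv$pos_tags)
}

word_shape <- function(tokens, inv) {
  cls <- vapply(tokens, function(w) {
    has_digit <- grepl("[0-9]", w)
    has_hyph <- grepl("-", w)
    has_apos <- grepl("'", w)
    has_punct <- grepl("[^A-Za-z0-9'-]", w)
    low <- grepl("^[a-z]+$", w)
    upp <- grepl("^[A-Z]+$", w)
    tit <- grepl("^[A-Z][a-z]+$", w)
    n <- nchar(w)
    if (has_punct) "punct"
    else if (has_hyph) "hyphenated"
    else if (has_apos) "apostrophe"
    else if (grepl("^[0-9]+$", w)) "digits"
    else if (has_digit && grepl("^[a-z0-9]+$", w)) "lower_digit"
    else if (has_digit && grepl("^[A-Z0-9]+$", w)) "upper_digit"
    else if (has_digit) "title_digit"
    else if (low && n == 1) "single_lower"
    else if (upp && n == 1) "single_upper"
    else if (low && n <= 3) "short_lower"
    else if (low && n >= 10) "long_lower"
    else if (low) "lower"
    else if (upp) "upper"
    else if (tit) "title"
    else if (grepl("^[A-Za-z]+$", w)) "mixed"
    else "other"
  }, character(1))
  unknown <- !(cls %in% inv$shape_classes)
  if (any(unknown)) {
    message(sprintf("%d token(s) assigned to the reserved 'other' shape class",
                    sum(unknown)))
    cls[unknown] <- "other"
  }
  factor(cls, levels = inv$shape_classes)
}

#' Build 75-dimensional symbolic (binary) embeddings
#'
#' Per token: one-hot part of speech (11), a stopword flag (1), one-hot word
#' shape (16), and multi-hot prefix (19) and suffix (28) matches, giving 75
#' binary features.
#'
#' @param tokens character vector of token strings.
#' @param inv a [symbolic_inventory()].
#' @param pos optional character vector of part-of-speech tags aligned to
#'   `tokens` (levels must be the inventory's tags); if missing, a built-in
#'   heuristic tagger is used.
#' @return an [embedding_table()] of kind `"symbolic"`, 75 columns.
#' @export
build_symbolic <- function(tokens, inv = symbolic_inventory(), pos = NULL) {
  n <- length(tokens)
  pos <- if (is.null(pos)) heuristic_pos(tokens, inv)
         else factor(pos, levels = inv$pos_tags)
  if (anyNA(pos)) stop("pos tags outside the inventory")
  low <- tolower(tokens)
  m <- matrix(0, n, 75)
  m[cbind(seq_len(n), as.integer(pos))] <- 1
  m[, 12] <- as.numeric(low %in% inv$stopword_lexicon)
  shp <- word_shape(tokens, inv)
  m[cbind(seq_len(n), 12L + as.integer(shp))] <- 1
  for (j in seq_along(inv$prefix_list))
    m[, 28L + j] <- as.numeric(startsWith(low, inv$prefix_list[j]))
  for (j in seq_along(inv$suffix_list))
    m[, 47L + j] <- as.numeric(endsWith(low, inv$suffix_list[j]))
  colnames(m) <- c(paste0("pos_", inv$pos_tags), "stopword",
                   paste0("shape_", inv$shape_classes),
                   paste0("pre_", inv$prefix_list),
                   paste0("suf_", inv$suffix_list))
  embedding_table(m, kind = "symbolic",
                  provenance = list(source = "symbolic-inventory"))
}

#' Append the symbolic features of the preceding words
#'
#' Each row is concatenated with the rows of the `n_prev` preceding tokens
#' (zero-padded at the start of the stream), so a 75-dim table becomes
#' 75 * (1 + n_prev) dimensional.
#'
#' @param table a symbolic [embedding_table()].
#' @param n_prev number of preceding tokens to splice in.
#' @return the widened symbolic `embedding_table`.
#' @export
add_symbolic_context <- function(table, n_prev = 3) {
  if (attr(table, "kind") != "symbolic")
    stop("add_symbolic_context expects a symbolic table")
  m <- unclass(table)
  out <- m
  for (p in seq_len(n_prev)) {
    shifted <- rbind(matrix(0, p, ncol(m)),
                     m[seq_len(nrow(m) - p), , drop = FALSE])
    out <- cbind(out, shifted)
  }
  embedding_table(out, kind = "symbolic",
                  provenance = c(attr(table, "provenance"),
                                 list(context_words = n_prev)))
}

#' Build pseudo-contextual embeddings from static vectors
#'
#' Concatenates the static embeddings of the `history` previous words to each
#' word's own static embedding (zero-padded at the stream start), yielding a
#' context-carrying baseline that is not induced by a language model.
#'
#' @param static_table an [embedding_table()] of kind `"static"`.
#' @param history number of previous words (default 10, giving dimension
#'   `(history + 1) * static_dim`).
#' @return an `embedding_table` of kind `"pseudo"` (or the input unchanged
#'   when `history = 0`).
#' @export
build_pseudo_contextual <- function(static_table, history = 10) {
  if (attr(static_table, "kind") != "static")
    stop("build_pseudo_contextual expects a static table")
  if (history == 0) return(static_table)
  m <- unclass(static_table)
  parts <- lapply(rev(seq_len(history)), function(p)
    rbind(matrix(0, p, ncol(m)), m[seq_len(nrow(m) - p), , drop = FALSE]))
  out <- do.call(cbind, c(parts, list(m)))
  embedding_table(out, kind = "pseudo",
                  provenance = c(attr(static_table, "provenance"),
                                 list(history = history)))
}

#' Collapse a contextual table to its per-type means (static baseline)
#'
#' One vector per word type (the mean of its occurrences, re-normalised to
#' unit length), broadcast back to every occurrence — the static-embedding
#' limit of a contextual table.
#'
#' @param table a contextual [embedding_table()].
#' @param type_id integer vector of type ids aligned to the rows.
#' @return an `embedding_table` of kind `"static"`.
#' @export
collapse_to_static <- function(table, type_id) {
  m <- unclass(table)
  means <- rowsum(m, type_id) / as.vector(table(type_id))
  means <- unit_rows(means)
  embedding_table(means[match(type_id, sort(unique(type_id))), , drop = FALSE],
                  kind = "static",
                  provenance = c(attr(table, "provenance"),
                                 list(collapsed = TRUE)))
}

#' Save / load an embedding table as TSV
#'
#' The table is written with a header row of dimension names, preceded by
#' commented metadata lines carrying the kind. The round trip is lossless.
#'
#' @param table an [embedding_table()].
#' @param path file path.
#' @param kind expected kind on load (checked against the file).
#' @param n_events optional event count to validate row alignment on load.
#' @export
save_table <- function(table, path) {
  m <- unclass(table)
  if (is.null(colnames(m))) colnames(m) <- paste0("d", seq_len(ncol(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind\t%s", attr(table, "kind")), con)
  utils::write.table(m, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname save_table
#' @export
load_table <- function(path, kind = NULL, n_events = NULL) {
  first <- readLines(path, n = 1)
  file_kind <- if (startsWith(first, "# kind")) strsplit(first, "\t")[[1]][2]
               else NULL
  kind <- kind %||% file_kind %||% stop("kind not stored in file and not supplied")
  if (!is.null(file_kind) && !identical(kind, file_kind))
    stop(sprintf("file stores kind '%s' but '%s' requested", file_kind, kind))
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   comment.char = "#", check.names = FALSE))
  if (!is.null(n_events) && nrow(m) != n_events)
    stop(sprintf("table has %d rows but %d events expected", nrow(m), n_events))
  embedding_table(m, kind = kind, provenance = list(source = path))
}
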