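#' Construct a path corpus
#'
#' A corpus is a list of raw (un-augmented) paths over a shared vocabulary.
#' Every symbol of every path must be a vocabulary label; the RESET symbol
#' never occurs inside raw paths.
#'
#' @param paths List of character vectors, one per path.
#' @param vocabulary A [state_vocabulary()]. If `NULL`, built from the union
#'   of path symbols in first-seen order.
#' @param meta Named list of free-form provenance notes.
#'
#' @return An object of class `path_corpus` with fields `paths`,
#'   `vocabulary`, `meta`.
#' @export
path_corpus <- function(paths, vocabulary = NULL, meta = list()) {
  if (!is.list(paths) || length(paths) < 1L) {
    stop("empty corpus")
  }
  paths <- lapply(paths, as.character)
  if (any(lengths(paths) == 0L)) stop("zero-length path in corpus")
  if (is.null(vocabulary)) {
    seen <- unique(unlist(paths, use.names = FALSE))
    vocabulary <- state_vocabulary(seen)
  } else {
    stopifnot(inherits(vocabulary, "state_vocabulary"))
    syms <- unique(unlist(paths, use.names = FALSE))
    if (vocabulary$reset_label %in% syms) {
      stop("reserved label in data: ", vocabulary$reset_label)
    }
    unknown <- setdiff(syms, vocabulary$labels)
    if (length(unknown)) {
      stop("path symbols outside vocabulary: ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(list(paths = paths, vocabulary = vocabulary, meta = meta),
            class = "path_corpus")
}

#' @export
print.path_corpus <- function(x, ...) {
  s <- corpus_stats(x)
  cat("<path_corpus> ", s$n_paths, " paths, ", s$n_clicks, " clicks, ",
      s$n_labels, " labels (+RESET)\n", sep = "")
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, paste,
        collapse = " ")), sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Corpus summary statistics
#'
#' Path count, total click (node-visit) count and alphabet size, the
#' quantities conventionally tabulated for navigation datasets.
#'
#' @param corpus A [path_corpus()].
#' @return A list with `n_paths`, `n_clicks` (sum of path lengths) and
#'   `n_labels` (data labels, excluding RESET).
#' @export
corpus_stats <- function(corpus) {
  stopifnot(inherits(corpus, "path_corpus"))
  list(n_paths = length(corpus$paths),
       n_clicks = sum(lengths(corpus$paths)),
       n_labels = length(corpus$vocabulary$labels))
}

#' Read a delimited path file
#'
#' One path per line, tokens separated by a single-character delimiter.
#' Blank lines are ignored.  Tokens are opaque labels; the vocabulary is the
#' union of tokens in first-seen order plus a RESET symbol guaranteed not to
#' collide.
#'
#' @param file Path to a UTF-8 text file.
#' @param delimiter Single-character token separator (default tab).
#' @param reset_label Explicit RESET label, or `NULL` to auto-generate a
#'   non-colliding one.  An explicit label occurring in the data is an error.
#' @return A [path_corpus()].
#' @export
read_paths <- function(file, delimiter = "\t", reset_label = NULL) {
  stopifnot(is.character(delimiter), nchar(delimiter) == 1L)
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty corpus")
  paths <- strsplit(lines, delimiter, fixed = TRUE)
  paths <- lapply(paths, function(p) p[nzchar(p)])
  if (any(lengths(paths) == 0L)) stop("line with no tokens")
  seen <- unique(unlist(paths, use.names = FALSE))
  if (!is.null(reset_label) && reset_label %in% seen) {
    stop("reserved label in data: ", reset_label)
  }
  vocab <- state_vocabulary(seen, reset_label)
  path_corpus(paths, vocab,
              meta = list(source = file, format = "plain",
                          delimiter = delimiter))
}

#' Write a corpus in the delimited path format
#'
#' Inverse of [read_paths()]: one path per line, tokens joined by
#' `delimiter`.  Round-trips corpora exactly.
#'
#' @inheritParams read_paths
#' @param corpus A [path_corpus()].
#' @return `file`, invisibly.
#' @export
write_paths <- function(corpus, file, delimiter = "\t") {
  stopifnot(inherits(corpus, "path_corpus"),
            is.character(delimiter), nchar(delimiter) == 1L)
  lines <- vapply(corpus$paths, paste, character(1), collapse = delimiter)
  writeLines(lines, file, useBytes = TRUE)
  invisible(file)
}

#' Read a UCI MSNBC-style sequence file
#'
#' The published dialect: `%`-prefixed comment lines, one legend line naming
#' the categories in order, then one space-separated sequence of 1-based
#' category indices per line (one user session per line).  Indices are
#' decoded to category names; no filtering is applied here.
#'
#' @param file Path to the sequence file.
#' @return A [path_corpus()] of decoded sessions.
#' @export
read_msnbc <- function(file) {
  lines <- readLines(file, warn = FALSE)
  body <- grep("^\\s*%", lines, invert = TRUE)
  body <- body[nzchar(trimws(lines[body]))]
  if (length(body) == 0L) stop("missing legend line")
  legend <- strsplit(trimws(lines[body[1L]]), "\\s+")[[1L]]
  if (length(legend) < 1L || any(grepl("^[0-9]+$", legend))) {
    stop("missing legend: first non-comment line must name the categories")
  }
  session_lines <- body[-1L]
  if (length(session_lines) == 0L) stop("empty corpus")
  paths <- vector("list", length(session_lines))
  for (i in seq_along(session_lines)) {
    ln <- session_lines[i]
    toks <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    idx <- suppressWarnings(as.integer(toks))
    if (anyNA(idx)) stop("non-integer token on line ", ln)
    if (any(idx < 1L | idx > length(legend))) {
      stop("category index out of legend range on line ", ln)
    }
    paths[[i]] <- legend[idx]
  }
  vocab <- state_vocabulary(legend)
  path_corpus(paths, vocab, meta = list(source = file, format = "msnbc"))
}

#' Keep only paths of a minimum length
#'
#' Single-click sessions carry no transition information beyond start/stop,
#' so corpora are conventionally restricted to paths with at least two
#' nodes.  The length is the node count (tuple length) of the raw path.
#'
#' @param corpus A [path_corpus()].
#' @param min_len Minimum node count to retain (default 2).
#' @return The filtered corpus; vocabulary unchanged, filter recorded in
#'   `meta`.
#' @export
filter_min_length <- function(corpus, min_len = 2L) {
  stopifnot(inherits(corpus, "path_corpus"), min_len >= 1L)
  keep <- lengths(corpus$paths) >= min_len
  if (!any(keep)) stop("empty corpus after filtering")
  meta <- corpus$meta
  meta$min_len <- min_len
  path_corpus(corpus$paths[keep], corpus$vocabulary, meta)
}

#' Relabel a corpus into categories
#'
#' Replaces every occurrence of each label by its mapped category.  When a
#' label maps to several equally ranked categories, one is drawn uniformly
#' at random under `seed` -- the draw is fixed per label (every occurrence of
#' that label gets the same category), and is independent of the order in
#' which labels appear in the mapping or the corpus.
#'
#' @param corpus A [path_corpus()].
#' @param mapping Named list: label -> character vector of one or more
#'   candidate categories; or a two-column data.frame (label, category) with
#'   repeated label rows for ties.
#' @param seed Integer seed for the tie-break draws.
#' @return A relabelled [path_corpus()] over the category vocabulary.
#' @export
relabel <- function(corpus, mapping, seed = 1L) {
  stopifnot(inherits(corpus, "path_corpus"))
  if (is.data.frame(mapping)) {
    stopifnot(ncol(mapping) >= 2L)
    mapping <- split(as.character(mapping[[2L]]),
                     as.character(mapping[[1L]]))
  }
  stopifnot(is.list(mapping), !is.null(names(mapping)))
  labs <- corpus$vocabulary$labels
  missing_labs <- setdiff(labs, names(mapping))
  if (length(missing_labs)) {
    stop("unmapped label(s): ", paste(missing_labs, collapse = ", "))
  }
  # deterministic per label: draw in sorted-label order under the seed
  ord <- sort(labs)
  chosen <- character(length(ord))
  names(chosen) <- ord
  withr::with_seed(seed, {
    for (lb in ord) {
      cands <- unique(as.character(mapping[[lb]]))
      if (length(cands) == 0L) stop("unmapped label(s): ", lb)
      chosen[lb] <- if (length(cands) == 1L) cands else
        cands[sample.int(length(cands), 1L)]
    }
  })
  new_paths <- lapply(corpus$paths, function(p) unname(chosen[p]))
  cats <- unique(unname(chosen))
  meta <- corpus$meta
  meta$relabeled <- TRUE
  meta$relabel_seed <- seed
  path_corpus(new_paths, state_vocabulary(cats), meta)
}
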