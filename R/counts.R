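#' Order-k transition counts from RESET-augmented paths
#'
#' Each path of length L is independently augmented to
#' `(RESET x k, path, RESET)` and all L+1 sliding windows (history of k
#' symbols, next symbol) within the augmented path are counted.  Windows
#' never span two paths, so histories cannot leak across path boundaries
#' and no artificial RESET-to-RESET transitions arise between consecutive
#' paths.  The total transition count is therefore
#' `N = sum over paths of (L + 1)` for every order.
#'
#' Histories are stored as dense base-m integer codes (see
#' [decode_history()]); counts are a sparse `data.table` over observed
#' (history, target) cells only.
#'
#' @param corpus A [path_corpus()].
#' @param order Markov order k >= 0.  For k = 0 there is a single empty
#'   history and the counts are the marginal next-state counts (including
#'   the terminal RESET of every path).
#' @return An object of class `transition_counts` with fields `order`,
#'   `vocabulary`, `dt` (columns `h` history code, `j` target index, `n`
#'   count), and `N` (total transitions).
#' @export
#' @examples
#' co <- path_corpus(list(c("a", "b")))
#' augment_and_count(co, 1L)  # RESET->a, a->b, b->RESET, N = 3
augment_and_count <- function(corpus, order) {
  stopifnot(inherits(corpus, "path_corpus"))
  if (length(order) != 1L || is.na(order) || order < 0 ||
      order != floor(order)) {
    stop("order must be a non-negative integer")
  }
  k <- as.integer(order)
  vocab <- corpus$vocabulary
  m <- vocab$m
  if (k > 0 && m^k > 2^52) stop("history space m^k exceeds exact range")
  ipaths <- lapply(corpus$paths, function(p) match(p, vocab$labels))
  lens <- lengths(ipaths)
  aug <- lapply(ipaths, function(ip) c(rep.int(m, k), ip, m))
  v <- unlist(aug, use.names = FALSE)
  alen <- lens + k + 1L
  offsets <- cumsum(c(0L, head(alen, -1L)))
  # valid window start positions (1-based within the concatenation)
  starts <- sequence(lens + 1L) + rep(offsets, lens + 1L)
  hcode <- numeric(length(starts))
  if (k > 0) {
    for (d in seq_len(k)) {
      hcode <- hcode * m + (v[starts + d - 1L] - 1)
    }
  }
  tgt <- v[starts + k]
  dt <- data.table(h = hcode, j = tgt)[, .(n = .N), by = .(h, j)]
  setkey(dt, h, j)
  structure(list(order = k, vocabulary = vocab, dt = dt,
                 N = length(starts)),
            class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, ...) {
  cat("<transition_counts> order ", x$order, ", ",
      length(unique(x$dt$h)), " observed histories, ",
      nrow(x$dt), " cells, N = ", x$N, "\n", sep = "")
  invisible(x)
}

#' Encode a label history to its internal code
#'
#' Histories of k labels (oldest first) are stored as base-m codes in
#' `0 .. m^k - 1`, with data labels mapping to digits `0 .. m-2` in
#' vocabulary order and RESET to digit `m - 1`.
#'
#' @param vocab A [state_vocabulary()].
#' @param history Character vector of k labels (oldest first); `character(0)`
#'   for the order-0 empty history.
#' @return A length-1 numeric code.
#' @export
encode_history <- function(vocab, history) {
  if (length(history) == 0L) return(0)
  idx <- vocab_index(vocab, history)
  code <- 0
  for (d in seq_along(idx)) code <- code * vocab$m + (idx[d] - 1)
  code
}

#' Decode internal history codes to label tuples
#'
#' @param vocab A [state_vocabulary()].
#' @param codes Numeric history codes.
#' @param order History length k.
#' @param sep Separator used to join labels (default `","`).
#' @return Character vector of joined label tuples (`""` for order 0).
#' @export
decode_history <- function(vocab, codes, order, sep = ",") {
  if (order == 0L) return(rep("", length(codes)))
  m <- vocab$m
  states <- vocab_states(vocab)
  digits <- matrix("", nrow = length(codes), ncol = order)
  rem <- codes
  for (d in order:1) {
    digits[, d] <- states[rem %% m + 1]
    rem <- rem %/% m
  }
  apply(digits, 1L, paste, collapse = sep)
}

#' Export transition counts as a labelled integer table
#'
#' @param counts A [augment_and_count()] result.
#' @param sep Separator for history labels.
#' @return A `data.frame` with columns `history`, `target`, `n`.
#' @export
counts_table <- function(counts, sep = ",") {
  stopifnot(inherits(counts, "transition_counts"))
  vocab <- counts$vocabulary
  data.frame(
    history = decode_history(vocab, counts$dt$h, counts$order, sep),
    target = vocab_states(vocab)[counts$dt$j],
    n = counts$dt$n,
    stringsAsFactors = FALSE
  )
}

#' Write / read transition counts as TSV
#'
#' Integer-exact round trip of the sparse count table.  The header records
#' the order, the RESET label and the vocabulary so the object can be
#' reconstructed bit-exactly.
#'
#' @param counts A `transition_counts` object.
#' @param file Output path.
#' @param corpus_vocab For [read_counts_tsv()]: ignored, vocabulary is
#'   recovered from the file header.
#' @return `file` invisibly; for the reader, a `transition_counts`.
#' @export
write_counts_tsv <- function(counts, file) {
  stopifnot(inherits(counts, "transition_counts"))
  vocab <- counts$vocabulary
  hdr <- c(
    paste0("# order\t", counts$order),
    paste0("# reset\t", vocab$reset_label),
    paste0("# labels\t", paste(vocab$labels, collapse = "\t"))
  )
  tab <- counts_table(counts, sep = "\x1f")
  body <- paste(tab$history, tab$target, tab$n, sep = "\t")
  writeLines(c(hdr, "history\ttarget\tn", body), file, useBytes = TRUE)
  invisible(file)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(file) {
  lines <- readLines(file, warn = FALSE)
  hdr <- grep("^# ", lines, value = TRUE)
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, "\t"))]
    strsplit(sub(paste0("^# ", key, "\t"), "", ln), "\t", fixed = TRUE)[[1L]]
  }
  k <- as.integer(get("order"))
  vocab <- state_vocabulary(get("labels"), get("reset"))
  body <- lines[!grepl("^#", lines)]
  body <- body[-1L]  # column header
  parts <- strsplit(body, "\t", fixed = TRUE)
  hist_lab <- vapply(parts, `[`, character(1), 1L)
  target <- vapply(parts, `[`, character(1), 2L)
  n <- as.integer(vapply(parts, `[`, character(1), 3L))
  hcodes <- if (k == 0L) rep(0, length(body)) else
    vapply(strsplit(hist_lab, "\x1f", fixed = TRUE),
           function(hh) encode_history(vocab, hh), numeric(1))
  dt <- data.table(h = hcodes, j = vocab_index(vocab, target), n = n)
  setkey(dt, h, j)
  structure(list(order = k, vocabulary = vocab, dt = dt, N = sum(n)),
            class = "transition_counts")
}
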