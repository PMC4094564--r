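#' Globally normalised transition table
#'
#' Instead of normalising each row to a conditional distribution, every
#' cell is divided by the grand total of transitions, so the table shows
#' where the mass of the whole corpus lies (the heatmap view of global
#' structure).  Cells sum to 1; RESET rows and columns are included.
#'
#' @param counts A `transition_counts` with `order >= 1` and `N > 0`.
#' @param sep Separator for history row labels.
#' @return An object of class `global_transition_table`: the labelled
#'   numeric matrix (histories x states) with attribute `N`.
#' @export
global_transition_table <- function(counts, sep = ",") {
  stopifnot(inherits(counts, "transition_counts"))
  if (counts$order < 1L) stop("global table requires order >= 1")
  if (counts$N == 0) stop("no transitions")
  vocab <- counts$vocabulary
  codes <- sort(unique(counts$dt$h))
  out <- matrix(0, nrow = length(codes), ncol = vocab$m,
                dimnames = list(decode_history(vocab, codes, counts$order,
                                               sep),
                                vocab_states(vocab)))
  out[cbind(match(counts$dt$h, codes), counts$dt$j)] <-
    counts$dt$n / counts$N
  structure(out, N = counts$N, order = counts$order,
            class = c("global_transition_table", "matrix", "array"))
}

#' Top outgoing transitions of a history
#'
#' The `top_n` most probable next states from a given history, with their
#' transition probabilities, ties broken by vocabulary label order.  The
#' canonical edge-list export behind the local-structure graphs.
#'
#' @param model A `markov_model`.
#' @param history Character vector of `model$order` labels (oldest first).
#' @param top_n Number of edges to return (clipped to m).
#' @param sep Separator for the history column.
#' @return A `data.frame` with columns `history`, `target`, `prob`, sorted
#'   by decreasing probability.
#' @export
top_transitions <- function(model, history, top_n = 4L, sep = ",") {
  stopifnot(inherits(model, "markov_model"), top_n >= 1L)
  row <- predict_row(model, history)
  states <- names(row)
  ord <- order(-row, seq_along(row))
  n_take <- min(top_n, length(row))
  take <- ord[seq_len(n_take)]
  data.frame(history = paste(history, collapse = sep),
             target = states[take], prob = unname(row[take]),
             stringsAsFactors = FALSE)
}

#' Self-transition profile by conditioning order
#'
#' For each category c and order k, the probability of staying in c given
#' a history of k consecutive occurrences of c:
#' `stay(c, k) = n(c^k -> c) / sum_j n(c^k -> j)` from the order-k counts.
#' Rising stay probabilities with k indicate topical "stickiness" --
#' the longer a user has already stayed, the likelier one more step in the
#' same category.  RESET is excluded (its runs are structural).  Both raw
#' counts and normalised probabilities are reported; unobserved histories
#' yield `NA`.
#'
#' @param corpus A [path_corpus()].
#' @param categories Categories to profile (default: all data labels).
#' @param k_range Orders to evaluate (default `1:3`).
#' @return A `data.frame` with columns `category`, `order`, `n_stay`,
#'   `n_switch`, `n_total`, `p_stay`, `p_switch`.
#' @export
self_transition_profile <- function(corpus, categories = NULL,
                                    k_range = 1:3) {
  stopifnot(inherits(corpus, "path_corpus"), all(k_range >= 1L))
  vocab <- corpus$vocabulary
  if (is.null(categories)) categories <- vocab$labels
  stopifnot(all(categories %in% vocab$labels))
  res <- vector("list", length(k_range) * length(categories))
  i <- 0L
  for (k in sort(unique(k_range))) {
    cnt <- augment_and_count(corpus, k)
    for (cc in categories) {
      code <- encode_history(vocab, rep(cc, k))
      cells <- cnt$dt[.(code), on = "h", nomatch = NULL]
      n_total <- sum(cells$n)
      jj <- vocab_index(vocab, cc)
      n_stay <- if (nrow(cells)) sum(cells$n[cells$j == jj]) else 0L
      i <- i + 1L
      res[[i]] <- data.frame(
        category = cc, order = k, n_stay = n_stay,
        n_switch = n_total - n_stay, n_total = n_total,
        p_stay = if (n_total > 0) n_stay / n_total else NA_real_,
        p_switch = if (n_total > 0) 1 - n_stay / n_total else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, res)
}

#' Split a corpus by path endpoints
#'
#' Partitions the corpus into paths whose first and last states coincide
#' (`same`) and paths with distinct endpoints (`different`).  Both parts
#' retain the full vocabulary, so their transition tables are directly
#' comparable -- the robustness check that endpoint placement does not
#' drive structural conclusions.
#'
#' @param corpus A [path_corpus()].
#' @return A list of two [path_corpus()] objects, `same` and `different`;
#'   either may have zero paths, in which case it is `NULL`.
#' @export
split_by_endpoints <- function(corpus) {
  stopifnot(inherits(corpus, "path_corpus"))
  is_same <- vapply(corpus$paths,
                    function(p) p[1L] == p[length(p)], logical(1))
  mk <- function(keep, tag) {
    if (!any(keep)) return(NULL)
    meta <- corpus$meta
    meta$endpoint_split <- tag
    path_corpus(corpus$paths[keep], corpus$vocabulary, meta)
  }
  list(same = mk(is_same, "same"), different = mk(!is_same, "different"))
}
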