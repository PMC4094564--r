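#' Stratified fold assignment by whole paths
#'
#' Paths are shuffled under the seed and then greedily assigned, one by
#' one, to the currently lightest fold by click weight (path length + 1,
#' the number of transitions each path contributes at any order).  Whole
#' paths are never split across folds -- splitting a path's transitions
#' between train and test would leak its history -- so each fold holds
#' approximately a 1/n_folds share of all clicks, up to the granularity of
#' a single path.
#'
#' @param corpus A [path_corpus()] with at least `n_folds` paths.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed for the shuffle.
#' @return An object of class `fold_assignment`: list with `fold`
#'   (integer per path), `n_folds`, `fold_weights` (clicks per fold),
#'   `seed`.
#' @export
make_stratified_folds <- function(corpus, n_folds = 10L, seed = 1L) {
  stopifnot(inherits(corpus, "path_corpus"), n_folds >= 2L)
  np <- length(corpus$paths)
  if (np < n_folds) stop("fewer paths than folds")
  w <- lengths(corpus$paths) + 1
  fold <- integer(np)
  withr::with_seed(seed, {
    ord <- sample.int(np)
    totals <- numeric(n_folds)
    for (i in ord) {
      f <- which.min(totals)
      fold[i] <- f
      totals[f] <- totals[f] + w[i]
    }
  })
  structure(list(fold = fold, n_folds = as.integer(n_folds),
                 fold_weights = totals, seed = seed),
            class = "fold_assignment")
}

#' Modified competition ranking of a probability row
#'
#' Descending ranks where every member of a tie group receives the group's
#' worst (maximum) rank -- the "14445" scheme: gaps are left before a set
#' of ties.  This deliberately penalises the many ties produced by sparse
#' high-order rows.
#'
#' @param row Numeric vector of finite, non-negative scores
#'   (probabilities).
#' @return Integer vector of ranks in `1..length(row)`.
#' @export
#' @examples
#' ranks_with_ties(c(0.4, 0.2, 0.2, 0.2, 0.1))  # 1 4 4 4 5
ranks_with_ties <- function(row) {
  if (any(!is.finite(row)) || any(row < 0)) {
    stop("row must be finite and non-negative")
  }
  rank(-row, ties.method = "max")
}

# Per-cell rank statistics of a posterior-mean model's training rows.
# For scalar alpha the posterior ordering within a row equals the count
# ordering, and all unobserved targets tie at the smoothed floor below
# every observed one. Returns the model dt with columns r (modified
# competition rank among all m states) and g (tie-group size).
model_cell_ranks <- function(model) {
  if (model$estimator_tag != "posterior_mean" ||
      length(model$alpha) != 1L) {
    stop("rank evaluation requires a posterior-mean model with scalar alpha")
  }
  dt <- copy(model$dt)
  dt[, r := rank(-n, ties.method = "max"), by = h]
  dt[, g := .N, by = .(h, n)]
  dt
}

#' Average prediction rank of held-out transitions
#'
#' For every held-out transition (history i, true next state j), the rank
#' of j in the model's predicted row under modified competition ranking is
#' averaged, weighted by the held-out counts.  Any cell unobserved in
#' training -- an unseen target in a seen row, or an entirely unseen
#' history -- sits at the smoothed probability floor and receives the
#' maximum rank m (the number of states), the natural Occam penalty that
#' makes sparse high-order models pay for their ties.
#'
#' @param model A posterior-mean `markov_model` with scalar alpha.
#' @param test_counts Held-out `transition_counts` of the same order.
#' @param include_reset Score transitions into RESET (path endings)?
#'   Default `TRUE`: they are counted, predictable events.
#' @return The average rank, a scalar in `[1, m]`.
#' @export
average_rank <- function(model, test_counts, include_reset = TRUE) {
  stopifnot(inherits(model, "markov_model"),
            inherits(test_counts, "transition_counts"))
  if (model$order != test_counts$order) stop("order mismatch")
  m <- model$vocabulary$m
  test <- test_counts$dt
  if (!include_reset) test <- test[j != m]
  if (nrow(test) == 0L) stop("no test transitions to score")
  ranks <- model_cell_ranks(model)
  joined <- ranks[test, on = c("h", "j")]
  rr <- joined$r
  rr[is.na(rr)] <- m
  sum(joined$i.n * rr) / sum(joined$i.n)
}

#' Top-K hit rate of held-out transitions
#'
#' Fraction of held-out transitions whose true next state lies among K
#' states taken from the model's sorted row.  When a tie group straddles
#' the K boundary, the occupants of the remaining slots are drawn
#' uniformly from the tie group per test transition (seeded), so a true
#' state in a straddling group of size g with s free slots is included
#' with probability s/g.
#'
#' @inheritParams average_rank
#' @param K Number of predicted states, `1 <= K <= m` (default 5).
#' @param seed Integer seed for tie draws, or `NULL` to use the current
#'   RNG stream.
#' @return The hit rate, a scalar in `[0, 1]`.
#' @export
topk_hit_rate <- function(model, test_counts, K = 5L, seed = NULL,
                          include_reset = TRUE) {
  stopifnot(inherits(model, "markov_model"),
            inherits(test_counts, "transition_counts"))
  if (model$order != test_counts$order) stop("order mismatch")
  m <- model$vocabulary$m
  if (K < 1L || K > m) stop("K out of range")
  test <- test_counts$dt
  if (!include_reset) test <- test[j != m]
  if (nrow(test) == 0L) stop("no test transitions to score")
  ranks <- model_cell_ranks(model)
  n_pos <- ranks[, .(npos = .N, Ni = Ni[1L]), keyby = h]
  joined <- ranks[test, on = c("h", "j")]
  npos <- n_pos[.(joined$h), on = "h"]$npos
  npos[is.na(npos)] <- 0L
  # b = states strictly ahead of the true state's tie group, g = group size
  bb <- joined$r - joined$g
  gg <- joined$g
  unseen <- is.na(joined$r)
  bb[unseen] <- npos[unseen]        # zero cells rank below all positives
  gg[unseen] <- m - npos[unseen]
  n_tr <- joined$i.n
  draw <- function() {
    hits <- numeric(nrow(joined))
    sure <- (bb + gg) <= K          # whole tie group fits
    never <- bb >= K                # group starts beyond the boundary
    hits[sure] <- n_tr[sure]
    straddle <- which(!sure & !never)
    if (length(straddle)) {
      p_in <- (K - bb[straddle]) / gg[straddle]
      hits[straddle] <- rbinom(length(straddle), n_tr[straddle], p_in)
    }
    sum(hits) / sum(n_tr)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Cross-validated order evaluation by prediction rank
#'
#' Stratified n-fold cross-validation of each candidate order: for every
#' fold, posterior-mean models of orders `0 .. k_max` are trained on the
#' remaining folds and the held-out fold's transitions are scored by
#' [average_rank()] (and optionally [topk_hit_rate()]).  The order with
#' the lowest mean average rank is suggested.
#'
#' @param corpus A [path_corpus()].
#' @param k_max Largest candidate order.
#' @param alpha Scalar Dirichlet pseudo-count for smoothing (default 1).
#' @param n_folds Number of folds (default 10).
#' @param seed Master seed; derives the fold shuffle and all tie draws.
#' @param topk If non-`NULL`, also compute the Top-K hit rate with this K.
#' @param include_reset Score transitions into RESET? Default `TRUE`.
#' @return An object of class `cv_result`: list with `rank` (matrix,
#'   orders x folds), `mean_rank`, `sd_rank`, optional `topk` matrix and
#'   `mean_topk`, `selected` (order with minimum mean rank), `n_folds`,
#'   `seed`, `alpha`.
#' @export
cv_order_evaluation <- function(corpus, k_max = 5L, alpha = 1,
                                n_folds = 10L, seed = 1L, topk = NULL,
                                include_reset = TRUE) {
  stopifnot(inherits(corpus, "path_corpus"), k_max >= 0L,
            length(alpha) == 1L, alpha > 0)
  folds <- make_stratified_folds(corpus, n_folds, seed)
  ks <- 0:k_max
  rank_mat <- matrix(NA_real_, nrow = length(ks), ncol = n_folds,
                     dimnames = list(order = ks, fold = seq_len(n_folds)))
  topk_mat <- if (!is.null(topk)) rank_mat else NULL
  vocab <- corpus$vocabulary
  for (i in seq_along(ks)) {
    k <- ks[i]
    # per-fold counts once; training counts = aggregate of the other folds
    fold_counts <- lapply(seq_len(n_folds), function(f) {
      sub <- path_corpus(corpus$paths[folds$fold == f], vocab)
      augment_and_count(sub, k)
    })
    for (f in seq_len(n_folds)) {
      train_dt <- rbindlist(
        lapply(fold_counts[-f], function(cc) cc$dt)
      )[, .(n = sum(n)), by = .(h, j)]
      setkey(train_dt, h, j)
      train <- structure(
        list(order = k, vocabulary = vocab, dt = train_dt,
             N = sum(train_dt$n)),
        class = "transition_counts")
      mod <- posterior_mean_model(train, alpha)
      rank_mat[i, f] <- average_rank(mod, fold_counts[[f]],
                                     include_reset = include_reset)
      if (!is.null(topk)) {
        topk_mat[i, f] <- topk_hit_rate(
          mod, fold_counts[[f]], K = topk,
          seed = seed + 7919L * k + f, include_reset = include_reset)
      }
    }
  }
  mean_rank <- rowMeans(rank_mat)
  out <- list(rank = rank_mat, mean_rank = mean_rank,
              sd_rank = apply(rank_mat, 1L, stats::sd),
              selected = ks[which.min(mean_rank)],
              n_folds = as.integer(n_folds), seed = seed, alpha = alpha)
  if (!is.null(topk)) {
    out$topk <- topk_mat
    out$mean_topk <- rowMeans(topk_mat)
    out$K <- topk
  }
  structure(out, class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$n_folds, "-fold, seed ", x$seed, "\n", sep = "")
  tab <- data.frame(order = as.integer(rownames(x$rank)),
                    mean_rank = x$mean_rank, sd_rank = x$sd_rank)
  if (!is.null(x$mean_topk)) tab[[paste0("top", x$K)]] <- x$mean_topk
  print(tab, row.names = FALSE, digits = 4)
  cat("Selected order (min mean rank):", x$selected, "\n")
  invisible(x)
}
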