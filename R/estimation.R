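#' Maximum-likelihood transition model
#'
#' Row-wise MLE of the order-k transition probabilities:
#' `p(j | i) = n_ij / sum_j n_ij`.  Histories with zero observations are
#' left undefined (absent), so the training-set log-likelihood is always
#' finite; smoothing is exclusively the Bayesian estimator's job
#' ([posterior_mean_model()]).
#'
#' @param counts A [augment_and_count()] result with `N > 0`.
#' @return An object of class `markov_model` with `estimator_tag = "mle"`.
#' @export
mle_estimate <- function(counts) {
  stopifnot(inherits(counts, "transition_counts"))
  if (counts$N <= 0) stop("no transitions to estimate from")
  dt <- copy(counts$dt)
  dt[, Ni := sum(n), by = h]
  structure(list(order = counts$order, vocabulary = counts$vocabulary,
                 dt = dt, alpha = NULL, estimator_tag = "mle"),
            class = "markov_model")
}

#' Dirichlet posterior-mean transition model
#'
#' Conjugate Dirichlet smoothing: with pseudo-counts `alpha` on every cell
#' of the nominal table, the posterior-mean probability is
#' `p(j | i) = (alpha_j + n_ij) / (A + N_i)` where `A = sum_j alpha_j` and
#' `N_i` is the row total.  Histories never observed in training fall back
#' to the prior-mean row `alpha_j / A`.  The scalar default `alpha = 1` is
#' the uniform (Laplace) prior.
#'
#' @param counts A [augment_and_count()] result.
#' @param alpha Positive scalar pseudo-count, or a numeric vector of length
#'   m (one pseudo-count per target state, shared across histories).
#' @return A `markov_model` with `estimator_tag = "posterior_mean"`; every
#'   probability is strictly positive.
#' @export
posterior_mean_model <- function(counts, alpha = 1) {
  stopifnot(inherits(counts, "transition_counts"))
  m <- counts$vocabulary$m
  alpha <- as.numeric(alpha)
  if (!length(alpha) %in% c(1L, m) || any(alpha <= 0) || anyNA(alpha)) {
    stop("alpha must be a positive scalar or length-m positive vector")
  }
  dt <- copy(counts$dt)
  dt[, Ni := sum(n), by = h]
  structure(list(order = counts$order, vocabulary = counts$vocabulary,
                 dt = dt, alpha = alpha,
                 estimator_tag = "posterior_mean"),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat("<markov_model> order ", x$order, ", ", x$estimator_tag,
      if (!is.null(x$alpha)) paste0(" (alpha = ",
        paste(format(x$alpha), collapse = ","), ")"),
      ", ", length(unique(x$dt$h)), " observed histories\n", sep = "")
  invisible(x)
}

# alpha per target state as a length-m vector
alpha_vec <- function(model) {
  m <- model$vocabulary$m
  if (length(model$alpha) == 1L) rep(model$alpha, m) else model$alpha
}

#' Predicted next-state distribution for one history
#'
#' @param model A `markov_model`.
#' @param history Character vector of `model$order` labels (oldest first).
#' @return Named numeric vector of length m over all states (RESET last).
#'   For MLE models an unobserved history is an error.
#' @export
predict_row <- function(model, history) {
  stopifnot(inherits(model, "markov_model"))
  if (length(history) != model$order) {
    stop("history length must equal the model order")
  }
  vocab <- model$vocabulary
  m <- vocab$m
  code <- encode_history(vocab, history)
  cells <- model$dt[.(code), on = "h", nomatch = NULL]
  out <- numeric(m)
  names(out) <- vocab_states(vocab)
  if (model$estimator_tag == "mle") {
    if (nrow(cells) == 0L) {
      stop("history unobserved under MLE; use a posterior-mean model ",
           "for smoothed prediction")
    }
    out[cells$j] <- cells$n / cells$Ni[1L]
  } else {
    av <- alpha_vec(model)
    A <- sum(av)
    Ni <- if (nrow(cells)) cells$Ni[1L] else 0
    out[] <- av / (A + Ni)
    if (nrow(cells)) out[cells$j] <- (av[cells$j] + cells$n) / (A + Ni)
  }
  out
}

#' Dense transition matrix of a model
#'
#' One row per history (observed histories by default; all nominal
#' histories if `histories = "nominal"` and the table is small enough),
#' columns over all m states.
#'
#' @param model A `markov_model`.
#' @param histories `"observed"` (default) or `"nominal"`.
#' @param sep Separator used in history row names.
#' @return Numeric matrix with history row names and state column names.
#' @export
transition_matrix <- function(model, histories = c("observed", "nominal"),
                              sep = ",") {
  histories <- match.arg(histories)
  vocab <- model$vocabulary
  m <- vocab$m
  k <- model$order
  codes <- if (histories == "nominal") {
    if (m^k > 1e6) stop("nominal history space too large to materialise")
    if (model$estimator_tag == "mle") {
      stop("nominal table undefined under MLE; use a posterior-mean model")
    }
    seq_len(m^k) - 1
  } else {
    sort(unique(model$dt$h))
  }
  states <- vocab_states(vocab)
  out <- matrix(0, nrow = length(codes), ncol = m,
                dimnames = list(decode_history(vocab, codes, k, sep),
                                states))
  if (model$estimator_tag == "posterior_mean") {
    av <- alpha_vec(model)
    A <- sum(av)
    rowNi <- model$dt[, .(Ni = Ni[1L]), keyby = h]
    Ni <- rowNi[.(codes), on = "h"]$Ni
    Ni[is.na(Ni)] <- 0
    out <- outer(1 / (A + Ni), av)
    dimnames(out) <- list(decode_history(vocab, codes, k, sep), states)
    cells <- model$dt[.(codes), on = "h", nomatch = NULL]
    ridx <- match(cells$h, codes)
    out[cbind(ridx, cells$j)] <-
      (av[cells$j] + cells$n) / (A + cells$Ni)
  } else {
    cells <- model$dt[.(codes), on = "h", nomatch = NULL]
    ridx <- match(cells$h, codes)
    out[cbind(ridx, cells$j)] <- cells$n / cells$Ni
  }
  out
}

#' Log-likelihood of counts under a model
#'
#' Returns `sum_ij n_ij * log p(j|i)` with `0 * log 0 = 0`.  A positive
#' count on a cell the model assigns probability zero (including, for MLE
#' models, any history absent from training) yields `-Inf`, signalling
#' unexplained transitions rather than an error.
#'
#' @param model A `markov_model`.
#' @param counts A `transition_counts` of the same order.
#' @return A scalar log-likelihood (possibly `-Inf`).
#' @export
log_likelihood <- function(model, counts) {
  stopifnot(inherits(model, "markov_model"),
            inherits(counts, "transition_counts"))
  if (model$order != counts$order) stop("order mismatch")
  test <- counts$dt
  if (nrow(test) == 0L) return(0)
  mod <- model$dt
  joined <- mod[test, on = c("h", "j")]
  # joined: columns h, j, n (model), Ni, i.n (test)
  n_test <- joined$i.n
  if (model$estimator_tag == "mle") {
    p <- joined$n / joined$Ni
    p[is.na(p)] <- 0
  } else {
    av <- alpha_vec(model)
    A <- sum(av)
    rowNi <- mod[, .(Ni = Ni[1L]), keyby = h]
    Ni <- rowNi[.(joined$h), on = "h"]$Ni
    Ni[is.na(Ni)] <- 0
    nmod <- joined$n
    nmod[is.na(nmod)] <- 0
    p <- (av[joined$j] + nmod) / (A + Ni)
  }
  if (any(p == 0 & n_test > 0)) return(-Inf)
  sum(n_test * log(p))
}

#' Dirichlet posterior variance of one transition probability
#'
#' For the cell (history, state) with posterior mean `u`, row pseudo-count
#' total `A` and row data total `N_i`, the posterior variance is
#' `u (1 - u) / (A + N_i + 1)`.
#'
#' @param counts A `transition_counts`.
#' @param alpha Positive scalar or length-m vector of pseudo-counts.
#' @param history Character vector of `counts$order` labels.
#' @param state A single state label (data label or the RESET label).
#' @return The posterior variance (scalar).
#' @export
posterior_variance <- function(counts, alpha, history, state) {
  stopifnot(inherits(counts, "transition_counts"))
  vocab <- counts$vocabulary
  m <- vocab$m
  alpha <- as.numeric(alpha)
  if (!length(alpha) %in% c(1L, m) || any(alpha <= 0)) {
    stop("alpha must be positive")
  }
  av <- if (length(alpha) == 1L) rep(alpha, m) else alpha
  jj <- vocab_index(vocab, state)
  if (length(jj) != 1L) stop("state must be a single label")
  code <- encode_history(vocab, history)
  cells <- counts$dt[.(code), on = "h", nomatch = NULL]
  A <- sum(av)
  Ni <- sum(cells$n)
  nij <- if (nrow(cells)) sum(cells$n[cells$j == jj]) else 0
  u <- (av[jj] + nij) / (A + Ni)
  u * (1 - u) / (A + Ni + 1)
}
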