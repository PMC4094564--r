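#' Free parameters of an order-k chain over m states
#'
#' Each of the `m^k` nominal history rows carries `m - 1` free
#' probabilities, so the count is `m^k * (m - 1)`.  It grows exponentially
#' with the order, which is why raw likelihood always favours higher k and
#' penalised criteria are needed.
#'
#' @param m Total state count (including RESET), m >= 2.
#' @param k Order, k >= 0.
#' @return The parameter count as a double (exact for counts below 2^53).
#' @export
free_parameters <- function(m, k) {
  stopifnot(m >= 2, k >= 0)
  p <- as.numeric(m)^k * (m - 1)
  if (!is.finite(p) || p > 2^53) {
    stop("parameter count exceeds exactly representable range; ",
         "reduce the candidate order")
  }
  p
}

#' Likelihood-ratio test between nested Markov orders
#'
#' The order-k0 chain is nested in the order-k1 chain (k0 < k1), so twice
#' the log-likelihood gain is asymptotically chi-squared.  The statistic is
#' `2 (logL_alt - logL_null)`; the default degrees of freedom use the full
#' nominal state space, `df = (m^k1 - m^k0) (m - 1)`.  Under strict
#' per-path windowing many nominal cells are structurally unreachable, so
#' the nominal-df test is conservative; pass `df` explicitly (e.g. computed
#' from observed histories) for a sensitivity analysis.
#'
#' @param logL_null,logL_alt Maximised log-likelihoods of the two fits;
#'   `logL_alt` may not be below `logL_null` beyond rounding (1e-8).
#' @param m Total state count (including RESET).
#' @param k0,k1 Null and alternative orders, k0 < k1.
#' @param df Optional explicit degrees of freedom (overrides nominal).
#' @return An object of class `lrt_result`: list with `order_null`,
#'   `order_alt`, `statistic`, `df`, `p_value`, `sig_1pct`, `sig_0.1pct`.
#' @export
likelihood_ratio_test <- function(logL_null, logL_alt, m, k0, k1,
                                  df = NULL) {
  if (k0 >= k1) stop("null order must be below the alternative order")
  if (logL_alt < logL_null - 1e-8) {
    stop("models not nested / likelihood inversion")
  }
  stat <- max(0, 2 * (logL_alt - logL_null))
  if (is.null(df)) {
    df <- free_parameters(m, k1) - free_parameters(m, k0)
  }
  if (df <= 0) stop("degrees of freedom must be positive")
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(order_null = k0, order_alt = k1, statistic = stat,
                 df = df, p_value = p,
                 sig_1pct = p < 0.01, sig_0.1pct = p < 0.001),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  stars <- if (x$sig_0.1pct) "**" else if (x$sig_1pct) "*" else ""
  cat(sprintf("LRT k=%d vs k=%d: stat = %.3f, df = %s, p = %.4g %s\n",
              x$order_null, x$order_alt, x$statistic,
              format(x$df, big.mark = ","), x$p_value, stars))
  invisible(x)
}

#' Akaike information criterion
#'
#' `AIC = -2 logL + 2 p` with `p = free_parameters(m, k)`.  The minimum-AIC
#' estimate (MAICE) over candidate orders selects the model; AIC may
#' overestimate the true order even asymptotically.
#'
#' @param logL Finite maximised log-likelihood.
#' @param m Total state count.
#' @param k Order.
#' @return The AIC value.
#' @export
aic <- function(logL, m, k) {
  stopifnot(is.finite(logL))
  -2 * logL + 2 * free_parameters(m, k)
}

#' Bayesian information criterion
#'
#' `BIC = -2 logL + p ln N`, penalising parameters by the log observation
#' count; a consistent estimator of the true order.
#'
#' @inheritParams aic
#' @param N Number of observations (transitions), N >= 1.
#' @return The BIC value.
#' @export
bic <- function(logL, m, k, N) {
  stopifnot(is.finite(logL), N >= 1)
  -2 * logL + free_parameters(m, k) * log(N)
}

#' Log marginal likelihood (evidence) of transition counts
#'
#' With a Dirichlet prior on every row, the parameters integrate out in
#' closed form: the evidence is a product over rows of Dirichlet-multinomial
#' factors,
#' `prod_i Gamma(A_i) / Gamma(A_i + N_i) * prod_j Gamma(a_ij + n_ij) / Gamma(a_ij)`,
#' computed throughout with `lgamma` to avoid underflow.  Rows with no
#' observations contribute a factor of 1 (the prior integrates to one), so
#' summing over observed rows only is exact.
#'
#' @param counts A `transition_counts`.
#' @param alpha Positive scalar pseudo-count, or length-m vector (per
#'   target state, shared across rows).
#' @return The log-evidence (0 for empty counts).
#' @export
log_evidence <- function(counts, alpha = 1) {
  stopifnot(inherits(counts, "transition_counts"))
  m <- counts$vocabulary$m
  alpha <- as.numeric(alpha)
  if (!length(alpha) %in% c(1L, m) || any(alpha <= 0) || anyNA(alpha)) {
    stop("alpha must be a positive scalar or length-m positive vector")
  }
  dt <- counts$dt
  if (nrow(dt) == 0L) return(0)
  av <- if (length(alpha) == 1L) rep(alpha, m) else alpha
  A <- sum(av)
  rows <- dt[, .(Ni = sum(n), cell = sum(lgamma(av[j] + n) - lgamma(av[j]))),
             by = h]
  sum(lgamma(A) - lgamma(A + rows$Ni) + rows$cell)
}

#' Posterior probabilities over candidate orders
#'
#' Normalises model evidences into posterior model probabilities under a
#' uniform prior or an exponential complexity penalty with
#' `prior(k) proportional to exp(-m^k)` (the state count of the order-k
#' chain).  Normalisation uses the log-sum-exp trick (the largest
#' log-evidence is pulled out of the sum), so evidences near -1e5 and
#' below pose no underflow problem.
#'
#' @param log_evidences Named numeric vector, one finite log-evidence per
#'   candidate order; names are the orders.
#' @param prior `"uniform"` or `"exp_penalty"`.
#' @param m Total state count (needed for the exponential penalty).
#' @return Named numeric vector of posterior probabilities summing to 1.
#' @export
model_posterior <- function(log_evidences, prior = c("uniform",
                            "exp_penalty"), m = NULL) {
  prior <- match.arg(prior)
  if (length(log_evidences) < 1L) stop("empty candidate set")
  if (any(!is.finite(log_evidences))) stop("log-evidences must be finite")
  ks <- as.numeric(names(log_evidences))
  if (anyNA(ks)) stop("log_evidences must be named by order")
  lp <- log_evidences
  if (prior == "exp_penalty") {
    if (is.null(m)) stop("m is required for the exponential penalty prior")
    lp <- lp - as.numeric(m)^ks
  }
  mx <- max(lp)
  w <- exp(lp - mx)
  out <- w / sum(w)
  names(out) <- names(log_evidences)
  out
}

#' Full order-selection report for a corpus
#'
#' Builds order-k transition counts and MLE fits for `k = 0 .. k_max` and
#' assembles: per-order log-likelihood, free parameter count, AIC (raw and
#' relative to `k_max`), BIC, log-evidence, and posterior model
#' probabilities under both the uniform and the exponential-penalty prior;
#' the likelihood-ratio-test table over consecutive order pairs; and the
#' per-criterion selected order.  The LRT criterion selects the smallest
#' order whose gain from one additional order of memory is not significant
#' at the 1% level (`k_max` if every step is significant).
#'
#' @param corpus A [path_corpus()] (already min-length filtered).
#' @param k_max Largest candidate order, >= 0 (default 5).
#' @param alpha Dirichlet pseudo-count for the evidence (default 1,
#'   Laplace).
#' @param df_mode `"nominal"` (full state space; default) or `"observed"`
#'   (degrees of freedom from observed history counts, a sensitivity mode
#'   for sparse regimes).
#' @return An object of class `order_selection_report`: list with
#'   `orders` (data.frame, one row per k), `lrt` (data.frame of consecutive
#'   tests), `selected` (named integer vector per criterion), `m`, `N`,
#'   `alpha`.
#' @export
select_order <- function(corpus, k_max = 5L, alpha = 1,
                         df_mode = c("nominal", "observed")) {
  stopifnot(inherits(corpus, "path_corpus"), k_max >= 0L)
  df_mode <- match.arg(df_mode)
  m <- corpus$vocabulary$m
  ks <- 0:k_max
  logL <- params <- logEv <- n_hist <- numeric(length(ks))
  N <- NA_real_
  for (i in seq_along(ks)) {
    k <- ks[i]
    cnt <- augment_and_count(corpus, k)
    N <- cnt$N
    logL[i] <- log_likelihood(mle_estimate(cnt), cnt)
    params[i] <- free_parameters(m, k)
    logEv[i] <- log_evidence(cnt, alpha)
    n_hist[i] <- length(unique(cnt$dt$h))
  }
  aic_v <- -2 * logL + 2 * params
  bic_v <- -2 * logL + params * log(N)
  names(logEv) <- ks
  post_u <- model_posterior(logEv, "uniform")
  post_e <- model_posterior(logEv, "exp_penalty", m = m)
  orders <- data.frame(
    order = ks, logL = logL, free_params = params,
    aic = aic_v, aic_vs_kmax = aic_v - aic_v[length(ks)],
    bic = bic_v, log_evidence = logEv,
    posterior_uniform = as.numeric(post_u),
    posterior_exp_penalty = as.numeric(post_e),
    n_observed_histories = n_hist,
    row.names = NULL
  )
  lrt_tab <- NULL
  if (k_max >= 1L) {
    lrt_list <- vector("list", k_max)
    for (i in seq_len(k_max)) {
      df <- if (df_mode == "observed") {
        max(1, (n_hist[i + 1L] - n_hist[i]) * (m - 1))
      } else NULL
      lt <- likelihood_ratio_test(logL[i], logL[i + 1L], m,
                                  ks[i], ks[i + 1L], df = df)
      lrt_list[[i]] <- data.frame(
        order_null = lt$order_null, order_alt = lt$order_alt,
        statistic = lt$statistic, df = lt$df, p_value = lt$p_value,
        sig_1pct = lt$sig_1pct, sig_0.1pct = lt$sig_0.1pct
      )
    }
    lrt_tab <- do.call(rbind, lrt_list)
  }
  sel_lrt <- if (is.null(lrt_tab)) 0L else {
    ns <- which(!lrt_tab$sig_1pct)
    if (length(ns)) lrt_tab$order_null[ns[1L]] else k_max
  }
  selected <- c(
    aic = ks[which.min(aic_v)],
    bic = ks[which.min(bic_v)],
    evidence = ks[which.max(logEv)],
    posterior_uniform = ks[which.max(post_u)],
    posterior_exp_penalty = ks[which.max(post_e)],
    lrt = as.integer(sel_lrt)
  )
  structure(list(orders = orders, lrt = lrt_tab, selected = selected,
                 m = m, N = N, alpha = alpha, df_mode = df_mode),
            class = "order_selection_report")
}

#' @export
print.order_selection_report <- function(x, ...) {
  cat("<order_selection_report> m =", x$m, ", N =", x$N, "transitions\n")
  print(x$orders[, c("order", "logL", "aic", "bic", "log_evidence",
                     "posterior_uniform", "posterior_exp_penalty")],
        row.names = FALSE, digits = 6)
  if (!is.null(x$lrt)) {
    cat("Consecutive likelihood-ratio tests:\n")
    print(x$lrt, row.names = FALSE, digits = 4)
  }
  cat("Selected order per criterion:\n")
  print(x$selected)
  invisible(x)
}

#' Write an order-selection report to TSV
#'
#' Two files: the per-order table and (when present) the LRT table at
#' `paste0(file, ".lrt.tsv")`.
#'
#' @param report An `order_selection_report`.
#' @param file Output path for the per-order table.
#' @return `file` invisibly.
#' @export
write_report_tsv <- function(report, file) {
  stopifnot(inherits(report, "order_selection_report"))
  utils::write.table(report$orders, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(report$lrt)) {
    utils::write.table(report$lrt, paste0(file, ".lrt.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}
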