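# Independent brute-force oracles used across tests. These deliberately
# re-derive quantities by direct enumeration, never via the package's own
# counting/ranking code paths.

# Enumerate all (history, target) windows of RESET-augmented paths with
# explicit loops; returns a data.frame history (labels joined by ","),
# target, n.
brute_force_window_counts <- function(paths, k, reset = "RESET") {
  env <- new.env(parent = emptyenv())
  for (p in paths) {
    aug <- c(rep(reset, k), p, reset)
    for (t in seq_len(length(p) + 1L)) {
      hist <- if (k > 0) paste(aug[t:(t + k - 1L)], collapse = ",") else ""
      key <- paste(hist, aug[t + k], sep = "\r")
      env[[key]] <- (if (is.null(env[[key]])) 0L else env[[key]]) + 1L
    }
  }
  keys <- ls(env)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(
    history = vapply(parts, function(x) if (length(x) == 2L) x[1L] else "",
                     character(1)),
    target = vapply(parts, function(x) x[length(x)], character(1)),
    n = vapply(keys, function(kk) env[[kk]], integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# Sort both tables into a canonical order for exact comparison.
canon_counts <- function(df) {
  df <- df[order(df$history, df$target), c("history", "target", "n")]
  rownames(df) <- NULL
  df
}

# O(m^2) modified competition ranking.
brute_force_ranks <- function(p) {
  vapply(seq_along(p), function(i) sum(p > p[i]) + sum(p == p[i]),
         numeric(1))
}

# Numeric quadrature of the Dirichlet-multinomial row marginal.
# m = 2: evidence = int_0^1 t^n1 (1-t)^n2 Beta(t; a, a) dt.
beta_evidence_quad <- function(n1, n2, a = 1) {
  stats::integrate(function(t) t^n1 * (1 - t)^n2 * stats::dbeta(t, a, a),
                   0, 1, rel.tol = 1e-12, abs.tol = 0)$value
}

# m = 3, uniform prior (density = Gamma(3) = 2 on the simplex):
# evidence = 2 * int int x^n1 y^n2 (1-x-y)^n3 dy dx, via nested adaptive
# 1-D quadrature (relative tolerance, so tiny values stay accurate).
dirichlet3_evidence_quad <- function(n1, n2, n3) {
  inner <- function(x) {
    vapply(x, function(xx) {
      if (xx >= 1) return(0)
      stats::integrate(function(y) y^n2 * (1 - xx - y)^n3, 0, 1 - xx,
                       rel.tol = 1e-11, abs.tol = 0)$value
    }, numeric(1))
  }
  2 * stats::integrate(function(x) x^n1 * inner(x), 0, 1,
                       rel.tol = 1e-10, abs.tol = 0)$value
}

# Random small corpus over given labels.
make_random_corpus <- function(n_paths, labels, max_len = 8L, seed = 1L) {
  withr::with_seed(seed, {
    paths <- lapply(seq_len(n_paths), function(i) {
      sample(labels, sample.int(max_len, 1L), replace = TRUE)
    })
  })
  path_corpus(paths, state_vocabulary(labels))
}

# Build a transition_counts object holding a single order-0 row with the
# given per-target counts (length m, RESET last). Used to test the
# evidence against quadrature row by row.
one_row_counts <- function(n_vec, vocab) {
  stopifnot(length(n_vec) == vocab$m)
  jj <- which(n_vec > 0)
  dt <- data.table::data.table(h = rep(0, length(jj)), j = jj,
                               n = as.integer(n_vec[jj]))
  data.table::setkey(dt, h, j)
  structure(list(order = 0L, vocabulary = vocab, dt = dt,
                 N = sum(n_vec)),
            class = "transition_counts")
}

# The order-2, 5-state recovery corpus used by several tests: a random
# Dirichlet(1) tensor has genuinely order-2 rows almost surely.
recovery_corpus <- function(total_clicks = 5e4, seed = 42L) {
  tensor <- random_stochastic_tensor(5L, 2L, concentration = 1,
                                     seed = seed)
  spec <- generator_spec(5L, 2L, tensor,
                         terminal_policy = list(kind = "geometric",
                                                p = 0.05),
                         total_clicks = total_clicks, seed = seed)
  filter_min_length(generate_markov_corpus(spec), 2L)
}
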