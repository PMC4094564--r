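#' Uniform random path corpus with a terminal symbol
#'
#' Emulates a memoryless control process: states are drawn uniformly from
#' `n_states` symbols, one of which is a designated terminal -- drawing it
#' ends the current path (the terminal itself is not emitted; RESET
#' augmentation later re-models termination).  Generation proceeds until
#' the accumulated click count (emitted symbols) reaches `total_clicks`.
#' Path lengths are therefore Geometric(1/n_states) in the number of
#' draws; single-click paths are retained for the filter stage to remove.
#'
#' @param n_states Number of symbols including the terminal (default 26,
#'   giving 25 data labels + RESET = 26 model states).
#' @param total_clicks Target number of emitted clicks.
#' @param seed Integer seed; a fixed seed reproduces the corpus exactly.
#' @return A [path_corpus()].
#' @export
generate_uniform_corpus <- function(n_states = 26L, total_clicks,
                                    seed = 1L) {
  stopifnot(n_states >= 2L, total_clicks >= 1)
  labels <- sprintf("s%02d", seq_len(n_states - 1L))
  paths <- list()
  withr::with_seed(seed, {
    clicks <- 0
    current <- integer(0)
    while (clicks < total_clicks) {
      chunk <- sample.int(n_states, size = max(1000L, n_states * 4L),
                          replace = TRUE)
      for (s in chunk) {
        if (s == n_states) {        # terminal symbol: close the path
          if (length(current)) {
            paths[[length(paths) + 1L]] <- labels[current]
            current <- integer(0)
          }
        } else {
          current <- c(current, s)
          clicks <- clicks + 1
          if (clicks >= total_clicks) break
        }
      }
    }
    if (length(current)) paths[[length(paths) + 1L]] <- labels[current]
  })
  path_corpus(paths, state_vocabulary(labels),
              meta = list(source = "generate_uniform_corpus",
                          n_states = n_states, seed = seed))
}

#' Specification of an order-k Markov corpus generator
#'
#' @param n_states Number of emitted data states, >= 2.
#' @param order Markov order k of the generating chain, >= 0.
#' @param tensor Row-stochastic matrix of dimension `n_states^order` x
#'   `n_states`; row r is the next-state distribution for the history with
#'   base-`n_states` code r-1 (oldest symbol first).
#' @param terminal_policy Either `list(kind = "geometric", p = ...)` --
#'   after each emitted click the path ends with probability p -- or
#'   `list(kind = "state", state = i)`: drawing state i ends the path and
#'   the symbol is dropped.
#' @param total_clicks Target total emitted clicks.
#' @param seed Integer seed.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_states, order, tensor,
                           terminal_policy = list(kind = "geometric",
                                                  p = 0.05),
                           total_clicks, seed = 1L) {
  stopifnot(n_states >= 2L, order >= 0L, total_clicks >= 1)
  tensor <- as.matrix(tensor)
  if (nrow(tensor) != n_states^order || ncol(tensor) != n_states) {
    stop("tensor must be n_states^order x n_states")
  }
  if (any(tensor < 0) || any(abs(rowSums(tensor) - 1) > 1e-9)) {
    stop("tensor rows must be stochastic")
  }
  kind <- terminal_policy$kind
  if (!kind %in% c("geometric", "state")) {
    stop("terminal_policy kind must be 'geometric' or 'state'")
  }
  if (kind == "geometric" &&
      (terminal_policy$p <= 0 || terminal_policy$p >= 1)) {
    stop("geometric stop probability must be in (0, 1)")
  }
  if (kind == "state" &&
      (terminal_policy$state < 1 || terminal_policy$state > n_states)) {
    stop("terminal state index out of range")
  }
  structure(list(n_states = as.integer(n_states), order = as.integer(order),
                 tensor = tensor, terminal_policy = terminal_policy,
                 total_clicks = total_clicks, seed = as.integer(seed)),
            class = "generator_spec")
}

#' Sample a corpus from a known order-k Markov chain
#'
#' Paths are sampled from the transition tensor of a [generator_spec()]:
#' the first k symbols of each path are drawn iid uniformly over the
#' (non-terminal) data states, subsequent symbols from the tensor row of
#' the current length-k history, until the terminal policy fires.
#' Generation stops once accumulated clicks reach the target.  Fully
#' seeded, so recovery experiments are reproducible.
#'
#' @param spec A [generator_spec()].
#' @return A [path_corpus()] whose vocabulary holds the emitted states.
#' @export
generate_markov_corpus <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  ns <- spec$n_states
  k <- spec$order
  tp <- spec$terminal_policy
  term_state <- if (tp$kind == "state") tp$state else 0L
  emit_states <- setdiff(seq_len(ns), term_state)
  labels <- sprintf("s%02d", seq_len(ns))
  cum <- t(apply(spec$tensor, 1L, cumsum))
  max_len <- 10000L
  paths <- list()
  withr::with_seed(spec$seed, {
    clicks <- 0
    while (clicks < spec$total_clicks) {
      p <- integer(0)
      # seed the history uniformly over emitted states
      hid <- 0
      alive <- TRUE
      for (d in seq_len(k)) {
        s <- emit_states[sample.int(length(emit_states), 1L)]
        p <- c(p, s)
        hid <- (hid %% ns^(k - 1)) * ns + (s - 1)
        if (tp$kind == "geometric" && runif(1) < tp$p) {
          alive <- FALSE
          break
        }
      }
      while (alive && length(p) < max_len) {
        s <- findInterval(runif(1), cum[hid + 1, ]) + 1L
        if (tp$kind == "state" && s == term_state) break
        p <- c(p, s)
        if (k > 0) hid <- (hid %% ns^(k - 1)) * ns + (s - 1)
        if (tp$kind == "geometric" && runif(1) < tp$p) break
      }
      if (length(p)) {
        paths[[length(paths) + 1L]] <- labels[p]
        clicks <- clicks + length(p)
      }
    }
  })
  vocab <- state_vocabulary(labels[sort(emit_states)])
  path_corpus(paths, vocab,
              meta = list(source = "generate_markov_corpus",
                          order = k, seed = spec$seed))
}

#' Random row-stochastic transition tensor
#'
#' Rows drawn independently from a symmetric Dirichlet(`concentration`);
#' large concentrations approach the uniform row, small ones give spiky
#' rows with genuine history dependence almost surely.
#'
#' @param m Number of states (columns), >= 2.
#' @param k History length; the tensor has `m^k` rows.
#' @param concentration Positive Dirichlet concentration (default 1).
#' @param seed Integer seed.
#' @return An `m^k` x `m` row-stochastic matrix.
#' @export
random_stochastic_tensor <- function(m, k, concentration = 1, seed = 1L) {
  stopifnot(m >= 2L, k >= 0L, concentration > 0)
  n_rows <- m^k
  withr::with_seed(seed, {
    g <- matrix(rgamma(n_rows * m, shape = concentration),
                nrow = n_rows, ncol = m)
  })
  g / rowSums(g)
}

#' Sticky transition tensor with inflated self-transitions
#'
#' A first-order tensor mixing a random Dirichlet row with mass `stay` on
#' the diagonal, producing corpora whose self-transition probability rises
#' with conditioning order -- a fixture for the self-transition profile
#' analyses.
#'
#' @param m Number of states.
#' @param stay Self-transition mass in (0, 1) added before normalisation.
#' @param concentration Dirichlet concentration of the off-diagonal part.
#' @param seed Integer seed.
#' @return An `m` x `m` row-stochastic matrix with a dominant diagonal.
#' @export
sticky_tensor <- function(m, stay = 0.6, concentration = 1, seed = 1L) {
  stopifnot(m >= 2L, stay > 0, stay < 1)
  base <- random_stochastic_tensor(m, 1L, concentration, seed)
  out <- (1 - stay) * base + stay * diag(m)
  out / rowSums(out)
}
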