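test_that("fold assignment partitions paths and balances clicks", {
  co <- make_random_corpus(40L, letters[1:3], max_len = 6L, seed = 1L)
  fa <- make_stratified_folds(co, n_folds = 10L, seed = 5L)
  expect_length(fa$fold, 40L)
  expect_setequal(unique(fa$fold), 1:10)
  expect_equal(sum(fa$fold_weights), sum(lengths(co$paths) + 1))
  # deterministic under the seed
  fa2 <- make_stratified_folds(co, n_folds = 10L, seed = 5L)
  expect_identical(fa$fold, fa2$fold)
  # ten equal-length paths over ten folds: exactly one path each
  eq <- path_corpus(rep(list(c("a", "b", "c")), 10L))
  fe <- make_stratified_folds(eq, 10L, seed = 1L)
  expect_identical(sort(tabulate(fe$fold, 10L)), rep(1L, 10L))
  expect_error(make_stratified_folds(eq, 11L), "fewer paths")
})

test_that("greedy packing keeps fold weights within one path of each other", {
  co <- make_random_corpus(10000L, letters[1:3], max_len = 50L, seed = 2L)
  fa <- make_stratified_folds(co, 10L, seed = 3L)
  w <- lengths(co$paths) + 1
  expect_lte(max(fa$fold_weights) - min(fa$fold_weights), max(w))
})

test_that("modified competition ranking leaves gaps before ties", {
  expect_identical(ranks_with_ties(c(0.4, 0.2, 0.2, 0.2, 0.1)),
                   c(1L, 4L, 4L, 4L, 5L))
  expect_identical(ranks_with_ties(rep(0.25, 4)), rep(4L, 4L))
  expect_error(ranks_with_ties(c(0.1, NA)), "finite")
  expect_error(ranks_with_ties(c(0.1, -0.2)), "finite|non-negative")
  withr::with_seed(4L, {
    for (i in 1:25) {
      p <- sample(c(stats::runif(6), stats::runif(2)), 10, replace = TRUE)
      expect_identical(as.numeric(ranks_with_ties(p)),
                       brute_force_ranks(p))
    }
  })
})

test_that("average rank hits its closed-form extremes", {
  v <- state_vocabulary(c("a", "b"))       # m = 3
  tr <- path_corpus(list(c("a", "a", "a")), v)  # histories: RESET, a
  model <- posterior_mean_model(augment_and_count(tr, 1L), 1)
  # every test transition is the row-wise most probable state:
  # row a is (a:2, RESET:1), so a->a sits at rank 1
  bc <- augment_and_count(path_corpus(list(c("a", "a", "a")), v), 1L)
  bc$dt <- bc$dt[bc$dt$j == 1L & bc$dt$h == encode_history(v, "a")]
  bc$N <- sum(bc$dt$n)
  expect_identical(average_rank(model, bc), 1)
  # all test histories unseen in training: rank m for everything
  uc <- augment_and_count(path_corpus(list(c("b", "b", "b")), v), 1L)
  uc$dt <- uc$dt[uc$dt$h == encode_history(v, "b")]
  uc$N <- sum(uc$dt$n)
  expect_identical(average_rank(model, uc), 3)  # m = 3
})

test_that("zero-order average rank equals a hand-computed weighted rank", {
  # training marginals: a 6, b 3, RESET 3 -> smoothed (7,4,4)/15
  # ranks: a = 1; b and RESET tie at the worst rank 3
  v <- state_vocabulary(c("a", "b"))
  train <- one_row_counts(c(6L, 3L, 3L), v)
  model <- posterior_mean_model(train, 1)
  test <- one_row_counts(c(2L, 1L, 1L), v)
  expect_equal(average_rank(model, test), (2 * 1 + 1 * 3 + 1 * 3) / 4)
  # order mismatch is an error
  co <- path_corpus(list(c("a", "b")), v)
  expect_error(average_rank(model, augment_and_count(co, 1L)),
               "order mismatch")
})

test_that("top-K hit rate honours its bounds and tie semantics", {
  v <- state_vocabulary(c("A", "B", "C", "D", "E"))  # m = 6
  # row A: B 5, C 2, D 2, E 2 (A and RESET unobserved)
  train_tab <- data.table::data.table(
    h = encode_history(v, "A"), j = c(2L, 3L, 4L, 5L), n = c(5L, 2L, 2L, 2L))
  data.table::setkey(train_tab, h, j)
  train <- structure(list(order = 1L, vocabulary = v, dt = train_tab,
                          N = 11L), class = "transition_counts")
  model <- posterior_mean_model(train, 1)
  test_hit <- structure(list(order = 1L, vocabulary = v,
                             dt = data.table::data.table(
                               h = encode_history(v, "A"), j = 2L, n = 10L),
                             N = 10L), class = "transition_counts")
  # true state at rank 1: always a hit, any K
  expect_identical(topk_hit_rate(model, test_hit, K = 1L, seed = 1L), 1)
  # K = m includes every state
  expect_identical(topk_hit_rate(model, test_hit, K = 6L, seed = 1L), 1)
  expect_error(topk_hit_rate(model, test_hit, K = 0L), "out of range")
  expect_error(topk_hit_rate(model, test_hit, K = 7L), "out of range")
})

test_that("boundary ties are drawn with the combinatorial probability", {
  v <- state_vocabulary(c("A", "B", "C", "D", "E"))  # m = 6
  train_tab <- data.table::data.table(
    h = encode_history(v, "A"), j = c(2L, 3L, 4L, 5L), n = c(5L, 2L, 2L, 2L))
  data.table::setkey(train_tab, h, j)
  train <- structure(list(order = 1L, vocabulary = v, dt = train_tab,
                          N = 11L), class = "transition_counts")
  model <- posterior_mean_model(train, 1)
  # true next state C sits in a 3-way tie straddling the K = 2 boundary:
  # one slot left after B, so inclusion probability is 1/3
  n_rep <- 1e4L
  test_tie <- structure(list(order = 1L, vocabulary = v,
                             dt = data.table::data.table(
                               h = encode_history(v, "A"), j = 3L,
                               n = n_rep),
                             N = n_rep), class = "transition_counts")
  rate <- topk_hit_rate(model, test_tie, K = 2L, seed = 77L)
  se <- sqrt((1 / 3) * (2 / 3) / n_rep)
  expect_lt(abs(rate - 1 / 3), 3 * se)
  # an unseen history: all m states tie, inclusion probability K/m
  test_unseen <- structure(list(order = 1L, vocabulary = v,
                                dt = data.table::data.table(
                                  h = encode_history(v, "B"), j = 1L,
                                  n = n_rep),
                                N = n_rep), class = "transition_counts")
  rate_u <- topk_hit_rate(model, test_unseen, K = 3L, seed = 78L)
  se_u <- sqrt(0.5 * 0.5 / n_rep)
  expect_lt(abs(rate_u - 3 / 6), 3 * se_u)
})

test_that("cross-validation scores every click exactly once per fold", {
  co <- make_random_corpus(60L, letters[1:4], max_len = 6L, seed = 12L)
  fa <- make_stratified_folds(co, 5L, seed = 9L)
  total <- 0L
  for (f in 1:5) {
    sub <- path_corpus(co$paths[fa$fold == f], co$vocabulary)
    total <- total + augment_and_count(sub, 1L)$N
  }
  expect_identical(total, augment_and_count(co, 1L)$N)
})

test_that("cv evaluation is deterministic and bounded", {
  co <- make_random_corpus(80L, letters[1:4], max_len = 6L, seed = 15L)
  cv <- cv_order_evaluation(co, k_max = 2L, n_folds = 5L, seed = 3L,
                            topk = 3L)
  cv2 <- cv_order_evaluation(co, k_max = 2L, n_folds = 5L, seed = 3L,
                             topk = 3L)
  expect_identical(cv$rank, cv2$rank)
  expect_identical(cv$topk, cv2$topk)
  m <- co$vocabulary$m
  expect_true(all(cv$rank >= 1 & cv$rank <= m))
  expect_true(all(cv$topk >= 0 & cv$topk <= 1))
  expect_equal(cv$mean_rank, rowMeans(cv$rank))
  # single-order evaluation returns exactly the zero-order frequency rank
  cv0 <- cv_order_evaluation(co, k_max = 0L, n_folds = 5L, seed = 3L)
  expect_identical(dim(cv0$rank), c(1L, 5L))
  expect_identical(cv0$selected, 0L)
})

test_that("rank and top-5 agree on which order wins the recovery corpus", {
  co <- recovery_corpus(total_clicks = 2e4, seed = 45L)
  cv <- cv_order_evaluation(co, k_max = 3L, n_folds = 10L, seed = 8L,
                            topk = 5L)
  ks <- as.integer(rownames(cv$rank))
  expect_identical(ks[which.min(cv$mean_rank)],
                   ks[which.max(cv$mean_topk)])
})
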