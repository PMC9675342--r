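test_that("Laplace smoothing adds one occurrence over the vocabulary", {
  # row A holds B four times; vocabulary {A, B, C}
  train <- list(c("A", "B", "A", "B", "A", "B", "A", "B", "C"))
  m <- fit_ngram_model(train, max_order = 1)
  expect_equal(m$vocabulary, c("A", "B", "C"))
  expect_equal(unname(m$tables[[1]]["A", ]), c(1 / 7, 5 / 7, 1 / 7))
  expect_true(all(abs(rowSums(m$tables[[1]]) - 1) < 1e-9))
  expect_true(all(m$base_probs > 0))
  expect_equal(sum(m$base_probs), 1)
})

test_that("interpolated scores are the product of suffix conditionals", {
  # hand-built model: P(C|B) = 0.5, P(C|A,B) = 0.8 -> score 0.4
  vocab <- c("A", "B", "C")
  model <- structure(list(
    max_order = 2, vocabulary = vocab,
    tables = list(
      matrix(c(0.25, 0.25, 0.5), 1, 3, dimnames = list("B", vocab)),
      matrix(c(0.1, 0.1, 0.8), 1, 3, dimnames = list("A/B", vocab))),
    base_probs = setNames(rep(1 / 3, 3), vocab)), class = "ngram_model")
  expect_equal(interpolated_score(model, c("A", "B"), "C"), 0.5 * 0.8)
  # a single antecedent is the plain smoothed conditional
  expect_equal(interpolated_score(model, "B", "C"), 0.5)
  expect_error(interpolated_score(model, c("A", "B", "C"), "C"), "max_order")
  expect_error(interpolated_score(model, "B", "Zz"), "vocabulary")
})

test_that("unseen contexts fall back to the uniform Laplace floor", {
  train <- list(c("a", "b", "c", "d"))
  m <- fit_ngram_model(train, max_order = 3)
  # "d" never occurs as an antecedent, so every suffix ending in d is
  # unseen and contributes the 1/|V| floor
  expect_equal(interpolated_score(m, c("a", "b", "d"), "a"),
               prod(rep(1 / 4, 3)))
})

test_that("predicted distributions normalise interpolated scores", {
  train <- list(c("A", "B", "A", "C", "A", "B"))
  m <- fit_ngram_model(train, max_order = 2)
  d <- predict_distribution(m, c("B", "A"))
  expect_equal(sum(d), 1)
  expect_true(all(d > 0))
  expect_equal(names(d), m$vocabulary)
  expect_equal(sum(predict_distribution(m)), 1)  # base probabilities
})

test_that("deterministic alternation is perfectly predictable at order 1", {
  bouts <- token_bouts(rep(list(rep(c("A", "B"), 10)), 20))
  cfg <- play_config(kfold_reps = 5, rng_seed = 9)
  a1 <- kfold_accuracy(bouts, 1, "argmax", cfg)
  expect_equal(a1$mean_accuracy, 1)
  a0 <- kfold_accuracy(bouts, 0, "expected_match", cfg)
  expect_lt(abs(a0$mean_accuracy - 0.5), 0.02)  # base rates are 50/50
})

test_that("order-0 expected-match accuracy equals the analytic fold value", {
  set.seed(20)
  vocab <- c("a", "b", "c", "d")
  bouts <- token_bouts(lapply(1:25, function(i)
    sample(vocab, 12, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))))
  cfg <- play_config(kfold_reps = 1, rng_seed = 77)
  rep <- kfold_accuracy(bouts, 0, "expected_match", cfg)

  # independent recomputation of the same fold with base R
  set.seed(derive_seed(77, "kfold", 1))
  test <- sample.int(25, max(1, round(0.05 * 25)))
  train_toks <- unlist(lapply(bouts[-test], bout_tokens))
  p_hat <- (table(factor(train_toks, levels = vocab)) + 1) /
    (length(train_toks) + 4)
  expected <- mean(vapply(bouts[test], function(b)
    mean(as.numeric(p_hat[bout_tokens(b)])), 0))
  expect_equal(rep$mean_accuracy, expected, tolerance = 1e-12)
})

test_that("iid uniform data give chance-level expected-match accuracy", {
  set.seed(14)
  V <- 8
  vocab <- sprintf("e%d", 1:V)
  bouts <- token_bouts(lapply(1:40, function(i)
    sample(vocab, 20, replace = TRUE)))
  cfg <- play_config(kfold_reps = 30, rng_seed = 3)
  a0 <- kfold_accuracy(bouts, 0, "expected_match", cfg)
  expect_lt(abs(a0$mean_accuracy - 1 / V), 0.01)
  a1 <- kfold_accuracy(bouts, 1, "expected_match", cfg)
  expect_lt(abs(a1$mean_accuracy - 1 / V), 0.015)  # no real gain
})

test_that("naive Bayes is perfect for a constant element and matches e1071", {
  bouts <- token_bouts(rep(list(rep("X", 6)), 25))
  cfg <- play_config(kfold_reps = 3, rng_seed = 5)
  nb <- naive_bayes_accuracy(bouts, 1, cfg)
  expect_equal(nb$mean_accuracy, 1)

  # likelihood tables against e1071's add-one-smoothed naive Bayes
  skip_if_not_installed("e1071")
  set.seed(8)
  seqs <- lapply(1:10, function(i)
    sample(c("A", "B", "C"), 15, replace = TRUE))
  w <- playseq:::transition_windows(seqs, 2)
  vocab <- c("A", "B", "C")
  cls <- factor(w$consequent, levels = vocab)
  fit <- e1071::naiveBayes(
    data.frame(f1 = factor(w$antecedents[, 1], levels = vocab),
               f2 = factor(w$antecedents[, 2], levels = vocab)),
    cls, laplace = 1)
  n_c <- table(cls)
  ours <- t(sapply(vocab, function(cc) {
    tb <- table(factor(w$antecedents[, 1], levels = vocab), cls)
    (tb[, cc] + 1) / (n_c[[cc]] + 3)
  }))
  expect_equal(unclass(fit$tables$f1), unclass(ours), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("naive Bayes exploits second-order structure a first-order model misses", {
  # consequent driven by the two preceding elements via a fixed random map
  truth <- make_order2_structure(n_elements = 5, p_preferred = 0.8,
                                 seed = 3, cooccur_rate = 0,
                                 break_rate = 0, n_bouts = 25)
  bouts <- simulate_bouts(truth, seed = 6)
  cfg <- play_config(kfold_reps = 10, rng_seed = 21)
  nb1 <- naive_bayes_accuracy(bouts, 1, cfg)
  nb2 <- naive_bayes_accuracy(bouts, 2, cfg)
  expect_gt(nb2$mean_accuracy, nb1$mean_accuracy)
})
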