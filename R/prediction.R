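# antecedent windows of a fixed order: returns a matrix of antecedent tokens
# (one column per position, oldest first) and the consequent vector; windows
# never span markers or sequence boundaries
transition_windows <- function(seqs, order) {
  all <- unlist(lapply(seqs, function(s) c(s, rep(BREAK, max(order, 1)))),
                use.names = FALSE)
  n <- length(all)
  if (n < order + 1)
    return(list(antecedents = matrix(character(), 0, order),
                consequent = character()))
  m <- is_marker(all)
  ci <- (order + 1):n
  valid <- !m[ci]
  for (k in seq_len(order)) valid <- valid & !m[ci - k]
  ci <- ci[valid]
  ante <- vapply(order:1, function(k) all[ci - k], character(length(ci)))
  if (length(ci) == 1) ante <- matrix(ante, nrow = 1)
  list(antecedents = ante, consequent = all[ci])
}

#' Fit an interpolated n-gram model with Laplace smoothing
#'
#' For every order up to `max_order`, raw antecedent-tuple counts are
#' collected and smoothed by adding one occurrence to every
#' (observed antecedent, vocabulary element) cell and renormalising, so no
#' observed context assigns probability zero to any element. Base occurrence
#' probabilities get the same add-one treatment. Contexts never observed in
#' training carry no row; scoring backs off to the uniform Laplace floor
#' `1/|V|` for them.
#'
#' @param training_sequences List of linearized token sequences.
#' @param max_order Maximum antecedent length (1 to 3).
#' @param vocabulary Optional fixed element vocabulary; defaults to the
#'   elements seen in training. Supply the full repertoire when held-out
#'   data may contain elements absent from a training fold.
#' @return Object of class `ngram_model`: list with `max_order`,
#'   `vocabulary`, `tables` (per order, a smoothed probability matrix with
#'   one row per observed antecedent tuple) and `base_probs`.
#' @export
fit_ngram_model <- function(training_sequences, max_order = 3,
                            vocabulary = NULL) {
  stopifnot(max_order >= 1, max_order <= 3)
  if (is.character(training_sequences))
    training_sequences <- list(training_sequences)
  vocab <- sort(vocabulary %||% seq_vocabulary(training_sequences))
  V <- length(vocab)
  if (V == 0) stop("empty vocabulary")
  toks <- unlist(training_sequences, use.names = FALSE)
  toks <- toks[!is_marker(toks)]
  freq <- table(factor(toks, levels = vocab))
  base_probs <- setNames((as.numeric(freq) + 1) / (length(toks) + V), vocab)

  tables <- lapply(seq_len(max_order), function(k) {
    cts <- count_transitions(training_sequences, order = k)$counts
    if (nrow(cts) == 0)
      return(matrix(numeric(), 0, V, dimnames = list(NULL, vocab)))
    keys <- sort(unique(cts$antecedent))
    M <- matrix(0, length(keys), V, dimnames = list(keys, vocab))
    M[cbind(match(cts$antecedent, keys), match(cts$consequent, vocab))] <-
      cts$count
    (M + 1) / (rowSums(M) + V)
  })
  structure(list(max_order = max_order, vocabulary = vocab,
                 tables = tables, base_probs = base_probs),
            class = "ngram_model")
}

#' @export
print.ngram_model <- function(x, ...) {
  cat(sprintf("n-gram model: vocabulary %d, orders 1..%d (%s observed contexts)\n",
              length(x$vocabulary), x$max_order,
              paste(vapply(x$tables, nrow, 0L), collapse = "/")))
  invisible(x)
}

# smoothed conditional row for a context of length k, or the uniform floor
context_row <- function(model, context_key, k) {
  tab <- model$tables[[k]]
  if (!is.null(tab) && nrow(tab) && context_key %in% rownames(tab))
    tab[context_key, ]
  else
    setNames(rep(1 / length(model$vocabulary), length(model$vocabulary)),
             model$vocabulary)
}

#' Interpolated n-gram score of a consequent
#'
#' The score of a consequent given an antecedent tuple is the product over
#' suffix lengths of the smoothed conditional probabilities: for the
#' third-order antecedent `Approach/StareAt/Hit`, the score of a consequent
#' is the product of its probability given the full triad, given
#' `StareAt/Hit`, and given `Hit`. This interpolation lets sparse
#' higher-order contexts borrow strength from their frequent lower-order
#' suffixes. Contexts with no training row contribute the uniform Laplace
#' floor `1/|V|`.
#'
#' @param model An [fit_ngram_model()] result.
#' @param antecedents Character vector of antecedent elements, oldest first,
#'   length 1 to `max_order`.
#' @param consequent A single vocabulary element.
#' @return The (unnormalised) interpolated score.
#' @export
interpolated_score <- function(model, antecedents, consequent) {
  r <- length(antecedents)
  if (r < 1) stop("need at least one antecedent; use base_probs for order 0")
  if (r > model$max_order)
    stop("antecedent tuple longer than the model's max_order")
  if (!consequent %in% model$vocabulary)
    stop("consequent '", consequent, "' not in the model vocabulary")
  score <- 1
  for (k in seq_len(r)) {
    key <- paste(tail(antecedents, k), collapse = TUPLE_SEP)
    score <- score * context_row(model, key, k)[[consequent]]
  }
  score
}

#' Predicted next-element distribution
#'
#' Interpolated scores over the whole vocabulary, normalised to sum to one.
#' With no antecedents the smoothed base occurrence probabilities are
#' returned.
#'
#' @inheritParams interpolated_score
#' @return Named probability vector over the vocabulary.
#' @export
predict_distribution <- function(model, antecedents = character()) {
  r <- length(antecedents)
  if (r == 0) return(model$base_probs)
  if (r > model$max_order)
    stop("antecedent tuple longer than the model's max_order")
  score <- rep(1, length(model$vocabulary))
  for (k in seq_len(r)) {
    key <- paste(tail(antecedents, k), collapse = TUPLE_SEP)
    score <- score * context_row(model, key, k)
  }
  score / sum(score)
}

# shared k-fold machinery: returns per-(bout, rep) proportions
kfold_run <- function(bouts, reps, train_fraction, seed, scorer) {
  n <- length(bouts)
  if (n < 2) stop("k-fold validation needs at least two individual-bouts")
  if (n < 20)
    warning("fewer than 20 individual-bouts: folds are degenerate")
  per_bout <- numeric()
  n_scoreable <- 0
  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, "kfold", r))
    n_test <- max(1, round((1 - train_fraction) * n))
    test <- sample.int(n, n_test)
    lin <- lapply(bouts, linearize)
    scores <- scorer(lin[-test], lin[test])
    n_scoreable <- n_scoreable + sum(lengths(scores))
    props <- vapply(scores, function(s) if (length(s)) mean(s) else NA_real_,
                    0)
    per_bout <- c(per_bout, props[!is.na(props)])
  }
  if (n_scoreable == 0)
    stop("no scoreable tokens: sequences shorter than the antecedent window")
  list(per_bout = per_bout, n_scoreable = n_scoreable)
}

#' Next-element prediction accuracy under k-fold validation
#'
#' In each repetition a random 5% of individual-bouts (at least one) is held
#' out, an n-gram model is fitted to the rest, and every held-out element
#' with a full antecedent window is predicted from the interpolated model.
#' Two notions of "correct classification" are provided: `expected_match`
#' scores each element by the probability the model assigned to it (the
#' expected accuracy of probability-matched guessing), and `argmax` scores 1
#' when the modal prediction is the truth (ties broken by lexicographic
#' element order). Order 0 predicts from base occurrence probabilities
#' alone, quantifying accuracy with no antecedent information.
#'
#' @param bouts Pre-processed [individual_bout()]s.
#' @param order Antecedent length, 0 to 3.
#' @param mode `"expected_match"` or `"argmax"`.
#' @param config A [play_config()]; uses `train_fraction`, `kfold_reps`,
#'   `rng_seed`.
#' @param seed Optional override of `config$rng_seed`.
#' @return Object of class `accuracy_report`: list with `order`, `mode`,
#'   `mean_accuracy` (mean over bouts and repetitions), `per_bout`, `reps`,
#'   `n_scoreable` and `se` (standard error over bout-level proportions).
#' @export
kfold_accuracy <- function(bouts, order = 1,
                           mode = c("expected_match", "argmax"),
                           config = play_config(), seed = NULL) {
  mode <- match.arg(mode)
  if (!order %in% 0:3) stop("order must be 0, 1, 2 or 3")
  seed <- seed %||% config$rng_seed
  vocab <- sort(unique(unlist(lapply(bouts, bout_tokens), use.names = FALSE)))

  scorer <- function(train, test) {
    if (order == 0) {
      toks <- unlist(train, use.names = FALSE)
      toks <- toks[!is_marker(toks)]
      freq <- table(factor(toks, levels = vocab))
      bp <- (as.numeric(freq) + 1) / (length(toks) + length(vocab))
      names(bp) <- vocab
      top <- vocab[which.max(bp)]
      lapply(test, function(s) {
        s <- s[!is_marker(s)]
        if (mode == "expected_match") unname(bp[s]) else as.numeric(s == top)
      })
    } else {
      model <- fit_ngram_model(train, max_order = order, vocabulary = vocab)
      lapply(test, function(s) {
        w <- transition_windows(list(s), order)
        if (length(w$consequent) == 0) return(numeric())
        vapply(seq_along(w$consequent), function(i) {
          d <- predict_distribution(model, w$antecedents[i, ])
          if (mode == "expected_match") d[[w$consequent[i]]]
          else as.numeric(names(d)[which.max(d)] == w$consequent[i])
        }, 0)
      })
    }
  }
  run <- kfold_run(bouts, config$kfold_reps, config$train_fraction, seed,
                   scorer)
  structure(list(order = order, mode = mode,
                 mean_accuracy = mean(run$per_bout),
                 per_bout = run$per_bout, reps = config$kfold_reps,
                 n_scoreable = run$n_scoreable,
                 se = sd(run$per_bout) / sqrt(length(run$per_bout))),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("prediction accuracy: order %d, %s mode: %.4f (se %.4f, %d reps, %d tokens)\n",
              x$order, x$mode, x$mean_accuracy, x$se, x$reps, x$n_scoreable))
  invisible(x)
}

#' Naive Bayes prediction accuracy under k-fold validation
#'
#' A categorical naive Bayes classifier with add-one smoothing: the class is
#' the consequent element and each of the previous `order` positions is a
#' feature, treated as independent given the class — a strong independence
#' assumption, so its accuracy cannot be read as purely sequential
#' information. Uses the same fold scheme as [kfold_accuracy()] and argmax
#' scoring.
#'
#' @inheritParams kfold_accuracy
#' @param order Number of antecedent features, 1 to 3.
#' @return An `accuracy_report` with mode `"naive_bayes"`.
#' @export
naive_bayes_accuracy <- function(bouts, order = 1, config = play_config(),
                                 seed = NULL) {
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  seed <- seed %||% config$rng_seed
  vocab <- sort(unique(unlist(lapply(bouts, bout_tokens), use.names = FALSE)))
  V <- length(vocab)

  scorer <- function(train, test) {
    w <- transition_windows(train, order)
    cls <- factor(w$consequent, levels = vocab)
    n_c <- table(cls)
    log_prior <- log((as.numeric(n_c) + 1) / (length(w$consequent) + V))
    # per feature position: log P(value | class), rows = value, cols = class
    log_lik <- lapply(seq_len(order), function(j) {
      tb <- table(factor(w$antecedents[, j], levels = vocab), cls)
      log(sweep(tb + 1, 2, as.numeric(n_c) + V, "/"))
    })
    lapply(test, function(s) {
      tw <- transition_windows(list(s), order)
      if (length(tw$consequent) == 0) return(numeric())
      vapply(seq_along(tw$consequent), function(i) {
        sc <- log_prior
        for (j in seq_len(order))
          sc <- sc + log_lik[[j]][match(tw$antecedents[i, j], vocab), ]
        as.numeric(vocab[which.max(sc)] == tw$consequent[i])
      }, 0)
    })
  }
  run <- kfold_run(bouts, config$kfold_reps, config$train_fraction, seed,
                   scorer)
  structure(list(order = order, mode = "naive_bayes",
                 mean_accuracy = mean(run$per_bout),
                 per_bout = run$per_bout, reps = config$kfold_reps,
                 n_scoreable = run$n_scoreable,
                 se = sd(run$per_bout) / sqrt(length(run$per_bout))),
            class = "accuracy_report")
}
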