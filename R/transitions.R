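# --- internal helpers -------------------------------------------------------

# vocabulary = sorted unique non-marker tokens over a list of sequences
seq_vocabulary <- function(seqs) {
  toks <- unlist(seqs, use.names = FALSE)
  sort(unique(toks[!is_marker(toks)]))
}

# fast first-order count matrix over a fixed vocabulary; windows never span
# markers or sequence boundaries
count_matrix1 <- function(seqs, vocab) {
  V <- length(vocab)
  M <- matrix(0, V, V, dimnames = list(vocab, vocab))
  idx <- unlist(lapply(seqs, function(s) c(match(s, vocab), NA_integer_)),
                use.names = FALSE)
  n <- length(idx)
  if (n < 2) return(M)
  a <- idx[-n]
  b <- idx[-1]
  ok <- !is.na(a) & !is.na(b)
  if (any(ok)) {
    tb <- tabulate((a[ok] - 1L) * V + b[ok], nbins = V * V)
    M[] <- matrix(tb, V, V, byrow = TRUE)
  }
  M
}

row_probs <- function(M) {
  tot <- rowSums(M)
  P <- M / ifelse(tot > 0, tot, 1)
  P[tot == 0, ] <- 0
  P
}

# --- counting ---------------------------------------------------------------

#' Count antecedent-to-consequent transitions
#'
#' Counts adjacent `(antecedent tuple, consequent)` pairs within each
#' sequence. The antecedent is the `order` immediately preceding elements
#' (joined with `/` for display, e.g. `StareAt/Hit`); the consequent is
#' always a single element. Windows never span a `BREAK`, a `MISSING`, or a
#' sequence boundary — a transition across a pause is not a transition.
#'
#' @param sequences A list of linearized token sequences (see
#'   [linearize()]), or a single character vector.
#' @param order Number of antecedent elements, 1 to 3. Longer antecedents
#'   are not supported: the combinatorial space outgrows any realistic
#'   sample.
#' @return An object of class `transition_counts`: list with `order`,
#'   `counts` (data frame `antecedent,consequent,count`) and `vocabulary`.
#' @export
count_transitions <- function(sequences, order = 1) {
  if (!order %in% 1:3)
    stop("unsupported order ", order, ": at most three antecedent elements")
  if (is.character(sequences)) sequences <- list(sequences)
  vocab <- seq_vocabulary(sequences)
  all <- unlist(lapply(sequences, function(s) c(s, rep(BREAK, order))),
                use.names = FALSE)
  n <- length(all)
  empty <- data.frame(antecedent = character(), consequent = character(),
                      count = numeric(), stringsAsFactors = FALSE)
  out <- structure(list(order = order, counts = empty, vocabulary = vocab),
                   class = "transition_counts")
  if (n < order + 1) return(out)
  m <- is_marker(all)
  ci <- (order + 1):n
  valid <- !m[ci]
  for (k in seq_len(order)) valid <- valid & !m[ci - k]
  if (!any(valid)) return(out)
  ci <- ci[valid]
  ante <- if (order == 1) all[ci - 1] else
    do.call(paste, c(lapply(order:1, function(k) all[ci - k]),
                     list(sep = TUPLE_SEP)))
  key <- paste(ante, all[ci], sep = "\x1f")
  tb <- table(key)
  parts <- strsplit(names(tb), "\x1f", fixed = TRUE)
  out$counts <- data.frame(
    antecedent = vapply(parts, `[`, "", 1),
    consequent = vapply(parts, `[`, "", 2),
    count = as.numeric(tb), stringsAsFactors = FALSE)
  out
}

#' Average transition counts over a linearization ensemble
#'
#' Elementwise mean of the per-linearization transition counts. Because
#' co-occurring elements are ordered at random in each linearization, the
#' averaged counts are in general fractional.
#'
#' @param ensemble A list of linearizations from [linearize_ensemble()].
#' @param order Antecedent length, 1 to 3.
#' @return A `transition_counts` object with fractional counts.
#' @export
average_counts <- function(ensemble, order = 1) {
  if (length(ensemble) == 0) stop("empty linearization ensemble")
  per <- lapply(ensemble, count_transitions, order = order)
  vocab <- per[[1]]$vocabulary
  for (p in per)
    if (!identical(p$vocabulary, vocab))
      stop("internal error: inconsistent vocabularies across linearizations")
  big <- do.call(rbind, lapply(per, `[[`, "counts"))
  key <- paste(big$antecedent, big$consequent, sep = "\x1f")
  s <- rowsum(big$count, key) / length(ensemble)
  parts <- strsplit(rownames(s), "\x1f", fixed = TRUE)
  counts <- data.frame(
    antecedent = vapply(parts, `[`, "", 1),
    consequent = vapply(parts, `[`, "", 2),
    count = as.numeric(s), stringsAsFactors = FALSE)
  counts <- counts[base::order(counts$antecedent, counts$consequent), ]
  rownames(counts) <- NULL
  structure(list(order = order, counts = counts, vocabulary = vocab),
            class = "transition_counts")
}

#' Conditional transition probabilities
#'
#' Each transition count is divided by the total number of times any element
#' followed its antecedent, giving the conditional probability of the
#' consequent given the antecedent. Antecedents that were never followed by
#' anything are omitted.
#'
#' @param counts A `transition_counts` object.
#' @return An object of class `transition_probabilities`: list with `order`,
#'   `probs` (data frame `antecedent,consequent,count,prob`) and
#'   `vocabulary`.
#' @export
conditional_probabilities <- function(counts) {
  df <- counts$counts
  if (nrow(df)) {
    tot <- rowsum(df$count, df$antecedent)
    df$prob <- df$count / tot[df$antecedent, 1]
  } else df$prob <- numeric()
  structure(list(order = counts$order, probs = df,
                 vocabulary = counts$vocabulary),
            class = "transition_probabilities")
}

#' Square matrix view of first-order transitions
#'
#' @param x A `transition_counts` or `transition_probabilities` object of
#'   order 1.
#' @param value `"count"` or `"prob"`.
#' @return A vocabulary-by-vocabulary numeric matrix.
#' @export
transition_matrix <- function(x, value = c("count", "prob")) {
  value <- match.arg(value)
  if (x$order != 1) stop("matrix view is defined for order-1 tables")
  df <- if (inherits(x, "transition_probabilities")) x$probs else x$counts
  if (value == "prob" && is.null(df$prob))
    stop("no probabilities: call conditional_probabilities() first")
  v <- x$vocabulary
  M <- matrix(0, length(v), length(v), dimnames = list(v, v))
  if (nrow(df))
    M[cbind(match(df$antecedent, v), match(df$consequent, v))] <- df[[value]]
  M
}

# --- permutation null -------------------------------------------------------

# one null randomisation: reassign non-marker tokens uniformly at random to
# the non-marker slots (markers and per-sequence slot counts fixed); scope
# "across" pools tokens over all sequences, "within" shuffles per sequence
permute_slots <- function(seqs, scope = "across") {
  lens <- lengths(seqs)
  flat <- unlist(seqs, use.names = FALSE)
  nm <- !is_marker(flat)
  if (scope == "across") {
    flat[nm] <- sample(flat[nm])
  } else {
    grp <- rep(seq_along(lens), lens)
    for (ix in split(which(nm), grp[nm])) flat[ix] <- sample(flat[ix])
  }
  unname(split(flat, factor(rep(seq_along(lens), lens),
                            levels = seq_along(lens))))
}

#' Permutation test of transitions against a bout-preserving null
#'
#' Tests whether elements follow specific antecedents more often than
#' expected if elements were strung together at random given their base
#' probabilities. Each randomisation linearizes the observed bouts afresh
#' (so co-occurrence noise is folded into the null), then reassigns all
#' non-marker tokens uniformly at random to the non-marker slots — across
#' bouts by default — while the number of elements per bout, the global
#' element frequencies, and the positions of `BREAK`/`MISSING` markers stay
#' exactly fixed. The p-value of a transition is the fraction of
#' randomisations whose transition probability reaches or exceeds the
#' observed value (ties count against significance). A transition is flagged
#' significant if `p <= alpha` and its observed (fractional) count reaches
#' `min_transition_count`.
#'
#' @param bouts Pre-processed [individual_bout()]s (lumped and collapsed).
#' @param config A [play_config()]; uses `n_linearizations`,
#'   `n_permutations`, `alpha`, `min_transition_count`,
#'   `permutation_scope`, `rng_seed`.
#' @param seed Optional override of `config$rng_seed`.
#' @return Object of class `transition_tests`: data frame with columns
#'   `antecedent`, `consequent`, `observed_count`, `observed_prob`,
#'   `null_exceed_count`, `p_value`, `significant`.
#' @export
permutation_null <- function(bouts, config = play_config(), seed = NULL) {
  seed <- seed %||% config$rng_seed
  n_perm <- config$n_permutations
  if (n_perm < 100)
    warning("fewer than 100 permutations: p-values will be unstable")
  vocab <- sort(unique(unlist(lapply(bouts, bout_tokens), use.names = FALSE)))
  V <- length(vocab)
  if (V == 0) stop("no element tokens in bouts")

  Mobs <- matrix(0, V, V, dimnames = list(vocab, vocab))
  for (i in seq_len(config$n_linearizations)) {
    set.seed(derive_seed(seed, "observed-linearization", i))
    Mobs <- Mobs + count_matrix1(lapply(bouts, linearize), vocab)
  }
  Mobs <- Mobs / config$n_linearizations
  Pobs <- row_probs(Mobs)

  exceed <- matrix(0L, V, V, dimnames = list(vocab, vocab))
  for (p in seq_len(n_perm)) {
    set.seed(derive_seed(seed, "permutation", p))
    seqs2 <- permute_slots(lapply(bouts, linearize),
                           config$permutation_scope)
    Pp <- row_probs(count_matrix1(seqs2, vocab))
    exceed <- exceed + (Pp >= Pobs - 1e-12)
  }

  keep <- which(Mobs > 0, arr.ind = TRUE)
  res <- data.frame(
    antecedent = vocab[keep[, 1]],
    consequent = vocab[keep[, 2]],
    observed_count = Mobs[keep],
    observed_prob = Pobs[keep],
    null_exceed_count = as.integer(exceed[keep]),
    stringsAsFactors = FALSE)
  res$p_value <- res$null_exceed_count / n_perm
  res$significant <- res$p_value <= config$alpha &
    res$observed_count >= config$min_transition_count
  res <- res[order(res$antecedent, res$consequent), ]
  rownames(res) <- NULL
  structure(res, class = c("transition_tests", "data.frame"),
            alpha = config$alpha,
            min_transition_count = config$min_transition_count,
            n_permutations = n_perm, vocabulary = vocab)
}

#' Keep only significant, sufficiently frequent transitions
#'
#' Retains transitions that occurred at least `min_transition_count` times
#' (fractional counts included) and were significant at the `alpha` level.
#'
#' @param results A `transition_tests` object from [permutation_null()].
#' @param config A [play_config()].
#' @return The filtered `transition_tests`.
#' @export
filter_significant <- function(results, config = play_config()) {
  keep <- results$p_value <= config$alpha &
    results$observed_count >= config$min_transition_count
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- config$alpha
  attr(out, "min_transition_count") <- config$min_transition_count
  attr(out, "vocabulary") <- attr(results, "vocabulary")
  attr(out, "n_permutations") <- attr(results, "n_permutations")
  class(out) <- class(results)
  out
}

# --- bootstrap --------------------------------------------------------------

#' Bootstrap robustness intervals for transition probabilities
#'
#' Resamples individual-bouts with replacement (the natural exchangeable
#' unit), re-estimates first-order transition probabilities in each
#' resample, and summarises each transition by its 2.5th and 97.5th
#' percentile and their range. Transitions of rare antecedents are volatile:
#' the antecedent occurrence count is attached so that interval width can be
#' plotted against it.
#'
#' @param bouts Pre-processed [individual_bout()]s.
#' @param config A [play_config()]; uses `n_bootstrap`, `n_linearizations`,
#'   `rng_seed`.
#' @param seed Optional override of `config$rng_seed`.
#' @return Object of class `bootstrap_intervals`: data frame with columns
#'   `antecedent`, `consequent`, `observed_prob`, `pct_2_5`, `pct_97_5`,
#'   `range` (percentile difference), `range_minmax` (highest minus lowest
#'   bootstrap probability), `antecedent_occurrences`, `n_defined`
#'   (replicates in which the antecedent occurred).
#' @export
bootstrap_intervals <- function(bouts, config = play_config(), seed = NULL) {
  if (length(bouts) < 1) stop("need at least one individual-bout")
  seed <- seed %||% config$rng_seed
  vocab <- sort(unique(unlist(lapply(bouts, bout_tokens), use.names = FALSE)))
  V <- length(vocab)

  Mobs <- matrix(0, V, V, dimnames = list(vocab, vocab))
  for (i in seq_len(config$n_linearizations)) {
    set.seed(derive_seed(seed, "bootstrap-observed", i))
    Mobs <- Mobs + count_matrix1(lapply(bouts, linearize), vocab)
  }
  Mobs <- Mobs / config$n_linearizations
  Pobs <- row_probs(Mobs)
  pairs <- which(Mobs > 0, arr.ind = TRUE)
  np <- nrow(pairs)
  if (np == 0) stop("no transitions observed")

  reps <- config$n_bootstrap
  B <- matrix(NA_real_, reps, np)
  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, "bootstrap-resample", r))
    idx <- sample.int(length(bouts), replace = TRUE)
    seqs <- lapply(bouts[idx], linearize)
    M <- count_matrix1(seqs, vocab)
    tot <- rowSums(M)
    P <- M / ifelse(tot > 0, tot, 1)
    P[tot == 0, ] <- NA_real_
    B[r, ] <- P[pairs]
  }

  occ <- table(factor(unlist(lapply(bouts, bout_tokens), use.names = FALSE),
                      levels = vocab))
  lo <- apply(B, 2, quantile, probs = 0.025, na.rm = TRUE, names = FALSE)
  hi <- apply(B, 2, quantile, probs = 0.975, na.rm = TRUE, names = FALSE)
  mn <- suppressWarnings(apply(B, 2, min, na.rm = TRUE))
  mx <- suppressWarnings(apply(B, 2, max, na.rm = TRUE))
  res <- data.frame(
    antecedent = vocab[pairs[, 1]],
    consequent = vocab[pairs[, 2]],
    observed_prob = Pobs[pairs],
    pct_2_5 = lo, pct_97_5 = hi,
    range = hi - lo,
    range_minmax = ifelse(is.finite(mx - mn), mx - mn, NA_real_),
    antecedent_occurrences = as.numeric(occ[pairs[, 1]]),
    n_defined = colSums(!is.na(B)),
    stringsAsFactors = FALSE)
  res <- res[order(res$antecedent, res$consequent), ]
  rownames(res) <- NULL
  structure(res, class = c("bootstrap_intervals", "data.frame"),
            n_bootstrap = reps)
}
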