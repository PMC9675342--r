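# mean of a lognormal truncated to [a, b] (closed form)
trunc_lnorm_mean <- function(mu, s, a, b) {
  la <- (log(a) - mu) / s
  lb <- (log(b) - mu) / s
  exp(mu + s^2 / 2) * (pnorm(lb - s) - pnorm(la - s)) / (pnorm(lb) - pnorm(la))
}

# draw integer bout lengths from a lognormal truncated to [min, max] whose
# truncated mean matches `mean`; meanlog is solved once by root finding
draw_bout_lengths <- function(n, mean = 30.3, min = 3, max = 181,
                              sdlog = 0.8) {
  mu <- uniroot(function(m) trunc_lnorm_mean(m, sdlog, min, max) - mean,
                c(log(min), log(max)))$root
  out <- integer(0)
  while (length(out) < n) {
    x <- round(rlnorm(2 * (n - length(out)) + 10, mu, sdlog))
    out <- c(out, x[x >= min & x <= max])
  }
  out[seq_len(n)]
}

#' Planted game structure for synthetic play sequences
#'
#' Builds a ground-truth repertoire partitioned into "games": clusters of
#' elements that transition into each other far more than into outsiders.
#' Each element's transition row places `within_mass` uniformly on its own
#' game's elements (self-loops included by default) and the remainder
#' uniformly on all other elements. Defaults emulate the scale of a detailed
#' play ethogram: 6 games of about 10 elements (about 60 elements in
#' total), seven of them continuously-coded states, bout lengths 3 to 181
#' with mean 30.3.
#'
#' @param n_games Number of games.
#' @param elements_per_game Elements per game (at least 2 unless self-loops
#'   are enabled).
#' @param within_mass Probability mass each row places within its own game.
#' @param self_loops Whether an element may follow itself.
#' @param n_state_elements How many elements (spread across games) behave
#'   as continuous states that persist across steps.
#' @param cooccur_rate Probability that a generated element shares its
#'   onset with the previous one.
#' @param break_rate Probability of inserting a `BREAK` after a step.
#' @param n_bouts Default number of bouts for [simulate_bouts()].
#' @param players_min,players_max Range of players per bout.
#' @param state_persist Per-step continuation probability of an active
#'   state element.
#' @param bout_length_mean,bout_length_min,bout_length_max,bout_length_sdlog
#'   Truncated-lognormal bout length distribution (token count per player).
#' @return Object of class `ground_truth`: list with `elements`,
#'   `game_memberships`, `transition_matrix`, `base_probs`,
#'   `state_elements`, `generator_params`, `order = 1`.
#' @export
make_game_structure <- function(n_games = 6, elements_per_game = 10,
                                within_mass = 0.9, self_loops = TRUE,
                                n_state_elements = 7,
                                cooccur_rate = 0.1, break_rate = 0.05,
                                n_bouts = 300, players_min = 2,
                                players_max = 4, state_persist = 0.5,
                                bout_length_mean = 30.3,
                                bout_length_min = 3, bout_length_max = 181,
                                bout_length_sdlog = 0.8) {
  stopifnot(n_games >= 1, within_mass > 0, within_mass <= 1)
  if (elements_per_game < 2 && !self_loops)
    stop("elements_per_game < 2 requires self-loops")
  V <- n_games * elements_per_game
  elements <- sprintf("g%02de%02d", rep(seq_len(n_games),
                                        each = elements_per_game),
                      rep(seq_len(elements_per_game), n_games))
  games <- setNames(rep(seq_len(n_games), each = elements_per_game),
                    elements)
  n_state_elements <- min(n_state_elements, V)
  # spread state elements across games so run collapse touches each cluster
  state_idx <- ((seq_len(n_state_elements) - 1) %% n_games) *
    elements_per_game + ((seq_len(n_state_elements) - 1) %/% n_games) + 1
  if (n_state_elements > 0 && elements_per_game < 2)
    stop("state elements need at least 2 elements per game")
  Tm <- matrix(0, V, V, dimnames = list(elements, elements))
  for (i in seq_len(V)) {
    within <- which(games == games[i])
    # a continuous state cannot re-initiate while active, so state rows
    # carry no self-loop mass; event rows keep self-loops if requested
    if (!self_loops || i %in% state_idx) within <- setdiff(within, i)
    outside <- setdiff(seq_len(V), which(games == games[i]))
    Tm[i, within] <- within_mass / length(within)
    if (length(outside))
      Tm[i, outside] <- (1 - within_mass) / length(outside)
    else
      Tm[i, within] <- Tm[i, within] / sum(Tm[i, within])
  }
  structure(list(
    elements = elements,
    game_memberships = games,
    transition_matrix = Tm,
    transition_tensor = NULL,
    base_probs = setNames(rep(1 / V, V), elements),
    state_elements = elements[state_idx],
    order = 1L,
    generator_params = list(
      n_games = n_games, elements_per_game = elements_per_game,
      within_mass = within_mass, self_loops = self_loops,
      cooccur_rate = cooccur_rate, break_rate = break_rate,
      n_bouts = n_bouts, players_min = players_min,
      players_max = players_max, state_persist = state_persist,
      bout_length = list(mean = bout_length_mean, min = bout_length_min,
                         max = bout_length_max, sdlog = bout_length_sdlog))),
    class = "ground_truth")
}

#' Ground truth with second-order transition structure
#'
#' A variant generator in which the consequent depends on the previous two
#' elements: each ordered pair of antecedents has one preferred consequent
#' (a pseudo-random but fixed map) receiving probability `p_preferred`, the
#' rest uniform. First-order and zero-order models can only capture the
#' marginals, so prediction accuracy should rise strictly from order 0 to 1
#' to 2 on data simulated from it.
#'
#' @param n_elements Repertoire size.
#' @param p_preferred Probability of the preferred consequent.
#' @param seed Seed fixing the preferred-consequent map.
#' @inheritParams make_game_structure
#' @return A `ground_truth` with `order = 2` and a `transition_tensor`
#'   (rows = antecedent pairs `a/b`).
#' @export
make_order2_structure <- function(n_elements = 20, p_preferred = 0.5,
                                  seed = 1L, cooccur_rate = 0.1,
                                  break_rate = 0.05, n_bouts = 100,
                                  players_min = 2, players_max = 4,
                                  bout_length_mean = 30.3,
                                  bout_length_min = 3,
                                  bout_length_max = 181,
                                  bout_length_sdlog = 0.8) {
  elements <- sprintf("e%02d", seq_len(n_elements))
  V <- n_elements
  set.seed(seed)
  keys <- as.vector(outer(elements, elements,
                          function(a, b) paste(a, b, sep = TUPLE_SEP)))
  pref <- sample.int(V, length(keys), replace = TRUE)
  T2 <- matrix((1 - p_preferred) / (V - 1), length(keys), V,
               dimnames = list(keys, elements))
  T2[cbind(seq_along(keys), pref)] <- p_preferred
  structure(list(
    elements = elements,
    game_memberships = setNames(rep(1L, V), elements),
    transition_matrix = NULL,
    transition_tensor = T2,
    base_probs = setNames(rep(1 / V, V), elements),
    state_elements = character(),
    order = 2L,
    generator_params = list(
      p_preferred = p_preferred, cooccur_rate = cooccur_rate,
      break_rate = break_rate, n_bouts = n_bouts,
      players_min = players_min, players_max = players_max,
      state_persist = 0,
      bout_length = list(mean = bout_length_mean, min = bout_length_min,
                         max = bout_length_max, sdlog = bout_length_sdlog))),
    class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground truth: %d elements, %d game(s), order %d\n",
              length(x$elements), length(unique(x$game_memberships)),
              x$order))
  invisible(x)
}

# assemble a token chain into an individual-bout: co-occurrence grouping,
# breaks, state persistence (uses the current random stream)
assemble_bout <- function(tokens, params, states, bout_id, player_id) {
  L <- length(tokens)
  step_of <- integer(L)
  step_of[1] <- 1
  if (L > 1) for (i in 2:L) {
    prev_alone <- i == 2 || step_of[i - 1] > step_of[i - 2]
    # a state cannot still be active when it re-initiates, so never group a
    # token into a state's step when that same state follows next
    state_clash <- i < L && tokens[i - 1] %in% states &&
      tokens[i + 1] == tokens[i - 1]
    co <- runif(1) < params$cooccur_rate && prev_alone && !state_clash &&
      tokens[i] != tokens[i - 1]                           # max 2 per step
    step_of[i] <- if (co) step_of[i - 1] else step_of[i - 1] + 1
  }
  steps <- unname(split(tokens, factor(step_of, levels = unique(step_of))))
  # breaks between steps, inserted before persistence so that a break
  # genuinely interrupts state activity
  if (params$break_rate > 0 && length(steps) > 1) {
    brk <- runif(length(steps) - 1) < params$break_rate
    out <- list(steps[[1]])
    for (j in 2:length(steps)) {
      if (brk[j - 1]) out <- c(out, list(BREAK))
      out <- c(out, list(steps[[j]]))
    }
    steps <- out
  }
  # state persistence: an initiated state stays listed in following steps
  # for a geometric number of steps; activity ends at a break, and never
  # swallows a later genuine re-initiation of the same element
  if (length(states)) {
    chain_steps <- steps                  # snapshot: initiation steps only
    for (j in seq_along(chain_steps)) {
      s <- chain_steps[[j]]
      if (any(is_marker(s))) next
      for (e in intersect(s, states)) {
        g <- rgeom(1, max(1 - params$state_persist, 1e-6))
        if (g > 0) for (jj in (j + 1):(j + g)) {
          if (jj > length(steps) || any(is_marker(chain_steps[[jj]])))
            break
          nxt <- if (jj + 1 <= length(chain_steps))
            chain_steps[[jj + 1]] else character()
          if (e %in% chain_steps[[jj]] || e %in% nxt) break
          if (!e %in% steps[[jj]]) steps[[jj]] <- c(steps[[jj]], e)
        }
      }
    }
  }
  individual_bout(bout_id, player_id, seq_along(steps), steps)
}

# one player's token chain from the ground truth
simulate_chain <- function(truth, L) {
  v <- truth$elements
  if (truth$order == 1) {
    Tm <- truth$transition_matrix
    toks <- character(L)
    toks[1] <- sample(v, 1, prob = truth$base_probs)
    if (L > 1) for (i in 2:L)
      toks[i] <- sample(v, 1, prob = Tm[toks[i - 1], ])
  } else {
    T2 <- truth$transition_tensor
    toks <- character(L)
    toks[1] <- sample(v, 1, prob = truth$base_probs)
    if (L > 1) toks[2] <- sample(v, 1, prob = truth$base_probs)
    if (L > 2) for (i in 3:L)
      toks[i] <- sample(v, 1,
                        prob = T2[paste(toks[i - 2], toks[i - 1],
                                        sep = TUPLE_SEP), ])
  }
  toks
}

#' Simulate individual-bouts from a ground truth
#'
#' Each bout involves 2 to 4 players; every player contributes an
#' independent token chain drawn from the planted transition structure
#' (partner behaviour is treated as noise by the analysis, so players are
#' generated independently). Chains are dressed with the coding artefacts
#' the pre-processing stage must undo: co-occurring onsets, persisting
#' state elements, and `BREAK` markers.
#'
#' @param truth A [make_game_structure()] / [make_order2_structure()]
#'   result.
#' @param n_bouts Number of (multi-player) bouts; default from the truth's
#'   generator parameters.
#' @param seed Master seed.
#' @return A list of [individual_bout()]s.
#' @export
simulate_bouts <- function(truth, n_bouts = NULL, seed = 1L) {
  p <- truth$generator_params
  n_bouts <- n_bouts %||% p$n_bouts
  set.seed(derive_seed(seed, "simulate-bouts"))
  out <- list()
  ks <- p$players_min:p$players_max
  for (b in seq_len(n_bouts)) {
    k <- ks[sample.int(length(ks), 1)]
    for (pl in seq_len(k)) {
      L <- draw_bout_lengths(1, p$bout_length$mean, p$bout_length$min,
                             p$bout_length$max, p$bout_length$sdlog)
      toks <- simulate_chain(truth, L)
      out[[length(out) + 1]] <- assemble_bout(
        toks, p, truth$state_elements,
        sprintf("b%04d", b), sprintf("p%d", pl))
    }
  }
  out
}

#' Simulate structureless (null) individual-bouts
#'
#' Tokens are drawn i.i.d. from the base probabilities, with the same
#' bout-shape machinery (lengths, players, co-occurrence, breaks) as
#' [simulate_bouts()] but no transition structure and, by default, no
#' persisting states: no transition exceeds chance, so a calibrated test
#' should flag about `alpha` of them.
#'
#' @param base_probs Named probability vector over elements.
#' @param n_bouts Number of bouts.
#' @param cooccur_rate,break_rate,players_min,players_max,bout_length_mean,bout_length_min,bout_length_max,bout_length_sdlog
#'   Bout-shape parameters as in [make_game_structure()].
#' @param state_elements Elements given persisting-state behaviour
#'   (default none).
#' @param state_persist Per-step continuation probability.
#' @param seed Master seed.
#' @return A list of [individual_bout()]s.
#' @export
simulate_null_bouts <- function(base_probs, n_bouts = 200,
                                cooccur_rate = 0.1, break_rate = 0.05,
                                players_min = 2, players_max = 4,
                                bout_length_mean = 30.3,
                                bout_length_min = 3, bout_length_max = 181,
                                bout_length_sdlog = 0.8,
                                state_elements = character(),
                                state_persist = 0.5, seed = 1L) {
  stopifnot(abs(sum(base_probs) - 1) < 1e-9, !is.null(names(base_probs)))
  p <- list(cooccur_rate = cooccur_rate, break_rate = break_rate,
            state_persist = state_persist,
            bout_length = list(mean = bout_length_mean,
                               min = bout_length_min,
                               max = bout_length_max,
                               sdlog = bout_length_sdlog))
  set.seed(derive_seed(seed, "simulate-null"))
  out <- list()
  ks <- players_min:players_max
  for (b in seq_len(n_bouts)) {
    k <- ks[sample.int(length(ks), 1)]
    for (pl in seq_len(k)) {
      L <- draw_bout_lengths(1, bout_length_mean, bout_length_min,
                             bout_length_max, bout_length_sdlog)
      toks <- sample(names(base_probs), L, replace = TRUE,
                     prob = base_probs)
      out[[length(out) + 1]] <- assemble_bout(
        toks, p, state_elements, sprintf("b%04d", b), sprintf("p%d", pl))
    }
  }
  out
}

#' Minimal ethogram matching a ground truth
#'
#' Builds the ethogram the synthetic data implies: all elements in category
#' `non-contact`, the designated state elements flagged as continuous
#' states, no lump targets.
#'
#' @param truth A `ground_truth`.
#' @return An [ethogram()].
#' @export
truth_ethogram <- function(truth) {
  ethogram(data.frame(
    name = truth$elements, category = "non-contact",
    kind = ifelse(truth$elements %in% truth$state_elements, "state",
                  "event"),
    is_continuous_state = truth$elements %in% truth$state_elements,
    lump_target = NA_character_, stringsAsFactors = FALSE))
}
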