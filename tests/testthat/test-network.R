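fake_tests <- function(df) {
  df$significant <- rep(TRUE, nrow(df))
  structure(df, class = c("transition_tests", "data.frame"))
}

test_that("networks keep directed edges, self-loops and isolates", {
  tests <- fake_tests(data.frame(
    antecedent = c("A", "B", "C"), consequent = c("B", "A", "C"),
    observed_count = c(7, 6, 9), observed_prob = c(0.3, 0.2, 0.5),
    null_exceed_count = 0L, p_value = 0))
  nw <- build_network(tests, elements = c("A", "B", "C", "D"))
  expect_equal(nrow(nw$edges), 3)
  expect_equal(sum(nw$edges$source == nw$edges$target), 1)  # C self-loop
  expect_setequal(nw$nodes, c("A", "B", "C"))
  expect_equal(nw$isolates, "D")

  bad <- tests
  bad$significant[2] <- FALSE
  expect_error(build_network(bad), "significance filter")
  expect_warning(nw0 <- build_network(fake_tests(tests[0, ])), "empty")
  expect_length(nw0$nodes, 0)
})

# two unit-weight triangles joined by one bridge edge
triangle_bridge <- function() {
  tests <- fake_tests(data.frame(
    antecedent  = c("a", "b", "c", "d", "e", "f", "a"),
    consequent  = c("b", "c", "a", "e", "f", "d", "d"),
    observed_count = 10, observed_prob = 1, null_exceed_count = 0L,
    p_value = 0))
  build_network(tests)
}

test_that("modularity matches hand-computed and closed-form values", {
  nw <- triangle_bridge()
  memb <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L), letters[1:6])
  expect_equal(modularity_q(nw, memb), 2 * (3 / 7 - (7 / 14)^2))  # 5/14
  # igraph agrees on the symmetrized graph
  g <- as_igraph(nw, "collapsed")
  expect_equal(modularity_q(nw, memb),
               igraph::modularity(g, memb[igraph::V(g)$name],
                                  weights = igraph::E(g)$weight))
  # one community: Q = 0 (self-loops excluded)
  expect_equal(modularity_q(nw, setNames(rep(1L, 6), letters[1:6])), 0)
  expect_error(modularity_q(nw, memb[1:3]), "cover")

  # perfect two-block structure: Q = 0.5
  tests <- fake_tests(data.frame(
    antecedent = c("a", "b", "c", "d"), consequent = c("b", "a", "d", "c"),
    observed_count = 10, observed_prob = 1, null_exceed_count = 0L,
    p_value = 0))
  nw2 <- build_network(tests)
  memb2 <- setNames(c(1L, 1L, 2L, 2L), letters[1:4])
  expect_equal(modularity_q(nw2, memb2), 0.5)
})

test_that("community detection finds the exact modularity optimum", {
  nw <- triangle_bridge()
  cfg <- play_config()
  part <- detect_communities(nw, cfg)
  expect_equal(part$method, "exhaustive")
  expect_equal(part$modularity, 5 / 14)
  expect_length(unique(part$memberships), 2)
  expect_equal(part$memberships[["a"]], part$memberships[["b"]])
  expect_true(part$acceptable)

  # exhaustive enumeration agrees with igraph's exact ILP maximizer
  set.seed(60)
  for (i in 1:10) {
    n <- sample(4:7, 1)
    W <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    for (a in 1:(n - 1)) for (b in (a + 1):n)
      if (runif(1) < 0.5) W[a, b] <- round(runif(1, 0.1, 1), 2)
    if (sum(W) == 0) next
    e <- which(W > 0, arr.ind = TRUE)
    tests <- fake_tests(data.frame(
      antecedent = rownames(W)[e[, 1]], consequent = colnames(W)[e[, 2]],
      observed_count = 10, observed_prob = W[e], null_exceed_count = 0L,
      p_value = 0))
    nwi <- build_network(tests)
    exh <- detect_communities(nwi, cfg, method = "exhaustive")
    ilp <- detect_communities(nwi, cfg, method = "ilp")
    expect_equal(exh$modularity, ilp$modularity, tolerance = 1e-9)
  }
})

test_that("within-community transition fractions behave at the null and planted limits", {
  seqs <- list(c("a", "b", "a", "c", BREAK, "d", "e"),
               c("d", "e", "d", "b"))
  one <- setNames(rep(1L, 5), letters[1:5])
  fr <- community_transition_fractions(seqs, one, n_label_perms = 50,
                                       seed = 1)
  expect_equal(fr$observed_within, 1)
  expect_equal(fr$expected_within, 1)
  expect_equal(fr$ratio, 1)
  expect_equal(fr$n_transitions, 7)  # BREAK splits one adjacency

  # random labels on the data itself: ratio ~ 1
  set.seed(2)
  seqs2 <- lapply(1:40, function(i) sample(letters[1:6], 30, replace = TRUE))
  rand <- setNames(sample(rep(1:3, each = 2)), letters[1:6])
  fr2 <- community_transition_fractions(seqs2, rand, n_label_perms = 400,
                                        seed = 3)
  expect_lt(abs(fr2$ratio - 1), 0.1)

  # planted 0.9-within-game structure: strong enrichment
  truth <- make_game_structure(n_games = 3, elements_per_game = 5,
                               n_state_elements = 0, n_bouts = 40)
  bouts <- simulate_bouts(truth, seed = 4)
  lin <- linearize_ensemble(bouts, 1, seed = 5)[[1]]
  fr3 <- community_transition_fractions(lin, truth$game_memberships,
                                        n_label_perms = 200, seed = 6)
  expect_gt(fr3$ratio, 1.5)
  expect_error(community_transition_fractions(
    list(c("zz", "qq")), one, 10, 1), "no transitions")
})

test_that("partition agreement indices hit their reference points", {
  a <- setNames(c(1L, 1L, 2L, 2L, 3L, 3L), letters[1:6])
  expect_equal(compare_partitions(a, a)$adjusted_rand, 1)
  expect_equal(compare_partitions(a, a)$nmi, 1)
  singletons <- setNames(1:6, letters[1:6])
  oneblock <- setNames(rep(1L, 6), letters[1:6])
  expect_equal(compare_partitions(singletons, oneblock)$adjusted_rand, 0)
  expect_error(compare_partitions(a, setNames(1L, "zz")), "share no")
  cp <- compare_partitions(a, setNames(c(1L, 1L, 2L, 2L), letters[1:4]))
  expect_equal(cp$n_shared, 4)
})
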