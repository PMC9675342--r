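test_that("transition counting follows adjacency and never spans markers", {
  ct <- count_transitions(list(c("A", "B", "A", "B", BREAK, "A")), 1)
  df <- ct$counts
  expect_equal(df$count[df$antecedent == "A" & df$consequent == "B"], 2)
  expect_equal(df$count[df$antecedent == "B" & df$consequent == "A"], 1)
  expect_equal(sum(df$count), 3)   # nothing across the BREAK

  ct2 <- count_transitions(list(c("A", "B", "C")), 2)
  expect_equal(ct2$counts,
               data.frame(antecedent = "A/B", consequent = "C", count = 1))
  expect_equal(nrow(count_transitions(list("A"), 2)$counts), 0)
  expect_error(count_transitions(list(c("A", "B")), 4), "unsupported")
})

test_that("windows never span sequence boundaries", {
  ct <- count_transitions(list(c("A", "B"), c("C", "D")), 1)
  expect_equal(sort(paste(ct$counts$antecedent, ct$counts$consequent)),
               c("A B", "C D"))
})

test_that("averaging over linearizations yields fractional counts", {
  lin1 <- list(list(c("A", "B", "C")))
  lin2 <- list(list(c("A", "B", "A", "B", "C")))
  avg <- average_counts(c(lin1, lin2), 1)
  ab <- avg$counts
  expect_equal(ab$count[ab$antecedent == "A" & ab$consequent == "B"], 1.5)

  # one bout [{A,B},{C}]: each of A->B, B->A has probability 1/2, and the
  # later of the two always precedes C
  b <- make_bout(list(c("A", "B"), "C"))
  ens <- linearize_ensemble(list(b), 4000, seed = 11)
  avg2 <- transition_matrix(average_counts(ens, 1))
  tol <- 4 * sqrt(0.25 / 4000)
  expect_lt(abs(avg2["A", "B"] - 0.5), tol)
  expect_lt(abs(avg2["B", "A"] - 0.5), tol)
  expect_lt(abs(avg2["A", "C"] - 0.5), tol)
  expect_lt(abs(avg2["B", "C"] - 0.5), tol)
})

test_that("conditional probabilities renormalize rows, fractional included", {
  ct <- structure(list(order = 1, counts = data.frame(
    antecedent = c("A", "A", "B"), consequent = c("B", "C", "B"),
    count = c(1.5, 0.5, 3)), vocabulary = c("A", "B", "C")),
    class = "transition_counts")
  pr <- conditional_probabilities(ct)$probs
  expect_equal(pr$prob[pr$antecedent == "A"], c(0.75, 0.25))
  expect_equal(pr$prob[pr$antecedent == "B"], 1)
  sums <- tapply(pr$prob, pr$antecedent, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("slot permutation preserves bout shapes, markers and frequencies", {
  seqs <- list(c("A", "B", BREAK, "A"), c("C", MISSING, "B", "B"), "A")
  set.seed(5)
  for (scope in c("across", "within")) for (i in 1:25) {
    p <- playseq:::permute_slots(seqs, scope)
    expect_equal(lengths(p), lengths(seqs))
    for (j in seq_along(seqs)) {
      expect_equal(p[[j]] %in% c(BREAK, MISSING),
                   seqs[[j]] %in% c(BREAK, MISSING))
      if (scope == "within")
        expect_equal(sort(p[[j]]), sort(seqs[[j]]))
    }
    expect_equal(sort(unlist(p)), sort(unlist(seqs)))
  }
})

test_that("a single repeated element is never significant", {
  bouts <- token_bouts(list(rep("A", 10), rep("A", 8)))
  cfg <- play_config(n_linearizations = 2, n_permutations = 100,
                     rng_seed = 4)
  tt <- suppressWarnings(permutation_null(bouts, cfg))
  expect_equal(nrow(tt), 1)
  expect_equal(tt$p_value, 1)
  expect_false(tt$significant)
})

test_that("significance filtering applies both the count and alpha rules", {
  tests <- structure(data.frame(
    antecedent = c("A", "B", "C"), consequent = c("B", "C", "A"),
    observed_count = c(7, 4, 12), observed_prob = c(0.3, 0.2, 0.4),
    null_exceed_count = c(4, 1, 20), p_value = c(0.004, 0.001, 0.02),
    significant = c(TRUE, FALSE, FALSE)),
    class = c("transition_tests", "data.frame"))
  out <- filter_significant(tests, play_config())
  expect_equal(nrow(out), 1)
  expect_equal(out$antecedent, "A")  # count 4 and p 0.02 both fail
})

test_that("bootstrap intervals collapse for degenerate data", {
  # resampling a single bout always reproduces it: zero range
  cfg <- play_config(n_linearizations = 2, n_bootstrap = 60, rng_seed = 2)
  single <- token_bouts(list(c("A", "B", "A", "B")))
  bi <- bootstrap_intervals(single, cfg)
  expect_true(all(bi$range == 0))
  expect_true(all(bi$range_minmax == 0))

  # deterministic A->B in every bout: interval [1, 1]
  many <- token_bouts(rep(list(c("A", "B")), 6))
  bi2 <- bootstrap_intervals(many, cfg)
  ab <- bi2[bi2$antecedent == "A" & bi2$consequent == "B", ]
  expect_equal(ab$pct_2_5, 1)
  expect_equal(ab$pct_97_5, 1)
  expect_equal(ab$range, 0)
  expect_equal(ab$antecedent_occurrences, 6)
})

test_that("rare antecedents have wider bootstrap intervals than common ones", {
  set.seed(31)
  # common antecedent A (stable 50/50), rare antecedent R seen twice
  bouts <- token_bouts(c(
    lapply(1:30, function(i) c("A", sample(c("B", "C"), 1))),
    list(c("R", "B"), c("R", "C"))))
  cfg <- play_config(n_linearizations = 2, n_bootstrap = 200, rng_seed = 6)
  bi <- bootstrap_intervals(bouts, cfg)
  r_rng <- max(bi$range[bi$antecedent == "R"])
  a_rng <- max(bi$range[bi$antecedent == "A"])
  expect_gt(r_rng, a_rng)
})
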