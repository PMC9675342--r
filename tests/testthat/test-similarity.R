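test_that("transition profile rows reproduce the conditional probabilities", {
  probs <- structure(list(order = 1, probs = data.frame(
    antecedent = c("A", "A", "B"), consequent = c("B", "C", "A"),
    count = c(3, 1, 2), prob = c(0.75, 0.25, 1)),
    vocabulary = c("A", "B", "C")), class = "transition_probabilities")
  M <- transition_profile_matrix(probs)
  expect_equal(dim(M), c(3, 3))
  expect_equal(M["A", c("B", "C")], c(B = 0.75, C = 0.25))
  expect_equal(unname(M["B", "A"]), 1)
  expect_equal(attr(M, "unobserved"), "C")   # never an antecedent
  expect_equal(unname(rowSums(M)[c("A", "B")]), c(1, 1))
})

# two groups of near-identical transition profiles, small within-group noise
planted_profiles <- function(n_groups = 2, per_group = 6, seed = 1) {
  set.seed(seed)
  proto <- matrix(runif(n_groups * 8), n_groups, 8)
  proto <- proto / rowSums(proto)
  M <- proto[rep(seq_len(n_groups), each = per_group), ] +
    matrix(rnorm(n_groups * per_group * 8, sd = 0.005),
           n_groups * per_group, 8)
  rownames(M) <- sprintf("el%02d", seq_len(nrow(M)))
  M
}

test_that("embedding separates planted groups and is reproducible", {
  M <- planted_profiles()
  xy1 <- embed_2d(M, epochs = 500, n_neighbors = 5, seed = 42)
  xy2 <- embed_2d(M, epochs = 500, n_neighbors = 5, seed = 42)
  expect_identical(xy1, xy2)
  expect_false(identical(xy1, embed_2d(M, epochs = 500, n_neighbors = 5,
                                       seed = 43)))
  g <- rep(1:2, each = 6)
  d <- as.matrix(dist(xy1))
  within <- d[outer(g, g, "==") & upper.tri(d)]
  between <- d[outer(g, g, "!=")]
  expect_gt(min(between), max(within))
  expect_warning(embed_2d(M[1:6, ], epochs = 50), "n_neighbors reduced")
  expect_error(embed_2d(M[1:3, ]), "at least 4")
})

test_that("silhouette-selected k recovers planted blob counts", {
  set.seed(10)
  blobs <- function(k, per, spread = 0.02) {
    centers <- matrix(runif(k * 2, 0, 10), k, 2)
    pts <- centers[rep(1:k, each = per), ] +
      matrix(rnorm(k * per * 2, sd = spread), k * per, 2)
    rownames(pts) <- sprintf("p%03d", seq_len(k * per))
    pts
  }
  two <- optimal_k(blobs(2, 10), seed = 2)
  expect_equal(two$k, 2)
  expect_gt(two$silhouette, 0.9)
  expect_true(two$acceptable)

  twelve <- optimal_k(blobs(12, 5), seed = 3)
  expect_equal(twelve$k, 12)
  expect_gt(twelve$silhouette, 0.8)

  ident <- optimal_k(matrix(1, 5, 2,
                            dimnames = list(sprintf("p%d", 1:5), NULL)))
  expect_true(ident$degenerate)
  expect_false(ident$acceptable)
})

test_that("dendrogram cuts behave at the extremes and merge close pairs first", {
  pts <- rbind(c(0, 0), c(0, 0.1), c(10, 10), c(10, 10.1))
  rownames(pts) <- c("a1", "a2", "b1", "b2")
  sol <- hierarchical_dendrogram(pts, k = 2)
  expect_equal(sol$memberships[["a1"]], sol$memberships[["a2"]])
  expect_equal(sol$memberships[["b1"]], sol$memberships[["b2"]])
  expect_equal(length(unique(sol$memberships)), 2)
  expect_false(is.unsorted(sol$dendrogram$height))
  expect_equal(length(unique(hierarchical_dendrogram(pts, 1)$memberships)), 1)
  expect_equal(length(unique(hierarchical_dendrogram(pts, 4)$memberships)), 4)
})

test_that("consensus clustering recovers planted game structure", {
  truth <- make_game_structure(n_games = 6, elements_per_game = 8,
                               within_mass = 0.9)
  # perturb the exact rows slightly so elements are not exact duplicates
  set.seed(12)
  M <- truth$transition_matrix +
    matrix(runif(length(truth$transition_matrix), 0, 0.004),
           nrow(truth$transition_matrix))
  M <- M / rowSums(M)
  cfg <- play_config(n_embedding_runs = 5, mean_epochs = 500, rng_seed = 31)
  cons <- consensus_clusters(M, cfg)
  expect_equal(cons$final$k, as.integer(names(which.max(table(cons$runs$k)))))
  ari <- mclust::adjustedRandIndex(cons$final$memberships,
                                   truth$game_memberships[names(cons$final$memberships)])
  expect_gte(ari, 0.9)
  expect_gt(cons$final$silhouette, 0.3)
  # reported silhouette matches an independent recomputation
  sil <- mean(cluster::silhouette(cons$final$memberships,
                                  dist(cons$points))[, 3])
  expect_equal(cons$final$silhouette, sil, tolerance = 1e-9)
  # stability entries are frequencies
  expect_true(all(cons$stability >= 0 & cons$stability <= 1))
  # elements with (near-)identical rows from the same game co-cluster
  memb <- cons$final$memberships
  same_game <- split(names(memb), truth$game_memberships[names(memb)])
  for (g in same_game)
    expect_length(unique(memb[g]), 1)
})

test_that("dendrograms export as newick", {
  pts <- matrix(rnorm(20), 10, 2,
                dimnames = list(sprintf("e%02d", 1:10), NULL))
  sol <- hierarchical_dendrogram(pts, 3)
  f <- withr::local_tempfile(fileext = ".newick")
  write_dendrogram(sol, f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, rownames(pts))
})
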