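#' Matrix of outgoing transition profiles
#'
#' Represents every element by its vector of first-order conditional
#' transition probabilities to all elements. Elements with similar rows are
#' used at similar points in sequences — behavioural "synonyms". Elements
#' never observed as antecedent get a zero row and are flagged in the
#' `unobserved` attribute. Markers are excluded.
#'
#' @param probs A `transition_probabilities` object of order 1 (averaged
#'   over linearizations, typically).
#' @return A square numeric matrix (rows = antecedents, columns =
#'   consequents) with attribute `unobserved`.
#' @export
transition_profile_matrix <- function(probs) {
  if (probs$order != 1) stop("transition profiles use first-order probabilities")
  M <- transition_matrix(probs, "prob")
  attr(M, "unobserved") <- rownames(M)[rowSums(M) == 0]
  M
}

#' Two-dimensional UMAP embedding of transition profiles
#'
#' Projects the transition-profile vectors to two dimensions with UMAP
#' (nearest-neighbour graph plus cross-entropy layout); distances between
#' embedded points are what the clustering operates on. The embedding is
#' deterministic given `seed` (single-threaded optimisation).
#'
#' @param matrix A [transition_profile_matrix()] (any numeric matrix works).
#' @param epochs Optimisation epochs.
#' @param n_neighbors Neighbourhood size; reduced with a warning when there
#'   are fewer points.
#' @param min_dist UMAP minimum embedded distance.
#' @param seed Seed for the embedding.
#' @return An n-by-2 coordinate matrix with the input rownames.
#' @export
embed_2d <- function(matrix, epochs = 7000, n_neighbors = 15,
                     min_dist = 0.1, seed = 1L) {
  n <- nrow(matrix)
  if (n < 4) stop("need at least 4 elements to embed")
  if (n_neighbors > n - 1) {
    warning("n_neighbors reduced to ", n - 1, " (only ", n, " elements)")
    n_neighbors <- n - 1
  }
  set.seed(seed)
  xy <- uwot::umap(matrix, n_components = 2, n_neighbors = n_neighbors,
                   n_epochs = epochs, min_dist = min_dist, init = "pca",
                   n_threads = 1, n_sgd_threads = 0)
  rownames(xy) <- rownames(matrix)
  colnames(xy) <- c("x", "y")
  xy
}

#' Silhouette-optimal number of k-means clusters
#'
#' Runs k-means at every candidate `k` and scores each solution by its mean
#' silhouette on the Euclidean distances of the points; the `k` with the
#' highest silhouette wins. A solution is labelled acceptable when its
#' silhouette exceeds `silhouette_threshold` — above 0.3 there is more
#' similarity within than between clusters.
#'
#' @param points An n-by-2 coordinate matrix (or any numeric matrix).
#' @param k_range Candidate cluster numbers; default `2:min(20, n - 1)`.
#' @param silhouette_threshold Acceptability threshold (default 0.3).
#' @param nstart Random restarts per k-means run.
#' @param seed Seed for the k-means restarts.
#' @return A list with `k`, `silhouette`, `memberships` (named, contiguous
#'   ids), `acceptable`, `degenerate` and `per_k` (silhouette per candidate).
#' @export
optimal_k <- function(points, k_range = NULL, silhouette_threshold = 0.3,
                      nstart = 10, seed = 1L) {
  n <- nrow(points)
  n_distinct <- nrow(unique(points))
  if (n_distinct < 2) {
    return(list(k = 1L, silhouette = NA_real_,
                memberships = setNames(rep(1L, n), rownames(points)),
                acceptable = FALSE, degenerate = TRUE,
                per_k = data.frame(k = integer(), silhouette = numeric())))
  }
  k_range <- k_range %||% 2:min(20, n - 1)
  k_range <- k_range[k_range >= 2 & k_range <= min(n - 1, n_distinct)]
  if (length(k_range) == 0) k_range <- 2L
  d <- dist(points)
  set.seed(seed)
  sols <- lapply(k_range, function(k) {
    km <- NULL
    for (try in 1:5) {  # duplicated points can collide with random centers
      km <- tryCatch(suppressWarnings(
        kmeans(points, centers = k, nstart = nstart, iter.max = 50)),
        error = function(e) NULL)
      if (!is.null(km)) break
    }
    if (is.null(km)) return(list(k = k, sil = -Inf, cl = NULL))
    sil <- mean(cluster::silhouette(km$cluster, d)[, 3])
    list(k = k, sil = sil, cl = km$cluster)
  })
  sils <- vapply(sols, `[[`, 0, "sil")
  if (all(!is.finite(sils))) stop("k-means failed for every candidate k")
  best <- sols[[which.max(sils)]]
  list(k = as.integer(best$k), silhouette = best$sil,
       memberships = setNames(as.integer(best$cl), rownames(points)),
       acceptable = best$sil > silhouette_threshold, degenerate = FALSE,
       per_k = data.frame(k = k_range, silhouette = sils))
}

#' Hierarchical dendrogram of embedded elements
#'
#' Agglomerative (UPGMA average-linkage) clustering on the Euclidean
#' distances of the embedded points, cut at `k` clusters; the cut is scored
#' by its own silhouette so it can be compared with the k-means solution.
#'
#' @param points An n-by-2 coordinate matrix.
#' @param k Number of clusters to cut at (from [optimal_k()], typically).
#' @param method Linkage passed to [stats::hclust()].
#' @return Object of class `cluster_solution`: list with `memberships`,
#'   `k`, `silhouette` (of the cut; `NA` for k = 1 or n), `dendrogram` (the
#'   `hclust` tree).
#' @export
hierarchical_dendrogram <- function(points, k, method = "average") {
  d <- dist(points)
  hc <- hclust(d, method = method)
  memb <- cutree(hc, k = k)
  sil <- if (k > 1 && k < nrow(points))
    mean(cluster::silhouette(memb, d)[, 3]) else NA_real_
  structure(list(memberships = setNames(as.integer(memb), rownames(points)),
                 k = as.integer(k), silhouette = sil, dendrogram = hc),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster solution: k = %d, silhouette = %s\n", x$k,
              format(x$silhouette, digits = 3)))
  invisible(x)
}

#' Consensus clustering over repeated embeddings
#'
#' UMAP layouts vary with their stochastic optimisation, so the embedding
#' and cluster selection are repeated (50 times by default) with epochs
#' drawn uniformly in `[0.5, 1.5]` times `mean_epochs`. The most likely
#' solution is operationalised as the modal `k` across runs; among runs with
#' that `k`, the one with the highest silhouette is reported as final,
#' together with its hierarchical dendrogram and a pairwise co-assignment
#' (stability) matrix over all runs.
#'
#' @param matrix A [transition_profile_matrix()].
#' @param config A [play_config()]; uses `n_embedding_runs`, `mean_epochs`,
#'   `silhouette_threshold`, `rng_seed`.
#' @param seed Optional override of `config$rng_seed`.
#' @return A list with `final` (a `cluster_solution` carrying the k-means
#'   memberships, their silhouette, the hierarchical tree and its cut
#'   silhouette as `silhouette_hierarchical`), `stability` (co-assignment
#'   frequency matrix), `runs` (per-run k, epochs, silhouette) and `points`
#'   (the final run's embedding).
#' @export
consensus_clusters <- function(matrix, config = play_config(), seed = NULL) {
  stopifnot(config$n_embedding_runs >= 2)
  seed <- seed %||% config$rng_seed
  n <- nrow(matrix)
  runs <- vector("list", config$n_embedding_runs)
  co <- matrix(0, n, n, dimnames = list(rownames(matrix), rownames(matrix)))
  for (i in seq_len(config$n_embedding_runs)) {
    s <- derive_seed(seed, "embedding-run", i)
    set.seed(s)
    epochs <- round(runif(1, 0.5, 1.5) * config$mean_epochs)
    pts <- suppressWarnings(
      embed_2d(matrix, epochs = epochs, seed = derive_seed(s, "umap")))
    sol <- optimal_k(pts, silhouette_threshold = config$silhouette_threshold,
                     seed = derive_seed(s, "kmeans"))
    runs[[i]] <- list(k = sol$k, silhouette = sol$silhouette,
                      epochs = epochs, sol = sol, points = pts)
    co <- co + outer(sol$memberships, sol$memberships, "==")
  }
  ks <- vapply(runs, `[[`, 0L, "k")
  modal_k <- as.integer(names(which.max(table(ks))))
  cand <- which(ks == modal_k)
  sils <- vapply(runs[cand], `[[`, 0, "silhouette")
  pick <- if (all(is.na(sils))) runs[[cand[1]]]
          else runs[[cand[which.max(sils)]]]
  hier <- hierarchical_dendrogram(pick$points, modal_k)
  final <- structure(list(memberships = pick$sol$memberships, k = modal_k,
                          silhouette = pick$sol$silhouette,
                          silhouette_hierarchical = hier$silhouette,
                          acceptable = pick$sol$acceptable,
                          dendrogram = hier$dendrogram),
                     class = "cluster_solution")
  list(final = final, stability = co / config$n_embedding_runs,
       runs = data.frame(run = seq_along(runs), k = ks,
                         epochs = vapply(runs, `[[`, 0, "epochs"),
                         silhouette = vapply(runs, `[[`, 0, "silhouette")),
       points = pick$points)
}

#' Export a dendrogram as a newick tree
#'
#' @param solution A `cluster_solution` with a `dendrogram`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(solution, path) {
  phy <- ape::as.phylo(solution$dendrogram)
  ape::write.tree(phy, file = path)
  invisible(path)
}
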