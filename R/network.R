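#' Build the directed network of significant transitions
#'
#' Nodes are play elements, edges the transitions that survived the
#' significance filter (at least `min_transition_count` occurrences and
#' `p <= alpha`), weighted by their conditional transition probability and
#' directed — A-to-B and B-to-A are distinct edges, and self-loops
#' (elements significantly following themselves) are kept. Elements with no
#' significant transition are excluded from the node set and reported as
#' isolates.
#'
#' @param tests A filtered `transition_tests` object (see
#'   [filter_significant()]); construction fails if any row is not
#'   significant.
#' @param elements Optional full element vocabulary used to determine the
#'   isolates; defaults to the vocabulary attribute of `tests`.
#' @return Object of class `transition_network`: list with `nodes`, `edges`
#'   (data frame `source,target,weight,count,p_value`) and `isolates`.
#' @export
build_network <- function(tests, elements = NULL) {
  if (nrow(tests) && !all(tests$significant))
    stop("network edges must all pass the significance filter")
  elements <- elements %||% attr(tests, "vocabulary") %||%
    sort(unique(c(tests$antecedent, tests$consequent)))
  edges <- data.frame(source = tests$antecedent,
                      target = tests$consequent,
                      weight = tests$observed_prob,
                      count = tests$observed_count,
                      p_value = tests$p_value,
                      stringsAsFactors = FALSE)
  if (nrow(edges) == 0) warning("no significant transitions: empty network")
  nodes <- sort(unique(c(edges$source, edges$target)))
  structure(list(nodes = nodes, edges = edges,
                 isolates = sort(setdiff(elements, nodes))),
            class = "transition_network")
}

#' @export
print.transition_network <- function(x, ...) {
  cat(sprintf("transition network: %d nodes, %d directed edges (%d self-loops), %d isolates\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$source == x$edges$target), length(x$isolates)))
  invisible(x)
}

# symmetrized weight matrix: directions collapsed by weight-summing,
# self-loops optionally removed
symmetric_weights <- function(network, drop_loops = TRUE) {
  v <- network$nodes
  W <- matrix(0, length(v), length(v), dimnames = list(v, v))
  e <- network$edges
  if (nrow(e)) {
    idx <- cbind(match(e$source, v), match(e$target, v))
    for (r in seq_len(nrow(e))) W[idx[r, 1], idx[r, 2]] <-
        W[idx[r, 1], idx[r, 2]] + e$weight[r]
  }
  W <- W + t(W)
  diag(W) <- if (drop_loops) 0 else diag(W) / 2
  W
}

#' Convert a transition network to an igraph graph
#'
#' @param network A [build_network()] result.
#' @param mode `"directed"` keeps the stored directed edges; `"collapsed"`
#'   returns the undirected weight-summed graph (self-loops dropped) used
#'   for the modularity objective.
#' @return An igraph object.
#' @export
as_igraph <- function(network, mode = c("directed", "collapsed")) {
  mode <- match.arg(mode)
  if (mode == "directed") {
    g <- igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                       vertices = network$nodes)
  } else {
    W <- symmetric_weights(network, drop_loops = TRUE)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
  }
  g
}

#' Newman-Girvan weighted modularity of a node partition
#'
#' Computed on the symmetrized (direction-collapsed, weight-summed) graph:
#' `Q = sum_c [w_c / m - (s_c / 2m)^2]` where `w_c` is the edge weight
#' inside community `c`, `s_c` the summed strength of its nodes and `m` the
#' total edge weight. Self-loops are excluded — a loop trivially inflates
#' within-community weight without saying anything about structure.
#'
#' @param network A [build_network()] result.
#' @param memberships Named integer vector covering all network nodes.
#' @return The modularity value.
#' @export
modularity_q <- function(network, memberships) {
  v <- network$nodes
  if (!all(v %in% names(memberships)))
    stop("memberships must cover every network node")
  if (length(setdiff(names(memberships), v)))
    stop("memberships contain unknown node(s): ",
         paste(setdiff(names(memberships), v), collapse = ", "))
  W <- symmetric_weights(network, drop_loops = TRUE)
  m <- sum(W) / 2
  if (m == 0) return(0)
  memb <- memberships[v]
  s <- rowSums(W)
  q <- 0
  for (c in unique(memb)) {
    in_c <- memb == c
    q <- q + sum(W[in_c, in_c]) / (2 * m) - (sum(s[in_c]) / (2 * m))^2
  }
  q
}

# all set partitions of n items as restricted-growth strings (n small)
set_partitions <- function(n) {
  grow <- function(prefix, maxv) {
    if (length(prefix) == n) return(list(prefix))
    out <- list()
    for (v in seq_len(maxv + 1))
      out <- c(out, grow(c(prefix, v), max(maxv, v)))
    out
  }
  grow(1L, 1L)
}

#' Modularity-maximizing community detection
#'
#' Finds the node partition maximizing the weighted Newman-Girvan
#' modularity of the symmetrized network. For networks up to
#' `exact_community_limit` nodes every set partition is enumerated, so the
#' returned optimum is exact by construction; larger networks are solved
#' with igraph's `cluster_optimal`, an exact integer-programming maximizer
#' (method `"ilp"`). A multi-start Louvain heuristic (method `"louvain"`)
#' is available for networks too large for the integer program. The
#' partition is labelled acceptable when its modularity exceeds
#' `modularity_threshold`.
#'
#' @param network A [build_network()] result.
#' @param config A [play_config()]; uses `exact_community_limit`,
#'   `modularity_threshold`.
#' @param method `"auto"` (exhaustive below the limit, ILP above),
#'   `"exhaustive"`, `"ilp"` or `"louvain"`.
#' @param seed Seed for the Louvain restarts.
#' @return Object of class `community_partition`: list with `memberships`
#'   (named, contiguous ids), `modularity`, `acceptable`, `method`,
#'   `isolates` (carried over from the network).
#' @export
detect_communities <- function(network, config = play_config(),
                               method = c("auto", "exhaustive", "ilp",
                                          "louvain"),
                               seed = 1L) {
  method <- match.arg(method)
  n <- length(network$nodes)
  if (n == 0) stop("empty network: no communities to detect")
  if (method == "auto")
    method <- if (n <= config$exact_community_limit) "exhaustive" else "ilp"

  if (method == "exhaustive") {
    W <- symmetric_weights(network, drop_loops = TRUE)
    m <- sum(W) / 2
    memb <- setNames(rep(1L, n), network$nodes)
    if (m > 0) {
      s <- rowSums(W)
      B <- W - outer(s, s) / (2 * m)
      best_q <- -Inf
      for (p in set_partitions(n)) {
        same <- outer(p, p, "==")
        q <- sum(B[same]) / (2 * m)
        if (q > best_q + 1e-12) {
          best_q <- q
          memb <- setNames(p, network$nodes)
        }
      }
    }
  } else if (method == "ilp") {
    g <- as_igraph(network, "collapsed")
    cl <- igraph::cluster_optimal(g, weights = igraph::E(g)$weight)
    memb <- setNames(as.integer(igraph::membership(cl)), network$nodes)
  } else {
    g <- as_igraph(network, "collapsed")
    best_q <- -Inf
    memb <- NULL
    set.seed(seed)
    for (i in 1:20) {
      cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
      q <- igraph::modularity(cl)
      if (q > best_q) {
        best_q <- q
        memb <- setNames(as.integer(igraph::membership(cl)), network$nodes)
      }
    }
  }
  memb <- setNames(as.integer(factor(memb, levels = unique(memb))),
                   names(memb))
  q <- modularity_q(network, memb)
  structure(list(memberships = memb, modularity = q,
                 acceptable = q > config$modularity_threshold,
                 method = method, isolates = network$isolates),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community partition: %d communities, modularity %.4f (%s)%s\n",
              length(unique(x$memberships)), x$modularity, x$method,
              if (x$acceptable) ", acceptable" else ""))
  invisible(x)
}

#' Within- versus between-community transition share
#'
#' Fraction of adjacent transitions whose antecedent and consequent belong
#' to the same community, compared with the expectation under random
#' community assignment — the mean of the same statistic over label
#' permutations that preserve community sizes. A ratio well above 1 means
#' elements transition into their own community's elements more than chance
#' allows.
#'
#' @param sequences A list of linearized sequences, or a linearization
#'   ensemble (list of lists); only transitions between partitioned nodes
#'   are counted.
#' @param memberships Named community ids from [detect_communities()].
#' @param n_label_perms Number of label permutations.
#' @param seed Seed for the permutations.
#' @return A list with `observed_within`, `expected_within`, `ratio` and
#'   `n_transitions`.
#' @export
community_transition_fractions <- function(sequences, memberships,
                                           n_label_perms = 1000, seed = 1L) {
  if (length(sequences) && is.list(sequences[[1]]))
    sequences <- unlist(sequences, recursive = FALSE)
  nodes <- names(memberships)
  pairs_a <- integer()
  pairs_c <- integer()
  for (s in sequences) {
    idx <- match(s, nodes)            # markers and non-nodes become NA
    if (length(idx) < 2) next
    a <- idx[-length(idx)]
    b <- idx[-1]
    ok <- !is.na(a) & !is.na(b)
    pairs_a <- c(pairs_a, a[ok])
    pairs_c <- c(pairs_c, b[ok])
  }
  if (length(pairs_a) == 0)
    stop("no transitions among partitioned nodes")
  memb <- as.integer(memberships)
  observed <- mean(memb[pairs_a] == memb[pairs_c])
  set.seed(seed)
  exp_within <- vapply(seq_len(n_label_perms), function(i) {
    pm <- sample(memb)
    mean(pm[pairs_a] == pm[pairs_c])
  }, 0)
  expected <- mean(exp_within)
  list(observed_within = observed, expected_within = expected,
       ratio = observed / expected, n_transitions = length(pairs_a))
}

# normalized mutual information with the mean-entropy normalization
# (two single-cluster partitions are identical: NMI 1 by convention)
nmi_index <- function(a, b) {
  n <- length(a)
  joint <- table(a, b) / n
  pa <- rowSums(joint)
  pb <- colSums(joint)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha + hb == 0) return(1)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
  2 * mi / (ha + hb)
}

#' Agreement between two element partitions
#'
#' Compares, on their shared elements, the similarity-based clusters with
#' the network communities (or any two partitions) via the adjusted Rand
#' index, normalized mutual information, and the cross-tabulation used for
#' side-by-side tables.
#'
#' @param a,b Named membership vectors.
#' @return A list with `adjusted_rand`, `nmi`, `contingency`, `n_shared`.
#' @export
compare_partitions <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0) stop("partitions share no elements")
  av <- as.integer(factor(a[shared]))
  bv <- as.integer(factor(b[shared]))
  list(adjusted_rand = mclust::adjustedRandIndex(av, bv),
       nmi = nmi_index(av, bv),
       contingency = table(similarity = av, network = bv),
       n_shared = length(shared))
}
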