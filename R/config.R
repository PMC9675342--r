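#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' Defaults follow the study design the package implements: elements with
#' fewer than 20 occurrences are lumped; transitions need at least 5
#' occurrences and p <= 0.01 to count as significant; co-occurrence
#' linearization, the permutation null and the bootstrap each use 1000
#' replicates; prediction uses 95% training folds repeated 1000 times up to
#' third order; the similarity consensus repeats UMAP + clustering 50 times
#' at on average 7000 epochs; cluster solutions need silhouette > 0.3 and
#' network partitions modularity > 0.3 to be called structured.
#'
#' @param lump_min_count Minimum total occurrences below which an element is
#'   replaced by its a-priori lump target.
#' @param min_transition_count Minimum (fractional) observed count for a
#'   transition to be eligible for significance.
#' @param alpha Significance level for the permutation test.
#' @param n_linearizations Number of random co-occurrence orders averaged
#'   over when estimating transition counts.
#' @param n_permutations Number of randomisations in the null model.
#' @param n_bootstrap Number of bootstrap resamples of individual-bouts.
#' @param train_fraction Fraction of individual-bouts used to fit prediction
#'   models in each k-fold repetition.
#' @param kfold_reps Number of k-fold repetitions.
#' @param max_order Maximum n-gram order (number of antecedents), at most 3.
#' @param n_embedding_runs Number of repeated UMAP + clustering runs in the
#'   consensus.
#' @param mean_epochs Mean UMAP optimisation epochs; per-run epochs are drawn
#'   uniformly in `[0.5, 1.5] * mean_epochs`.
#' @param silhouette_threshold Silhouette above which a cluster solution is
#'   considered acceptable.
#' @param modularity_threshold Modularity above which a community partition
#'   is considered acceptable.
#' @param exact_community_limit Largest network size for which community
#'   detection enumerates all partitions; larger networks use an exact
#'   integer-programming maximizer.
#' @param n_label_perms Label permutations when estimating the expected
#'   within-community transition share.
#' @param permutation_scope `"across"` pools tokens over all bouts when
#'   building the null (the default); `"within"` shuffles within each bout.
#' @param rng_seed Master seed; all stage seeds derive from it.
#' @return A validated list of class `play_config`.
#' @export
play_config <- function(lump_min_count = 20,
                        min_transition_count = 5,
                        alpha = 0.01,
                        n_linearizations = 1000,
                        n_permutations = 1000,
                        n_bootstrap = 1000,
                        train_fraction = 0.95,
                        kfold_reps = 1000,
                        max_order = 3,
                        n_embedding_runs = 50,
                        mean_epochs = 7000,
                        silhouette_threshold = 0.3,
                        modularity_threshold = 0.3,
                        exact_community_limit = 8,
                        n_label_perms = 1000,
                        permutation_scope = c("across", "within"),
                        rng_seed = 1L) {
  cfg <- list(
    lump_min_count = lump_min_count,
    min_transition_count = min_transition_count,
    alpha = alpha,
    n_linearizations = n_linearizations,
    n_permutations = n_permutations,
    n_bootstrap = n_bootstrap,
    train_fraction = train_fraction,
    kfold_reps = kfold_reps,
    max_order = max_order,
    n_embedding_runs = n_embedding_runs,
    mean_epochs = mean_epochs,
    silhouette_threshold = silhouette_threshold,
    modularity_threshold = modularity_threshold,
    exact_community_limit = exact_community_limit,
    n_label_perms = n_label_perms,
    permutation_scope = match.arg(permutation_scope),
    rng_seed = as.integer(rng_seed)
  )
  counts <- c("lump_min_count", "min_transition_count", "n_linearizations",
              "n_permutations", "n_bootstrap", "kfold_reps", "max_order",
              "n_embedding_runs", "mean_epochs", "exact_community_limit",
              "n_label_perms")
  for (k in counts) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v))
      stop(sprintf("config field '%s' must be a count >= 1", k))
  }
  if (!(cfg$alpha > 0 && cfg$alpha < 1))
    stop("alpha must lie strictly between 0 and 1")
  if (!(cfg$train_fraction > 0 && cfg$train_fraction < 1))
    stop("train_fraction must lie strictly between 0 and 1")
  if (cfg$max_order > 3)
    stop("max_order is limited to 3 antecedent elements")
  structure(cfg, class = "play_config")
}

#' Read a configuration from YAML
#'
#' Unknown keys are rejected so typos do not silently fall back to defaults.
#' A `synthetic:` block (passed through untouched) may describe a generator
#' scenario for [run_pipeline()].
#'
#' @param path Path to a YAML file whose top-level keys match the arguments
#'   of [play_config()].
#' @return A `play_config` with an optional `synthetic` attribute.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  synth <- raw$synthetic
  raw$synthetic <- NULL
  known <- names(formals(play_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg <- do.call(play_config, raw)
  attr(cfg, "synthetic") <- synth
  cfg
}

#' @export
print.play_config <- function(x, ...) {
  cat("play sequence analysis configuration\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}
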