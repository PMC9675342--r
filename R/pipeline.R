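#' Run the full play-sequence analysis pipeline
#'
#' Orchestrates every stage end-to-end: read (or simulate) the coded
#' events, lump rare elements and collapse state runs, build the
#' linearization ensemble, estimate averaged transition probabilities, run
#' the permutation null and bootstrap, score prediction accuracy
#' (orders 0 to `max_order`, both scoring modes, plus naive Bayes), run the
#' similarity consensus clustering, build the significant-transition
#' network with its communities and within/between statistics, and compare
#' the two partitions. All artefacts are written under `out_dir`; a run
#' manifest records the configuration snapshot, input digests, per-stage
#' seeds and timings, and output digests, so a rerun with the same inputs
#' and seed reproduces byte-identical files.
#'
#' @param config A [play_config()], or the path to a YAML config file. A
#'   `synthetic` attribute/block (fields of [make_game_structure()] plus
#'   optional `n_bouts`) makes the pipeline generate its own data.
#' @param out_dir Output directory.
#' @param events_path,ethogram_path Input tables (ignored when synthetic
#'   data are requested).
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = "playseq-run",
                         events_path = NULL, ethogram_path = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "play_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$rng_seed
  manifest <- list(config = unclass(config), seed = seed, stages = list(),
                   outputs = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    manifest$stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }
  out <- function(name, file) {
    manifest$outputs[[name]] <<- file.path(out_dir, file)
    file.path(out_dir, file)
  }

  # -- inputs ----------------------------------------------------------------
  synth <- attr(config, "synthetic")
  inputs <- t_stage("input", {
    if (!is.null(synth) || is.null(events_path)) {
      synth <- synth %||% list()
      n_bouts <- synth$n_bouts
      synth$n_bouts <- NULL
      truth <- do.call(make_game_structure, synth)
      bouts <- simulate_bouts(truth, n_bouts = n_bouts,
                              seed = derive_seed(seed, "simulate"))
      eth <- truth_ethogram(truth)
      write_events(bouts, out("events", "events.csv"))
      jsonlite::write_json(
        list(game_memberships = as.list(truth$game_memberships)),
        out("truth", "truth.json"), auto_unbox = TRUE)
      list(bouts = bouts, ethogram = eth, truth = truth)
    } else {
      eth <- read_ethogram(ethogram_path)
      manifest$inputs <<- list(
        events = unname(tools::md5sum(events_path)),
        ethogram = unname(tools::md5sum(ethogram_path)))
      list(bouts = read_events(events_path, eth), ethogram = eth,
           truth = NULL)
    }
  })

  # -- preprocess ------------------------------------------------------------
  prep <- t_stage("preprocess", {
    p <- preprocess_bouts(inputs$bouts, inputs$ethogram,
                          config$lump_min_count)
    write_report(p$lump_report, out("lump_report", "lump_report.csv"))
    p
  })
  bouts <- prep$bouts

  # -- linearization ensemble ------------------------------------------------
  ensemble <- t_stage("linearize",
    linearize_ensemble(bouts, config$n_linearizations,
                       derive_seed(seed, "ensemble")))

  # -- transition statistics -------------------------------------------------
  trans <- t_stage("transitions", {
    avg <- average_counts(ensemble, order = 1)
    probs <- conditional_probabilities(avg)
    write_report(probs$probs, out("transitions", "transitions.csv"))
    tests <- permutation_null(bouts, config,
                              seed = derive_seed(seed, "null"))
    write_report(as.data.frame(tests),
                 out("transition_tests", "transition_tests.csv"))
    boot <- bootstrap_intervals(bouts, config,
                                seed = derive_seed(seed, "bootstrap"))
    write_report(as.data.frame(boot),
                 out("bootstrap", "bootstrap_intervals.csv"))
    list(avg = avg, probs = probs, tests = tests, boot = boot)
  })

  # -- prediction ------------------------------------------------------------
  acc <- t_stage("prediction", {
    rows <- list()
    for (ord in 0:config$max_order) for (mode in c("expected_match",
                                                   "argmax")) {
      a <- kfold_accuracy(bouts, ord, mode, config,
                          seed = derive_seed(seed, "kfold", ord))
      rows[[length(rows) + 1]] <- data.frame(
        order = ord, mode = mode, mean_accuracy = a$mean_accuracy,
        se = a$se, reps = a$reps, n_scoreable = a$n_scoreable)
    }
    for (ord in seq_len(config$max_order)) {
      a <- naive_bayes_accuracy(bouts, ord, config,
                                seed = derive_seed(seed, "nb", ord))
      rows[[length(rows) + 1]] <- data.frame(
        order = ord, mode = "naive_bayes", mean_accuracy = a$mean_accuracy,
        se = a$se, reps = a$reps, n_scoreable = a$n_scoreable)
    }
    df <- do.call(rbind, rows)
    write_report(df, out("accuracy", "accuracy.csv"))
    df
  })

  # -- similarity clustering -------------------------------------------------
  sim <- t_stage("similarity", {
    M <- transition_profile_matrix(trans$probs)
    cons <- consensus_clusters(M, config,
                               seed = derive_seed(seed, "similarity"))
    write_report(data.frame(element = names(cons$final$memberships),
                            cluster = cons$final$memberships),
                 out("clusters", "clusters.csv"))
    write_report(as.data.frame(as.table(cons$stability)) |>
                   setNames(c("element_a", "element_b", "co_assignment")),
                 out("stability", "stability.csv"))
    write_dendrogram(cons$final, out("dendrogram", "dendrogram.newick"))
    cons
  })

  # -- transition network ----------------------------------------------------
  net <- t_stage("network", {
    sig <- filter_significant(trans$tests, config)
    nw <- build_network(sig)
    write_report(nw$edges, out("network_edges", "network_edges.csv"))
    if (nrow(nw$edges)) {
      igraph::write_graph(as_igraph(nw, "directed"),
                          out("network_graphml", "network.graphml"),
                          format = "graphml")
      comm <- detect_communities(nw, config,
                                 seed = derive_seed(seed, "communities"))
      write_report(data.frame(element = names(comm$memberships),
                              community = comm$memberships),
                   out("communities", "communities.csv"))
      frac <- community_transition_fractions(
        ensemble[[1]], comm$memberships, config$n_label_perms,
        seed = derive_seed(seed, "label-perms"))
      list(network = nw, communities = comm, fractions = frac)
    } else list(network = nw, communities = NULL, fractions = NULL)
  })

  # -- partition comparison --------------------------------------------------
  cmp <- t_stage("compare", {
    if (is.null(net$communities)) NULL else {
      cp <- compare_partitions(sim$final$memberships,
                               net$communities$memberships)
      cp$contingency <- NULL   # table kept out of the JSON summary
      cp
    }
  })

  summary <- list(
    n_individual_bouts = length(bouts),
    n_elements = length(trans$probs$vocabulary),
    n_observed_transitions = nrow(trans$probs$probs),
    n_significant_transitions = sum(trans$tests$significant),
    similarity_k = sim$final$k,
    similarity_silhouette = sim$final$silhouette,
    n_communities = if (!is.null(net$communities))
      length(unique(net$communities$memberships)) else 0,
    modularity = if (!is.null(net$communities))
      net$communities$modularity else NA,
    within_community = net$fractions,
    partition_agreement = cmp)
  write_report(summary, out("summary", "summary.json"), format = "json")

  manifest$output_digests <- lapply(manifest$outputs, function(f)
    unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  invisible(manifest)
}
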