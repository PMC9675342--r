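#' Lump rare elements into their a-priori replacements
#'
#' Rare elements destabilise transition estimates: a transition seen three
#' times cannot be told apart from noise. Any element whose total occurrence
#' count (over all bouts jointly) falls below `min_count` and that has a
#' `lump_target` in the ethogram is replaced by that target everywhere.
#' Counts are re-tallied after each pass and passes repeat until a fixpoint,
#' so chains of rare elements resolve transitively. Elements still below
#' threshold but without a target are retained. When lumping makes two
#' identical tokens co-occur within one step, the duplicate collapses to a
#' single token (the collapsed total is reported).
#'
#' @param bouts List of [individual_bout()]s.
#' @param ethogram An [ethogram()] supplying `lump_target`s.
#' @param min_count Occurrence threshold (default 20).
#' @return A list with `bouts` (transformed), `report` (data frame
#'   `old,new,count` per replacement pass) and `n_duplicates_collapsed`.
#' @export
lump_rare_elements <- function(bouts, ethogram, min_count = 20) {
  stopifnot(min_count >= 1)
  link <- setNames(ethogram$lump_target, ethogram$name)
  report <- data.frame(old = character(), new = character(),
                       count = numeric(), stringsAsFactors = FALSE)
  dup_collapsed <- 0
  repeat {
    toks <- unlist(lapply(bouts, bout_tokens), use.names = FALSE)
    counts <- table(toks)
    rare <- names(counts)[counts < min_count]
    rare <- rare[rare %in% names(link) & !is.na(link[rare])]
    if (length(rare) == 0) break
    map <- setNames(unname(link[rare]), rare)
    report <- rbind(report, data.frame(old = rare, new = unname(map),
                                       count = as.numeric(counts[rare]),
                                       stringsAsFactors = FALSE))
    bouts <- lapply(bouts, function(b) {
      b$steps <- lapply(b$steps, function(s) {
        if (any(is_marker(s))) return(s)
        hit <- s %in% names(map)
        s[hit] <- map[s[hit]]
        u <- unique(s)
        dup_collapsed <<- dup_collapsed + (length(s) - length(u))
        u
      })
      b
    })
  }
  list(bouts = bouts, report = report,
       n_duplicates_collapsed = dup_collapsed)
}

#' Collapse repeated occurrences of continuous-state elements
#'
#' The continuously coded state elements (e.g. a bipedal stance) are
#' re-marked at every change while they remain active, which would inflate
#' their transition counts. Within one continuous activity period — the
#' element present in every consecutive step, with no intervening marker —
#' only the first occurrence is retained. If the element leaves the active
#' set, or a `BREAK`/`MISSING` intervenes, a later occurrence counts as a
#' fresh choice. Event elements are untouched: two `Hit`s in consecutive
#' steps are two separate actions. Steps emptied by the collapse are
#' dropped.
#'
#' @param bout An [individual_bout()] (already lumped, typically).
#' @param ethogram An [ethogram()]; its `is_continuous_state` flags define
#'   which elements collapse.
#' @return The collapsed [individual_bout()].
#' @export
collapse_state_runs <- function(bout, ethogram) {
  states <- state_elements(ethogram)
  if (length(bout$steps) == 0 || length(states) == 0) return(bout)
  orig <- bout$steps
  keep_steps <- lapply(seq_along(orig), function(i) {
    s <- orig[[i]]
    if (any(is_marker(s)) || i == 1) return(s)
    prev <- orig[[i - 1]]
    if (any(is_marker(prev))) return(s)   # marker interrupts all activity
    drop <- s %in% states & s %in% prev
    s[!drop]
  })
  nonempty <- lengths(keep_steps) > 0
  bout$steps <- keep_steps[nonempty]
  bout$onsets <- bout$onsets[nonempty]
  bout
}

#' Linearize one bout into a strict token sequence
#'
#' Co-occurring elements (several elements initiated at one timestamp) have
#' no observable order, and there is no a-priori reason to give one primacy.
#' Each step's elements are therefore emitted in uniformly random order;
#' steps follow time order and markers are emitted in place. Analyses are
#' averaged over many linearizations (see [linearize_ensemble()]), which is
#' why downstream transition counts are fractional.
#'
#' Uses the current R random stream; seed control lives at the ensemble
#' level.
#'
#' @param bout An [individual_bout()], already lumped and run-collapsed.
#' @return A character vector of tokens with attributes `bout_id` and
#'   `player_id` (class `element_sequence`).
#' @export
linearize <- function(bout) {
  toks <- unlist(lapply(bout$steps, function(s) {
    if (length(s) > 1) s[sample.int(length(s))] else s
  }), use.names = FALSE)
  structure(toks %||% character(), bout_id = bout$bout_id,
            player_id = bout$player_id, class = "element_sequence")
}

#' Generate an ensemble of independent linearizations
#'
#' Produces `n` full linearizations of all bouts, each from its own derived
#' random stream, so the ensemble is reproducible given `seed` and
#' independent of evaluation order.
#'
#' @param bouts List of [individual_bout()]s.
#' @param n Number of linearizations.
#' @param seed Master seed.
#' @return A list of `n` linearizations, each a list of `element_sequence`s.
#' @export
linearize_ensemble <- function(bouts, n, seed) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    set.seed(derive_seed(seed, "linearize", i))
    lapply(bouts, linearize)
  })
}

#' Full pre-processing: lump, collapse, report
#'
#' Convenience wrapper applying [lump_rare_elements()] then
#' [collapse_state_runs()] to every bout, in that fixed order.
#'
#' @inheritParams lump_rare_elements
#' @return A list with `bouts`, `lump_report`, `n_duplicates_collapsed`.
#' @export
preprocess_bouts <- function(bouts, ethogram, min_count = 20) {
  lumped <- lump_rare_elements(bouts, ethogram, min_count)
  out <- lapply(lumped$bouts, collapse_state_runs, ethogram = ethogram)
  list(bouts = out, lump_report = lumped$report,
       n_duplicates_collapsed = lumped$n_duplicates_collapsed)
}
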