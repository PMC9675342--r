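#' Construct an individual-bout
#'
#' An individual-bout is one player's timestamped record within a play bout:
#' an ordered list of steps, each either the set of play elements active at
#' that onset, or a `BREAK`/`MISSING` marker. Element durations are not
#' represented; the analysis is purely sequential.
#'
#' @param bout_id,player_id Identifiers; one individual-bout per pair.
#' @param onsets Numeric vector of onset times in seconds, strictly
#'   increasing.
#' @param steps List, parallel to `onsets`: each entry a character vector of
#'   active elements, or the scalar `BREAK` / `MISSING`.
#' @param ethogram Optional [ethogram()] to validate element tokens against.
#' @return A list of class `individual_bout`.
#' @export
individual_bout <- function(bout_id, player_id, onsets, steps, ethogram = NULL) {
  stopifnot(length(onsets) == length(steps))
  onsets <- as.numeric(onsets)
  if (length(onsets) && (any(!is.finite(onsets)) || any(onsets < 0)))
    stop("onsets must be finite and non-negative")
  if (length(onsets) > 1 && any(diff(onsets) <= 0))
    stop("onsets must be strictly increasing within an individual-bout")
  steps <- lapply(steps, as.character)
  for (s in steps) {
    if (length(s) == 0) stop("non-marker steps must have a non-empty active set")
    if (any(is_marker(s)) && length(s) > 1)
      stop("a marker step cannot also list active elements")
  }
  if (!is.null(ethogram)) {
    toks <- unlist(steps, use.names = FALSE)
    bad <- setdiff(toks, c(ethogram$name, MARKERS))
    if (length(bad))
      stop("unknown element token(s): ", paste(unique(bad), collapse = ", "))
  }
  structure(list(bout_id = as.character(bout_id),
                 player_id = as.character(player_id),
                 onsets = onsets, steps = steps),
            class = "individual_bout")
}

#' @export
print.individual_bout <- function(x, ...) {
  marker <- vapply(x$steps, function(s) any(is_marker(s)), logical(1))
  cat(sprintf("individual-bout %s / player %s: %d steps, %d element tokens\n",
              x$bout_id, x$player_id, length(x$steps),
              sum(lengths(x$steps)[!marker])))
  invisible(x)
}

#' All element tokens of a bout (markers excluded)
#' @param bout An [individual_bout()].
#' @return Character vector of element occurrences in step order.
#' @export
bout_tokens <- function(bout) {
  out <- unlist(bout$steps, use.names = FALSE)
  out[!is_marker(out)]
}

#' Read coded play events
#'
#' Reads a BORIS-export-like event table with header
#' `bout_id,player_id,onset_s,element`, one row per element onset. Rows that
#' share a `(bout_id, player_id, onset_s)` triple are merged into one step's
#' active set, matching a coding convention that marks all active elements at
#' every change point. `BREAK` and `MISSING` are reserved marker tokens.
#'
#' @param path Path to a comma- or tab-delimited file.
#' @param ethogram An [ethogram()]; element tokens are validated against it.
#' @return A list of [individual_bout()]s, one per `(bout_id, player_id)`.
#' @export
read_events <- function(path, ethogram) {
  if (!file.exists(path)) stop("event file not found: ", path)
  sep <- if (grepl("\t", readLines(path, n = 1))) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  req <- c("bout_id", "player_id", "onset_s", "element")
  if (!all(req %in% names(df)))
    stop("event table needs columns: ", paste(req, collapse = ", "))
  bouts_from_events(df, ethogram)
}

#' Assemble individual-bouts from an event data frame
#'
#' @param df Data frame with columns `bout_id`, `player_id`, `onset_s`,
#'   `element`.
#' @inheritParams read_events
#' @return A list of [individual_bout()]s.
#' @export
bouts_from_events <- function(df, ethogram) {
  df$bout_id <- as.character(df$bout_id)
  df$player_id <- as.character(df$player_id)
  df$element <- as.character(df$element)
  df$onset_s <- as.numeric(df$onset_s)
  if (any(!is.finite(df$onset_s))) stop("non-finite onset_s")
  bad <- setdiff(unique(df$element), c(ethogram$name, MARKERS))
  if (length(bad))
    stop("unknown element token(s): ", paste(bad, collapse = ", "))
  df <- df[order(df$bout_id, df$player_id, df$onset_s), , drop = FALSE]
  key <- paste(df$bout_id, df$player_id, sep = "\r")
  out <- lapply(split(df, factor(key, levels = unique(key))), function(d) {
    steps <- split(d$element, factor(d$onset_s, levels = unique(d$onset_s)))
    onsets <- as.numeric(names(steps))
    steps <- lapply(steps, function(s) {
      s <- unique(s)
      if (any(is_marker(s)) && length(s) > 1)
        stop("conflicting rows at one timestamp: marker together with ",
             "elements in bout ", d$bout_id[1])
      s
    })
    individual_bout(d$bout_id[1], d$player_id[1], onsets, unname(steps))
  })
  unname(out)
}

#' Write individual-bouts back to an event table
#'
#' Inverse of [read_events()]: emits one row per element per step, in
#' deterministic order, so that reading the file back reproduces the same
#' steps and markers.
#'
#' @param bouts List of [individual_bout()]s.
#' @param path Output path; `NULL` returns the data frame instead.
#' @return The event data frame, invisibly when written.
#' @export
write_events <- function(bouts, path = NULL) {
  rows <- lapply(bouts, function(b) {
    data.frame(bout_id = b$bout_id, player_id = b$player_id,
               onset_s = rep(b$onsets, lengths(b$steps)),
               element = unlist(b$steps, use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(path)) return(df)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Write an analysis result to CSV or JSON
#'
#' Data-frame-like results go to CSV with a deterministic column order and
#' numbers at fixed precision; list-like results go to JSON. An empty result
#' yields a header-only CSV (or empty JSON object).
#'
#' @param results A data frame or (possibly nested) list.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (format == "csv") {
    df <- as.data.frame(results)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 10))
    write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE)
  }
  invisible(path)
}
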