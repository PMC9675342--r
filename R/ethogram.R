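#' Construct and validate an ethogram
#'
#' An ethogram defines the repertoire of play elements: each element has a
#' category (contact, non-contact, object, signal), a kind (`event` for
#' countable one-off actions, `state` for continuous behaviour with start and
#' end), a flag marking the continuously-coded state elements that undergo
#' run collapse, and an optional a-priori lump target — the similar element a
#' rare element is merged into.
#'
#' @param elements A data frame with columns `name`, `category`, `kind`,
#'   `is_continuous_state`, `lump_target` (`NA` when none).
#' @return A validated data frame of class `ethogram`.
#' @export
ethogram <- function(elements) {
  req <- c("name", "category", "kind", "is_continuous_state", "lump_target")
  if (!is.data.frame(elements) || !all(req %in% names(elements)))
    stop("ethogram needs columns: ", paste(req, collapse = ", "))
  e <- as.data.frame(elements)[req]
  if (nrow(e) == 0) stop("ethogram validation: no elements")
  e$name <- as.character(e$name)
  e$lump_target <- as.character(e$lump_target)
  e$lump_target[!is.na(e$lump_target) & e$lump_target == ""] <- NA_character_
  e$is_continuous_state <- as.logical(e$is_continuous_state)

  if (anyDuplicated(e$name))
    stop("ethogram format: duplicate element name(s): ",
         paste(unique(e$name[duplicated(e$name)]), collapse = ", "))
  if (any(e$name %in% MARKERS))
    stop("element names may not be reserved markers (BREAK, MISSING)")
  if (any(grepl(TUPLE_SEP, e$name, fixed = TRUE)))
    stop("element names may not contain '", TUPLE_SEP, "'")
  if (!all(e$category %in% c("contact", "non-contact", "object", "signal")))
    stop("category must be one of contact, non-contact, object, signal")
  if (!all(e$kind %in% c("event", "state")))
    stop("kind must be 'event' or 'state'")
  if (any(is.na(e$is_continuous_state)))
    stop("is_continuous_state must be TRUE/FALSE")
  if (any(e$is_continuous_state & e$kind != "state"))
    stop("only state elements can be continuous states")

  tgt <- e$lump_target[!is.na(e$lump_target)]
  unknown <- setdiff(tgt, e$name)
  if (length(unknown))
    stop("ethogram validation: unknown lump_target(s): ",
         paste(unknown, collapse = ", "))
  # follow lump chains; revisiting a node means a cycle
  link <- setNames(e$lump_target, e$name)
  for (nm in e$name) {
    seen <- character()
    cur <- nm
    while (!is.na(link[[cur]])) {
      if (cur %in% seen)
        stop("ethogram validation: lump_target cycle involving '", nm, "'")
      seen <- c(seen, cur)
      cur <- link[[cur]]
      if (cur == nm)
        stop("ethogram validation: lump_target cycle involving '", nm, "'")
    }
  }
  class(e) <- c("ethogram", "data.frame")
  e
}

#' Read an ethogram from delimited text
#'
#' Expects a header `name,category,kind,is_continuous_state,lump_target`;
#' comma- and tab-delimited files are both accepted. An empty `lump_target`
#' means the element has no a-priori replacement.
#'
#' @param path Path to the file.
#' @return An [ethogram()].
#' @export
read_ethogram <- function(path) {
  if (!file.exists(path)) stop("ethogram file not found: ", path)
  sep <- if (grepl("\t", readLines(path, n = 1))) "\t" else ","
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  na.strings = c("NA", ""))
  ethogram(raw)
}

#' @export
print.ethogram <- function(x, ...) {
  cat(sprintf("ethogram: %d elements (%d continuous states, %d with lump target)\n",
              nrow(x), sum(x$is_continuous_state), sum(!is.na(x$lump_target))))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Elements coded as continuous states
#'
#' @param ethogram An [ethogram()].
#' @return Character vector of element names with `is_continuous_state`.
#' @export
state_elements <- function(ethogram) {
  ethogram$name[ethogram$is_continuous_state]
}
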