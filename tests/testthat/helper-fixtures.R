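# shared fixtures built in code

# small ethogram: A, Hit = events; Bipedal, Flee = continuous states;
# X lumps into A, Y lumps into Hit
tiny_ethogram <- function() {
  ethogram(data.frame(
    name = c("A", "Hit", "Bipedal", "Flee", "X", "Y"),
    category = c("non-contact", "contact", "non-contact", "non-contact",
                 "non-contact", "contact"),
    kind = c("event", "event", "state", "state", "event", "event"),
    is_continuous_state = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    lump_target = c(NA, NA, NA, NA, "A", "Hit"),
    stringsAsFactors = FALSE))
}

# bout from a list of steps (each a character vector or a marker scalar)
make_bout <- function(steps, bout_id = "b1", player_id = "p1") {
  individual_bout(bout_id, player_id, seq_along(steps), steps)
}

# bouts whose steps are single tokens (no co-occurrence)
token_bouts <- function(token_vectors) {
  lapply(seq_along(token_vectors), function(i)
    make_bout(as.list(token_vectors[[i]]), bout_id = sprintf("b%03d", i)))
}

# an ethogram where every listed element is a plain event
event_ethogram <- function(elements) {
  ethogram(data.frame(name = elements, category = "non-contact",
                      kind = "event", is_continuous_state = FALSE,
                      lump_target = NA_character_, stringsAsFactors = FALSE))
}
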