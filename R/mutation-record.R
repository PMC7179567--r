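.sortEvents <- function(events) {
  if (is.null(events) || nrow(events) == 0L) return(.emptyEvents())
  kindRank <- match(events$kind, c("SUB", "DEL", "INS"))
  events[order(events$member, events$position, kindRank,
               method = "radix"), , drop = FALSE]
}

#' Serialize edit events to a canonical mutation record
#'
#' The compact record format is a space-separated token stream, one group
#' per event, events sorted by (member, position, kind):
#' `SUB <member> <position> <patternBase> <observedBase>`,
#' `DEL <member> <position> <patternBase>`,
#' `INS <member> <position> <observedBase>` (the base is inserted in
#' front of that pattern position). Positions are 0-based pattern
#' coordinates. An empty event list (an exact match) serializes to the
#' empty string.
#'
#' @param events Event data.frame as returned by [approxMatch()] /
#'   [matchTuple()].
#' @return A single record string.
#' @examples
#' r <- matchTuple(c("GGAGAUG", "UGGAGACU"), "GGAGGAGACGGGUCCUGGAGAUAAG")
#' serializeRecord(r$events)
#' @export
serializeRecord <- function(events) {
  events <- .sortEvents(events)
  if (nrow(events) == 0L) return("")
  toks <- vapply(seq_len(nrow(events)), function(k) {
    e <- events[k, ]
    switch(e$kind,
      SUB = paste("SUB", e$member, e$position, e$patternBase, e$observedBase),
      DEL = paste("DEL", e$member, e$position, e$patternBase),
      INS = paste("INS", e$member, e$position, e$observedBase),
      stop("unknown event kind: ", e$kind))
  }, "")
  paste(toks, collapse = " ")
}

#' Parse a mutation record back into events
#'
#' Inverse of [serializeRecord()]; `parseRecord(serializeRecord(e))`
#' reproduces `e` and vice versa.
#'
#' @param record A record string (possibly empty).
#' @return Event data.frame.
#' @export
parseRecord <- function(record) {
  stopifnot(is.character(record), length(record) == 1L)
  record <- trimws(record)
  if (!nzchar(record)) return(.emptyEvents())
  toks <- strsplit(record, "[ \t]+")[[1L]]
  kinds <- character(); mem <- integer(); pos <- integer()
  pb <- character(); ob <- character()
  k <- 1L
  while (k <= length(toks)) {
    kind <- toks[k]
    need <- switch(kind, SUB = 5L, DEL = 4L, INS = 4L,
                   stop(sprintf("malformed mutation record at token %d: '%s'",
                                k, kind)))
    if (k + need - 1L > length(toks))
      stop(sprintf("truncated mutation record at token %d", k))
    m <- suppressWarnings(as.integer(toks[k + 1L]))
    p <- suppressWarnings(as.integer(toks[k + 2L]))
    if (is.na(m) || is.na(p))
      stop(sprintf("malformed mutation record at token %d: expected integers",
                   k + 1L))
    kinds <- c(kinds, kind); mem <- c(mem, m); pos <- c(pos, p)
    if (kind == "SUB") {
      pb <- c(pb, toks[k + 3L]); ob <- c(ob, toks[k + 4L])
    } else if (kind == "DEL") {
      pb <- c(pb, toks[k + 3L]); ob <- c(ob, NA_character_)
    } else {
      pb <- c(pb, NA_character_); ob <- c(ob, toks[k + 3L])
    }
    k <- k + need
  }
  .sortEvents(data.frame(kind = kinds, member = mem, position = pos,
                         patternBase = pb, observedBase = ob,
                         stringsAsFactors = FALSE))
}

#' Apply a mutation record to tuple members
#'
#' Produces the variant member strings described by a record: SUB replaces
#' the pattern base, DEL removes it, INS inserts the observed base in
#' front of the position. Used by the synthetic generator to plant
#' approximate tuple placements with known records.
#'
#' @param members Character vector of tuple member strings.
#' @param record Canonical record string, or an event data.frame.
#' @return Character vector of mutated member strings.
#' @export
applyRecord <- function(members, record) {
  events <- if (is.data.frame(record)) .sortEvents(record)
            else parseRecord(record)
  out <- members
  if (nrow(events) == 0L) return(out)
  stopifnot(all(events$member >= 0L), all(events$member < length(members)))
  for (m in unique(events$member)) {
    ev <- events[events$member == m, , drop = FALSE]
    ## apply right-to-left so earlier positions stay valid
    ev <- ev[order(-ev$position), , drop = FALSE]
    chars <- strsplit(out[m + 1L], "", fixed = TRUE)[[1L]]
    for (k in seq_len(nrow(ev))) {
      p <- ev$position[k] + 1L
      if (ev$kind[k] == "SUB") {
        stopifnot(chars[p] == ev$patternBase[k])
        chars[p] <- ev$observedBase[k]
      } else if (ev$kind[k] == "DEL") {
        stopifnot(chars[p] == ev$patternBase[k])
        chars <- chars[-p]
      } else {
        chars <- append(chars, ev$observedBase[k], after = p - 1L)
      }
    }
    out[m + 1L] <- paste(chars, collapse = "")
  }
  out
}
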