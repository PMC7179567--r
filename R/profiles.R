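## All placements of an ordered tuple in one text via repeated greedy
## approximate matching on the remaining suffix; returns the canonical
## record of each placement ("" = exact).
.scanTuplePlacements <- function(members, text, scoring) {
  records <- character()
  offset <- 0L
  n <- nchar(text)
  while (offset < n) {
    r <- matchTuple(members, substring(text, offset + 1L), scoring)
    if (is.null(r)) break
    records <- c(records, r$record)
    endAbs <- offset + r$results[[length(r$results)]]$end
    if (endAbs <= offset) break   # no progress (degenerate zero-width span)
    offset <- endAbs
  }
  records
}

#' Build mutation profiles by re-scanning a dataset
#'
#' For each tuple the dataset is re-scanned with approximate matching:
#' every exact placement (no edit events) increments the tuple's exact
#' frequency, every approximate placement increments the frequency of its
#' canonical mutation record, creating entries as needed. Placements
#' within one sequence are taken greedily left-to-right and do not
#' overlap.
#'
#' @param tuples A [FrequentTuples-class], or a list of character vectors
#'   of tuple members.
#' @param x A [SequenceSet-class] (the profiling dataset).
#' @param scoring A [ScoringScheme-class].
#' @return A [MutationProfiles-class], one profile per tuple, entries
#'   ordered by decreasing frequency then record string.
#' @export
buildProfiles <- function(tuples, x, scoring = scoringScheme()) {
  members <- if (is(tuples, "FrequentTuples")) tuples@members else tuples
  stopifnot(is.list(members), is(x, "SequenceSet"))
  exact <- integer(length(members))
  entries <- vector("list", length(members))
  for (j in seq_along(members)) {
    recs <- unlist(lapply(x@residues, function(txt)
      .scanTuplePlacements(members[[j]], txt, scoring)))
    exact[j] <- sum(recs == "")
    recs <- recs[recs != ""]
    if (length(recs)) {
      tab <- table(recs)
      df <- data.frame(record = names(tab), frequency = as.integer(tab),
                       stringsAsFactors = FALSE)
      df <- df[order(-df$frequency, df$record, method = "radix"), ,
               drop = FALSE]
      rownames(df) <- NULL
      entries[[j]] <- df
    } else {
      entries[[j]] <- data.frame(record = character(), frequency = integer(),
                                 stringsAsFactors = FALSE)
    }
  }
  new("MutationProfiles", tuples = members, exactFrequency = exact,
      entries = entries)
}

#' Encode one sequence as a feature descriptor vector
#'
#' One component per profiled tuple: 1 if the tuple matches the sequence
#' exactly; otherwise, if the tuple matches approximately and the match's
#' canonical mutation record is present in the tuple's profile, the ratio
#' of that record's frequency to the tuple's exact frequency; otherwise 0.
#' An approximate match whose record is absent from the profile scores 0,
#' as does any approximate match when the exact frequency is 0. Among
#' several placements, an exact one takes precedence; otherwise the
#' best-scoring (then leftmost) placement defines the record.
#'
#' @param text Residue string (or [SequenceSet-class] of length 1).
#' @param profiles A [MutationProfiles-class].
#' @param scoring A [ScoringScheme-class].
#' @return Numeric vector, one component per profile, in profile order.
#' @export
encodeSequence <- function(text, profiles, scoring = scoringScheme()) {
  if (is(text, "SequenceSet")) {
    stopifnot(length(text) == 1L)
    text <- text@residues
  }
  stopifnot(is(profiles, "MutationProfiles"), length(profiles) > 0L)
  out <- numeric(length(profiles@tuples))
  for (j in seq_along(profiles@tuples)) {
    r <- matchTuple(profiles@tuples[[j]], text, scoring)
    if (is.null(r)) next
    if (r$record == "") {
      out[j] <- 1
    } else {
      hit <- match(r$record, profiles@entries[[j]]$record)
      if (!is.na(hit)) {
        ef <- profiles@exactFrequency[j]
        if (ef > 0L) {
          out[j] <- profiles@entries[[j]]$frequency[hit] / ef
          if (out[j] > 1)
            warning(sprintf(
              "component %d exceeds 1 (record frequency %d > exact frequency %d)",
              j, profiles@entries[[j]]$frequency[hit], ef))
        }
      }
    }
  }
  out
}

#' Encode a whole SequenceSet
#'
#' @param x A [SequenceSet-class].
#' @param profiles A [MutationProfiles-class].
#' @param scoring A [ScoringScheme-class].
#' @return Numeric matrix, one row per sequence (rownames = ids), one
#'   column per profiled tuple.
#' @export
encodeSequences <- function(x, profiles, scoring = scoringScheme()) {
  stopifnot(is(x, "SequenceSet"))
  m <- t(vapply(x@residues, encodeSequence, numeric(length(profiles)),
                profiles = profiles, scoring = scoring))
  dim(m) <- c(length(x), length(profiles))
  rownames(m) <- x@ids
  m
}
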