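## All leftmost-greedy non-overlapping occurrences of each symbol in one
## sequence, merged and ordered by start, then longer first, then symbol.
.symbolOccurrences <- function(symbols, text) {
  out <- data.frame(start = integer(), end = integer(),
                    symbol = character(), stringsAsFactors = FALSE)
  for (s in symbols) {
    st <- .occurrenceStarts(s, text)
    if (length(st))
      out <- rbind(out, data.frame(start = st, end = st + nchar(s) - 1L,
                                   symbol = s, stringsAsFactors = FALSE))
  }
  if (nrow(out))
    out <- out[order(out$start, -out$end, out$symbol, method = "radix"), ,
               drop = FALSE]
  out
}

## One left-to-right greedy pass placing a multiset `need` (named counts)
## repeatedly; returns list of permutations (character vectors), one per
## completed placement. Occurrences overlapping an already selected one,
## or of a symbol exhausted in the current round, are skipped.
.placeMultiset <- function(need, occs) {
  perms <- list()
  remaining <- need
  perm <- character()
  cursor <- 0L
  for (k in seq_len(nrow(occs))) {
    sym <- occs$symbol[k]
    if (occs$start[k] <= cursor) next
    if (is.na(remaining[sym]) || remaining[sym] < 1L) next
    remaining[sym] <- remaining[sym] - 1L
    perm <- c(perm, sym)
    cursor <- occs$end[k]
    if (all(remaining == 0L)) {
      perms[[length(perms) + 1L]] <- perm
      remaining <- need
      perm <- character()
    }
  }
  perms
}

## Count leftmost-greedy non-overlapping in-order placements of the
## ordered tuple `members` in `text`.
.placeTupleExact <- function(members, text) {
  occs <- .symbolOccurrences(unique(members), text)
  count <- 0L
  pos <- 1L
  cursor <- 0L
  if (nrow(occs) == 0L) return(0L)
  for (k in seq_len(nrow(occs))) {
    if (occs$start[k] <= cursor) next
    if (occs$symbol[k] != members[pos]) next
    cursor <- occs$end[k]
    pos <- pos + 1L
    if (pos > length(members)) {
      count <- count + 1L
      pos <- 1L
    }
  }
  count
}

#' Derive ordered frequent-sequence tuples from closed combinations
#'
#' Re-scans the dataset: for every closed combination, each exact in-order
#' non-overlapping placement of its members (leftmost-greedy, any gap
#' lengths between members) contributes one observed permutation. Identical
#' permutations are pooled over the whole dataset and their frequency is
#' the number of placements; permutations reaching `tupleMinFrequency`
#' become tuples.
#'
#' @param combinations A [SymbolCombinations-class].
#' @param x The [SequenceSet-class] that was mined.
#' @param tupleMinFrequency Minimum placement count for a permutation to
#'   be kept (defaults to 1; the pipeline passes the combination support
#'   threshold).
#' @return A [FrequentTuples-class] ordered by decreasing frequency, then
#'   by tuple string.
#' @export
deriveOrderedTuples <- function(combinations, x, tupleMinFrequency = 1L) {
  stopifnot(is(combinations, "SymbolCombinations"), is(x, "SequenceSet"))
  tupleMinFrequency <- max(1L, as.integer(tupleMinFrequency))
  counts <- new.env(parent = emptyenv())
  for (k in seq_along(combinations@symbols)) {
    need <- combinations@symbols[[k]]
    rows <- match(combinations@supportIds[[k]], x@ids)
    for (r in rows) {
      occs <- .symbolOccurrences(names(need), x@residues[r])
      if (nrow(occs) == 0L) next
      for (perm in .placeMultiset(need, occs)) {
        key <- paste(perm, collapse = "\t")
        counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
      }
    }
  }
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]], 1L)
  keep <- freq >= tupleMinFrequency
  keys <- keys[keep]; freq <- unname(freq[keep])
  ord <- order(-freq, keys, method = "radix")
  new("FrequentTuples",
      members = lapply(keys[ord], function(k) strsplit(k, "\t", fixed = TRUE)[[1L]]),
      frequency = as.integer(freq[ord]))
}
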