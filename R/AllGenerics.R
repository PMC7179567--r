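#' Accessors for motifTuples classes
#'
#' `seqIds`, `residues`, `seqLabels` and `alphabetName` extract the
#' corresponding fields of a [SequenceSet-class]; `residues` also extracts
#' the substring strings of a [FrequentSubsequences-class]; `supportIds`
#' the support-id sets of mined objects; `tupleMembers` and
#' `tupleFrequency` the fields of [FrequentTuples-class];
#' `exactFrequency` and `profileEntries` the fields of
#' [MutationProfiles-class].
#'
#' @param x Object to access.
#' @return The corresponding field.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))
#' @rdname accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))
#' @rdname accessors
#' @export
setGeneric("seqLabels", function(x) standardGeneric("seqLabels"))
#' @rdname accessors
#' @export
setGeneric("alphabetName", function(x) standardGeneric("alphabetName"))
#' @rdname accessors
#' @export
setGeneric("supportIds", function(x) standardGeneric("supportIds"))
#' @rdname accessors
#' @export
setGeneric("occurrenceTotal", function(x) standardGeneric("occurrenceTotal"))
#' @rdname accessors
#' @export
setGeneric("tupleMembers", function(x) standardGeneric("tupleMembers"))
#' @rdname accessors
#' @export
setGeneric("tupleFrequency", function(x) standardGeneric("tupleFrequency"))
#' @rdname accessors
#' @export
setGeneric("exactFrequency", function(x) standardGeneric("exactFrequency"))
#' @rdname accessors
#' @export
setGeneric("profileEntries", function(x) standardGeneric("profileEntries"))
#' @rdname accessors
#' @export
setGeneric("occurrenceCounts", function(x) standardGeneric("occurrenceCounts"))

#' @rdname accessors
setMethod("seqIds", "SequenceSet", function(x) x@ids)
#' @rdname accessors
setMethod("residues", "SequenceSet", function(x) setNames(x@residues, x@ids))
#' @rdname accessors
setMethod("seqLabels", "SequenceSet", function(x) setNames(x@labels, x@ids))
#' @rdname accessors
setMethod("alphabetName", "SequenceSet", function(x) x@alphabet)
#' @rdname accessors
setMethod("residues", "FrequentSubsequences", function(x) x@residues)
#' @rdname accessors
setMethod("supportIds", "FrequentSubsequences",
          function(x) setNames(x@supportIds, x@residues))
#' @rdname accessors
setMethod("occurrenceTotal", "FrequentSubsequences",
          function(x) setNames(x@occurrenceTotal, x@residues))
#' @rdname accessors
setMethod("supportIds", "SymbolCombinations", function(x) x@supportIds)
#' @rdname accessors
setMethod("tupleMembers", "FrequentTuples", function(x) x@members)
#' @rdname accessors
setMethod("tupleFrequency", "FrequentTuples", function(x) x@frequency)
#' @rdname accessors
setMethod("tupleMembers", "MutationProfiles", function(x) x@tuples)
#' @rdname accessors
setMethod("exactFrequency", "MutationProfiles", function(x) x@exactFrequency)
#' @rdname accessors
setMethod("profileEntries", "MutationProfiles", function(x) x@entries)
#' @rdname accessors
setMethod("occurrenceCounts", "OccurrenceTable", function(x) x@counts)

#' Multiset symbols of mined combinations
#'
#' @param x A [SymbolCombinations-class] object.
#' @return List of named integer vectors (symbol -> multiplicity).
#' @export
combinationSymbols <- function(x) {
  stopifnot(is(x, "SymbolCombinations"))
  x@symbols
}

#' @describeIn SequenceSet-class Number of sequences.
#' @param x A SequenceSet.
#' @export
setMethod("length", "SequenceSet", function(x) length(x@ids))

#' @describeIn FrequentSubsequences-class Number of mined subsequences.
#' @param x A FrequentSubsequences object.
#' @export
setMethod("length", "FrequentSubsequences", function(x) length(x@residues))

#' @describeIn SymbolCombinations-class Number of combinations.
#' @param x A SymbolCombinations object.
#' @export
setMethod("length", "SymbolCombinations", function(x) length(x@symbols))

#' @describeIn FrequentTuples-class Number of tuples.
#' @param x A FrequentTuples object.
#' @export
setMethod("length", "FrequentTuples", function(x) length(x@members))

#' @describeIn MutationProfiles-class Number of profiles.
#' @param x A MutationProfiles object.
#' @export
setMethod("length", "MutationProfiles", function(x) length(x@tuples))

#' @describeIn SequenceSet-class Subset by index or id.
#' @param i Index vector.
#' @param j,drop Ignored.
#' @param ... Ignored.
#' @export
setMethod("[", "SequenceSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  new("SequenceSet", ids = x@ids[i], residues = x@residues[i],
      alphabet = x@alphabet, labels = x@labels[i])
})

setMethod("show", "SequenceSet", function(object) {
  cat(sprintf("SequenceSet of %d %s sequence(s)\n", length(object),
              object@alphabet))
  n <- min(length(object), 5L)
  if (n > 0L) {
    w <- nchar(object@residues[seq_len(n)])
    prev <- ifelse(w > 40L,
                   paste0(substr(object@residues[seq_len(n)], 1L, 37L), "..."),
                   object@residues[seq_len(n)])
    cat(sprintf("  %s [%s, %d nt] %s\n", object@ids[seq_len(n)],
                object@labels[seq_len(n)], w, prev), sep = "")
    if (length(object) > n) cat(sprintf("  ... and %d more\n",
                                        length(object) - n))
  }
  invisible(object)
})

setMethod("show", "FrequentSubsequences", function(object) {
  cat(sprintf("FrequentSubsequences: %d closed/frequent substring(s)\n",
              length(object)))
  n <- min(length(object), 8L)
  if (n > 0L)
    cat(sprintf("  %s (support %d, %d occurrence(s))\n",
                object@residues[seq_len(n)],
                vapply(object@supportIds[seq_len(n)], length, 1L),
                object@occurrenceTotal[seq_len(n)]), sep = "")
  if (length(object) > n) cat(sprintf("  ... and %d more\n",
                                      length(object) - n))
  invisible(object)
})

setMethod("show", "OccurrenceTable", function(object) {
  m <- object@counts
  cat(sprintf("OccurrenceTable: %d sequence(s) x %d subsequence(s), %d non-zero cell(s)\n",
              nrow(m), ncol(m), sum(m != 0)))
  invisible(object)
})

setMethod("show", "SymbolCombinations", function(object) {
  cat(sprintf("SymbolCombinations: %d closed frequent combination(s)\n",
              length(object)))
  n <- min(length(object), 8L)
  for (k in seq_len(n)) {
    s <- object@symbols[[k]]
    cat(sprintf("  {%s} support %d\n",
                paste(ifelse(s > 1L, paste0(s, "x", names(s)), names(s)),
                      collapse = ", "),
                length(object@supportIds[[k]])))
  }
  if (length(object) > n) cat(sprintf("  ... and %d more\n",
                                      length(object) - n))
  invisible(object)
})

setMethod("show", "FrequentTuples", function(object) {
  cat(sprintf("FrequentTuples: %d ordered tuple(s)\n", length(object)))
  n <- min(length(object), 8L)
  if (n > 0L)
    cat(sprintf("  <%s> frequency %d\n",
                vapply(object@members[seq_len(n)], paste, "", collapse = ", "),
                object@frequency[seq_len(n)]), sep = "")
  if (length(object) > n) cat(sprintf("  ... and %d more\n",
                                      length(object) - n))
  invisible(object)
})

setMethod("show", "MutationProfiles", function(object) {
  cat(sprintf("MutationProfiles: %d tuple profile(s)\n", length(object)))
  n <- min(length(object), 5L)
  for (k in seq_len(n))
    cat(sprintf("  <%s> exact %d, %d mutation record(s)\n",
                paste(object@tuples[[k]], collapse = ", "),
                object@exactFrequency[k], nrow(object@entries[[k]])))
  if (length(object) > n) cat(sprintf("  ... and %d more\n",
                                      length(object) - n))
  invisible(object)
})

setMethod("show", "ScoringScheme", function(object) {
  cat(sprintf("ScoringScheme: match 0, sub %g, ins %g, del %g, minScore %g\n",
              object@sub, object@ins, object@del, object@minScore))
  invisible(object)
})

setMethod("show", "MinerConfig", function(object) {
  thr <- if (is.na(object@minSupport))
    sprintf("support ratio %g", object@supportRatio)
  else sprintf("min support %g", object@minSupport)
  cat(sprintf("MinerConfig: %s, length %d..%d, keepLongestAbove %g\n",
              thr, object@minLen, object@maxLen, object@keepLongestAbove))
  invisible(object)
})
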