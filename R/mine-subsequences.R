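## Leftmost-greedy non-overlapping exact occurrence count of `pattern`
## in each element of `texts` (the counting rule used throughout).
.countOccurrences <- function(pattern, texts) {
  m <- gregexpr(pattern, texts, fixed = TRUE)
  vapply(m, function(x) if (x[1L] == -1L) 0L else length(x), 1L)
}

## Start positions (1-based) of leftmost-greedy non-overlapping
## occurrences of `pattern` in a single `text`; integer(0) if absent.
.occurrenceStarts <- function(pattern, text) {
  m <- gregexpr(pattern, text, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

.resolveMinSupport <- function(config, n) {
  thr <- if (is.na(config@minSupport))
    ceiling(config@supportRatio * n) else ceiling(config@minSupport)
  thr <- as.integer(thr)
  if (thr < 1L)
    stop("support threshold resolves to fewer than one sequence")
  thr
}

#' Mine all frequent substrings of a sequence set
#'
#' Enumerates every substring whose per-sequence support (number of
#' distinct sequences containing it) reaches the configured threshold and
#' whose length lies within the configured bounds. Enumeration grows a
#' prefix tree over all suffixes, depth-capped at `maxLen`: candidates of
#' length L+1 extend frequent candidates of length L and are tested only
#' against the parent's supporting sequences (anti-monotonicity). No
#' closure filtering is applied here; see [closureFilter()].
#'
#' @param x A [SequenceSet-class].
#' @param config A [MinerConfig-class].
#' @return A [FrequentSubsequences-class], lexicographically ordered, each
#'   substring carrying its full support-id set and its total
#'   leftmost-greedy non-overlapping occurrence count.
#' @examples
#' set <- SequenceSet(c("s1", "s2"), c("ACGACG", "ACGT"))
#' mineFrequentSubstrings(set, minerConfig(minSupport = 2, minLen = 2,
#'                                         maxLen = 6))
#' @export
mineFrequentSubstrings <- function(x, config) {
  stopifnot(is(x, "SequenceSet"), is(config, "MinerConfig"))
  if (length(x) == 0L) stop("dataset is empty")
  thr <- .resolveMinSupport(config, length(x))
  seqs <- x@residues
  ids <- x@ids
  alpha <- .ALPHABETS[[x@alphabet]]

  kept <- character()
  keptSupport <- list()

  ## frontier: frequent strings of the current length + their support index
  frontier <- list(list(s = "", idx = seq_along(seqs)))
  for (L in seq_len(config@maxLen)) {
    nxt <- vector("list", 0L)
    for (node in frontier) {
      for (ch in alpha) {
        cand <- paste0(node$s, ch)
        hit <- node$idx[grepl(cand, seqs[node$idx], fixed = TRUE)]
        if (length(hit) >= thr) {
          nxt[[length(nxt) + 1L]] <- list(s = cand, idx = hit)
          if (L >= config@minLen) {
            kept[length(kept) + 1L] <- cand
            keptSupport[[length(keptSupport) + 1L]] <- hit
          }
        }
      }
    }
    if (length(nxt) == 0L) break
    frontier <- nxt
  }

  ord <- order(kept, method = "radix")
  kept <- kept[ord]
  keptSupport <- keptSupport[ord]
  occ <- vapply(seq_along(kept), function(k)
    sum(.countOccurrences(kept[k], seqs[keptSupport[[k]]])), 1L)
  new("FrequentSubsequences", residues = kept,
      supportIds = lapply(keptSupport, function(i) ids[i]),
      occurrenceTotal = occ)
}

#' Closure filter for frequent substrings
#'
#' A candidate is eliminated if and only if it is a proper substring of
#' another candidate occurring in exactly the same sequences: in that case
#' only the super-string is retained. Candidates longer than
#' `keepLongestAbove` residues are retained unconditionally.
#'
#' @param fs A [FrequentSubsequences-class] (output of
#'   [mineFrequentSubstrings()]).
#' @param keepLongestAbove Length above which candidates are exempt from
#'   elimination; default `Inf` (no exemption).
#' @return A [FrequentSubsequences-class] containing the closed set.
#' @export
closureFilter <- function(fs, keepLongestAbove = Inf) {
  stopifnot(is(fs, "FrequentSubsequences"))
  n <- length(fs@residues)
  if (n <= 1L) return(fs)
  key <- vapply(fs@supportIds,
                function(s) paste(sort(s), collapse = "\r"), "")
  len <- nchar(fs@residues)
  drop <- logical(n)
  for (i in seq_len(n)) {
    if (len[i] > keepLongestAbove) next
    same <- which(key == key[i] & len > len[i])
    for (j in same) {
      if (grepl(fs@residues[i], fs@residues[j], fixed = TRUE)) {
        drop[i] <- TRUE
        break
      }
    }
  }
  new("FrequentSubsequences", residues = fs@residues[!drop],
      supportIds = fs@supportIds[!drop],
      occurrenceTotal = fs@occurrenceTotal[!drop])
}
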