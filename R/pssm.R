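.inferAlphabet <- function(strings) {
  ch <- unique(strsplit(paste(strings, collapse = ""), "", fixed = TRUE)[[1L]])
  if (all(ch %in% .ALPHABETS$DNA)) return("DNA")
  if (all(ch %in% .ALPHABETS$RNA)) return("RNA")
  "protein"
}

#' Convert a mutation profile to position-specific scoring matrices
#'
#' One matrix per tuple member: rows are alphabet residues, columns are
#' 0-based pattern positions, cells are counts. Each consensus base starts
#' at the exact-placement frequency. Every profile entry then contributes
#' its frequency position-wise to the member: to the observed base where
#' the entry substitutes that position, nothing where it deletes it, and
#' to the consensus base at positions the entry does not touch (including
#' all positions of members the entry never mentions). Insertions carry no
#' positional information for a fixed-width matrix and are ignored. A
#' pseudocount may be added and columns may be normalized to frequencies.
#'
#' @param profiles A [MutationProfiles-class].
#' @param index Which profile to convert (default 1).
#' @param normalize If `TRUE`, each column is divided by its sum.
#' @param pseudocount Non-negative count added to every cell first.
#' @param alphabet Alphabet name; inferred from the member strings when
#'   `NULL`.
#' @return List of matrices, one per member, each carrying the member
#'   string as attribute `"member"`.
#' @export
toPSSM <- function(profiles, index = 1L, normalize = FALSE,
                   pseudocount = 0, alphabet = NULL) {
  stopifnot(is(profiles, "MutationProfiles"), pseudocount >= 0)
  index <- as.integer(index)
  stopifnot(index >= 1L, index <= length(profiles))
  members <- profiles@tuples[[index]]
  ef <- profiles@exactFrequency[index]
  entries <- profiles@entries[[index]]
  if (ef == 0L && nrow(entries) == 0L)
    stop("empty profile: no exact placements and no mutation records")
  if (is.null(alphabet)) alphabet <- .inferAlphabet(members)
  residues <- .ALPHABETS[[alphabet]]

  parsed <- lapply(entries$record, parseRecord)
  out <- vector("list", length(members))
  for (m in seq_along(members)) {
    w <- strsplit(members[m], "", fixed = TRUE)[[1L]]
    L <- length(w)
    counts <- matrix(0, nrow = length(residues), ncol = L,
                     dimnames = list(residues, as.character(0:(L - 1L))))
    for (p in seq_len(L)) counts[w[p], p] <- ef
    for (k in seq_len(nrow(entries))) {
      f <- entries$frequency[k]
      ev <- parsed[[k]]
      ev <- ev[ev$member == m - 1L, , drop = FALSE]
      for (p in seq_len(L)) {
        subHit <- which(ev$kind == "SUB" & ev$position == p - 1L)
        if (length(subHit)) {
          counts[ev$observedBase[subHit[1L]], p] <- counts[ev$observedBase[subHit[1L]], p] + f
        } else if (any(ev$kind == "DEL" & ev$position == p - 1L)) {
          ## deleted base: the entry contributes nothing at this position
        } else {
          counts[w[p], p] <- counts[w[p], p] + f
        }
      }
    }
    counts <- counts + pseudocount
    if (normalize) {
      cs <- colSums(counts)
      if (any(cs == 0))
        stop("cannot normalize a zero column; use a pseudocount")
      counts <- sweep(counts, 2L, cs, "/")
    }
    attr(counts, "member") <- members[m]
    out[[m]] <- counts
  }
  out
}
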