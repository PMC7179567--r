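#' Build the sequence-by-subsequence occurrence table
#'
#' Each cell counts the leftmost-greedy non-overlapping exact occurrences
#' of the column's subsequence in the row's sequence. The table is stored
#' sparse: with thousands of subsequences most cells are zero.
#'
#' @param x A [SequenceSet-class].
#' @param fs A [FrequentSubsequences-class], normally closure-filtered.
#' @return An [OccurrenceTable-class].
#' @export
buildOccurrenceTable <- function(x, fs) {
  stopifnot(is(x, "SequenceSet"), is(fs, "FrequentSubsequences"))
  i <- integer(); j <- integer(); v <- integer()
  for (col in seq_along(fs@residues)) {
    rows <- match(fs@supportIds[[col]], x@ids)
    rows <- rows[!is.na(rows)]
    if (length(rows) == 0L) next
    cnt <- .countOccurrences(fs@residues[col], x@residues[rows])
    nz <- cnt > 0L
    i <- c(i, rows[nz]); j <- c(j, rep(col, sum(nz))); v <- c(v, cnt[nz])
  }
  m <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(v),
                            dims = c(length(x), length(fs@residues)),
                            dimnames = list(x@ids, fs@residues))
  new("OccurrenceTable", counts = m)
}

#' Expand duplicate symbols into a transaction table
#'
#' A symbol occurring n times in a sequence is translated into the items
#' symbol, 2xsymbol, ..., nxsymbol, so that item "k x symbol" is present
#' exactly when the symbol occurs at least k times. This makes closed
#' frequent itemset mining over unique items equivalent to mining
#' multisets with duplicates, and the expansion is lossless: the count is
#' recovered as the largest k whose item is present.
#'
#' @param table An [OccurrenceTable-class].
#' @return A list with elements `transactions` (list of character item
#'   vectors, one per sequence, named by sequence id), `itemSymbols`
#'   (character: the subsequence behind each item id) and `itemCounts`
#'   (integer: the multiplicity k behind each item id), the latter two
#'   named by item id.
#' @export
expandDuplicates <- function(table) {
  stopifnot(is(table, "OccurrenceTable"))
  m <- table@counts
  symbols <- colnames(m)
  maxCount <- if (ncol(m)) apply(m, 2L, max) else numeric(0)
  itemIds <- character(); itemSym <- character(); itemK <- integer()
  for (c0 in seq_along(symbols)) {
    if (maxCount[c0] < 1) next
    ks <- seq_len(maxCount[c0])
    ids <- ifelse(ks == 1L, symbols[c0], paste0(ks, "x", symbols[c0]))
    itemIds <- c(itemIds, ids)
    itemSym <- c(itemSym, rep(symbols[c0], length(ks)))
    itemK <- c(itemK, ks)
  }
  transactions <- lapply(seq_len(nrow(m)), function(r) {
    cnt <- m[r, ]
    out <- character()
    for (c0 in which(cnt > 0)) {
      ks <- seq_len(cnt[c0])
      out <- c(out, ifelse(ks == 1L, symbols[c0], paste0(ks, "x", symbols[c0])))
    }
    out
  })
  names(transactions) <- rownames(m)
  list(transactions = transactions,
       itemSymbols = setNames(itemSym, itemIds),
       itemCounts = setNames(itemK, itemIds))
}
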