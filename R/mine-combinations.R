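#' Mine closed frequent symbol combinations
#'
#' Enumerates exactly the closed frequent itemsets of the expanded
#' transaction table: itemsets to which no item can be added without
#' shrinking the supporting-sequence set. The search is a depth-first
#' traversal of the item lattice with prefix-preserving closure extension
#' (each closed set is produced once), driven by an explicit stack rather
#' than call-stack recursion so that symbol counts in the thousands cannot
#' exhaust it. Item ids are translated back to multisets of subsequence
#' symbols with multiplicities.
#'
#' @param transactions Output of [expandDuplicates()], or a bare list of
#'   character item vectors (then items are their own symbols with
#'   multiplicity 1).
#' @param minSupport Minimum number of supporting sequences (>= 1).
#' @return A [SymbolCombinations-class] in a deterministic order
#'   (decreasing support, then by combination string).
#' @export
mineClosedCombinations <- function(transactions, minSupport) {
  if (is.list(transactions) && !is.null(transactions$transactions)) {
    tx <- transactions$transactions
    itemSym <- transactions$itemSymbols
    itemK <- transactions$itemCounts
  } else {
    tx <- transactions
    u <- sort(unique(unlist(tx)))
    itemSym <- setNames(u, u)
    itemK <- setNames(rep(1L, length(u)), u)
  }
  minSupport <- as.integer(minSupport)
  if (is.na(minSupport) || minSupport < 1L)
    stop("minSupport must be >= 1")
  if (is.null(names(tx))) names(tx) <- as.character(seq_along(tx))

  items <- names(itemSym)
  tidsets <- lapply(items, function(it)
    which(vapply(tx, function(t) it %in% t, logical(1L))))
  names(tidsets) <- items
  supp <- vapply(tidsets, length, 1L)
  items <- items[supp >= minSupport]
  if (length(items) == 0L || length(tx) < minSupport)
    return(new("SymbolCombinations", symbols = list(), supportIds = list()))
  ## DFS item order: descending support, ties lexicographic
  items <- items[order(-supp[items], items, method = "radix")]
  tidsets <- tidsets[items]
  ni <- length(items)

  found <- list()   # each: list(set = item indices, tid = tidset)
  ## node: (P = item index set, tid, core = index of last extension, 0 at root)
  stack <- list(list(P = integer(0), tid = seq_along(tx), core = 0L))
  while (length(stack) > 0L) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    inClo <- vapply(seq_len(ni), function(j)
      all(node$tid %in% tidsets[[j]]), logical(1L))
    clo <- which(inClo)
    ## prefix-preserving test: a closure item before the core that is not
    ## already in P means this closed set belongs to another branch
    if (any(clo < node$core & !(clo %in% node$P))) next
    C <- sort(union(node$P, clo))
    if (length(C) > 0L)
      found[[length(found) + 1L]] <- list(set = C, tid = node$tid)
    ext <- setdiff(seq_len(ni), C)
    ext <- ext[ext > node$core]
    for (e in rev(ext)) {
      tid <- intersect(node$tid, tidsets[[e]])
      if (length(tid) >= minSupport)
        stack[[length(stack) + 1L]] <- list(P = c(C, e), tid = tid, core = e)
    }
  }

  symbols <- lapply(found, function(node) {
    its <- items[node$set]
    mult <- tapply(itemK[its], itemSym[its], max)
    out <- as.integer(mult)
    names(out) <- names(mult)
    out[order(names(out), method = "radix")]
  })
  supportIds <- lapply(found, function(node) names(tx)[sort(node$tid)])
  keyOf <- vapply(symbols, function(s)
    paste(paste0(s, "x", names(s)), collapse = " "), "")
  ord <- order(-vapply(supportIds, length, 1L), keyOf, method = "radix")
  new("SymbolCombinations", symbols = symbols[ord],
      supportIds = supportIds[ord])
}
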