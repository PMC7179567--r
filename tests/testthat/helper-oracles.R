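# Independent brute-force oracles used to cross-check the miners and the
# matcher. These deliberately share no code with the implementation.

# All distinct substrings of `seqs` with length in [minLen, maxLen] and
# per-sequence support >= minSupport; returns a data.frame with the
# substring and a canonical support key (sorted ids, ";"-joined).
oracleFrequentSubstrings <- function(seqs, minSupport, minLen, maxLen) {
  stopifnot(!is.null(names(seqs)))
  subs <- unique(unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    out <- character(0)
    for (L in minLen:min(maxLen, n))
      out <- c(out, substring(s, 1:(n - L + 1L), L:n))
    out
  })))
  sup <- lapply(subs, function(p) sort(names(seqs)[grepl(p, seqs, fixed = TRUE)]))
  keep <- lengths(sup) >= minSupport
  data.frame(residues = subs[keep],
             supportKey = vapply(sup[keep], paste, "", collapse = ";"),
             stringsAsFactors = FALSE)
}

# Pairwise-containment closure oracle: drop a substring iff some other
# candidate is a proper superstring with the identical support key.
oracleClosure <- function(df, keepLongestAbove = Inf) {
  n <- nrow(df)
  drop <- logical(n)
  for (i in seq_len(n)) {
    if (nchar(df$residues[i]) > keepLongestAbove) next
    for (j in seq_len(n)) {
      if (i == j) next
      if (nchar(df$residues[j]) > nchar(df$residues[i]) &&
          df$supportKey[j] == df$supportKey[i] &&
          grepl(df$residues[i], df$residues[j], fixed = TRUE)) {
        drop[i] <- TRUE
        break
      }
    }
  }
  df[!drop, , drop = FALSE]
}

# Powerset closed-frequent-itemset oracle over <= 31 unique items,
# transactions encoded as bitmasks. Returns a sorted character vector of
# "item,item,..." keys of the closed frequent itemsets.
oracleClosedItemsets <- function(transactions, minSupport) {
  items <- sort(unique(unlist(transactions)))
  stopifnot(length(items) <= 31L)
  masks <- vapply(transactions, function(t)
    sum(bitwShiftL(1L, match(unique(t), items) - 1L)), 0L)
  nSets <- bitwShiftL(1L, length(items))
  keys <- character(0)
  for (S in seq_len(nSets - 1L)) {
    tid <- which(bitwAnd(masks, S) == S)
    if (length(tid) < minSupport) next
    ## closed iff adding any single item shrinks the tid set
    closed <- TRUE
    for (j in seq_along(items)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(S, bit) == bit) next
      if (all(bitwAnd(masks[tid], bit) == bit)) { closed <- FALSE; break }
    }
    if (closed)
      keys <- c(keys, paste(items[bitwAnd(S, bitwShiftL(1L, seq_along(items) - 1L)) > 0L],
                            collapse = ","))
  }
  sort(keys)
}

# Minimum edit distance between `pattern` and any substring of `text`
# (free start/end in the text), by the textbook dynamic programme.
oracleInfixEditDistance <- function(pattern, text) {
  p <- strsplit(pattern, "")[[1L]]
  t <- strsplit(text, "")[[1L]]
  m <- length(p); n <- length(t)
  prev <- rep(0L, n + 1L)
  for (i in seq_len(m)) {
    cur <- integer(n + 1L)
    cur[1L] <- i
    for (j in seq_len(n)) {
      cur[j + 1L] <- min(prev[j] + (p[i] != t[j]),
                         prev[j + 1L] + 1L,
                         cur[j] + 1L)
    }
    prev <- cur
  }
  min(prev)
}

randomSeqSet <- function(n, lenRange, alphabet = "DNA", prefix = "r") {
  res <- alphabetResidues(alphabet)
  lens <- sample(seq.int(lenRange[1L], lenRange[2L]), n, replace = TRUE)
  SequenceSet(paste0(prefix, seq_len(n)),
              vapply(lens, function(L)
                paste(sample(res, L, replace = TRUE), collapse = ""), ""),
              alphabet = alphabet)
}

randomTransactions <- function(nTx, nItems, density = 0.4) {
  items <- paste0("I", seq_len(nItems))
  tx <- lapply(seq_len(nTx), function(i)
    items[runif(nItems) < density])
  names(tx) <- paste0("t", seq_len(nTx))
  tx
}

# Canonical "item,item,..." key for a combination multiset as the
# powerset oracle spells it (k-fold items named I, 2xI, ...).
comboKey <- function(symbols) {
  toks <- unlist(lapply(seq_along(symbols), function(k) {
    s <- names(symbols)[k]
    vapply(seq_len(symbols[[k]]), function(i)
      if (i == 1L) s else paste0(i, "x", s), "")
  }))
  paste(sort(toks), collapse = ",")
}
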