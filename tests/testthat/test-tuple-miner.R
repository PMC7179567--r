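.fsFromStrings <- function(strings, set) {
  # helper: wrap plain strings as a mined FrequentSubsequences object
  sup <- lapply(strings, function(p)
    seqIds(set)[grepl(p, unname(residues(set)), fixed = TRUE)])
  new("FrequentSubsequences", residues = strings, supportIds = sup,
      occurrenceTotal = vapply(strings, function(p)
        sum(vapply(gregexpr(p, unname(residues(set)), fixed = TRUE),
                   function(m) if (m[1] == -1L) 0L else length(m), 1L)), 1L))
}

test_that("occurrence table counts leftmost-greedy non-overlapping matches", {
  set <- SequenceSet(c("s1", "s2"), c("ACGACGACG", "TTTTT"))
  tab <- buildOccurrenceTable(set, .fsFromStrings(c("ACGACG", "ACG"), set))
  m <- as.matrix(occurrenceCounts(tab))
  expect_equal(m["s1", "ACGACG"], 1)   # overlap forbidden
  expect_equal(m["s1", "ACG"], 3)
  expect_equal(unname(m["s2", ]), c(0, 0))  # all-zero row

  # two sequences each containing both symbols once -> [[1,1],[1,1]]
  toy <- SequenceSet(c("IDi", "IDj"),
                     c("GGAGGAGAUGGGGCCUGGAGACUAAG",
                       "CCGGAGAUGAAUGGAGACUCC"), alphabet = "RNA")
  tab2 <- buildOccurrenceTable(toy,
    .fsFromStrings(c("GGAGAUG", "UGGAGACU"), toy))
  expect_equal(unname(as.matrix(occurrenceCounts(tab2))),
               matrix(1, 2, 2))
})

test_that("duplicate expansion is lossless and matches the k-of-n rule", {
  set <- SequenceSet(c("s1", "s2", "s3"),
                     c("ACGACGTTTT", "ACGTTACGTACG", "GGGG"))
  tab <- buildOccurrenceTable(set, .fsFromStrings(c("ACG", "TT"), set))
  tx <- expandDuplicates(tab)
  expect_setequal(tx$transactions$s1, c("ACG", "2xACG", "TT", "2xTT"))
  expect_setequal(tx$transactions$s2, c("ACG", "2xACG", "3xACG", "TT"))
  expect_equal(tx$transactions$s3, character(0))
  # reconstruction: count = max k with the k-item present
  m <- as.matrix(occurrenceCounts(tab))
  for (id in seqIds(set)) for (sym in colnames(m)) {
    ks <- tx$itemCounts[tx$transactions[[id]][tx$itemSymbols[tx$transactions[[id]]] == sym]]
    expect_equal(if (length(ks)) max(ks) else 0L, unname(m[id, sym]))
  }
})

test_that("closed combination mining keeps only maximal equal-support sets", {
  tx <- list(IDi = c("a", "b"), IDj = c("a", "b"))
  combos <- mineClosedCombinations(tx, 2)
  expect_length(combos, 1L)
  expect_equal(combinationSymbols(combos)[[1]], c(a = 1L, b = 1L))
  expect_setequal(supportIds(combos)[[1]], c("IDi", "IDj"))

  # singleton kept iff support suffices
  tx2 <- list(t1 = "a", t2 = "a", t3 = character(0))
  expect_length(mineClosedCombinations(tx2, 2), 1L)
  expect_length(mineClosedCombinations(tx2, 3), 0L)
  expect_error(mineClosedCombinations(tx2, 0), "minSupport")
})

test_that("closed combination mining equals the powerset oracle", {
  set.seed(421)
  for (rep in 1:20) {
    tx <- randomTransactions(8, 6)
    for (thr in c(1L, 2L, 3L)) {
      combos <- mineClosedCombinations(tx, thr)
      got <- sort(vapply(combinationSymbols(combos), comboKey, ""))
      expect_equal(got, oracleClosedItemsets(tx, thr),
                   info = sprintf("rep %d thr %d", rep, thr))
    }
  }
})

test_that("duplicate symbols participate in combinations as k-th items", {
  # alpha twice and beta once in both sequences
  set <- SequenceSet(c("IDi", "IDj"),
                     c("GGAGGAGAUGGUGGAGAUGCCUGGAGACUAG",
                       "AAGGAGAUGAAGGAGAUGAAUGGAGACUAA"), alphabet = "RNA")
  tab <- buildOccurrenceTable(set, .fsFromStrings(c("GGAGAUG", "UGGAGACU"), set))
  combos <- mineClosedCombinations(expandDuplicates(tab), 2)
  expect_length(combos, 1L)
  expect_equal(combinationSymbols(combos)[[1]],
               c(GGAGAUG = 2L, UGGAGACU = 1L))
})

test_that("tuples are ordered permutations with placement frequencies", {
  # the worked-example sequence yields <GGAGAUG, UGGAGACU> once
  set <- SequenceSet("S", "GGAGGAGAUGGGGUCCUGGAGACUAAG", alphabet = "RNA")
  tab <- buildOccurrenceTable(set, .fsFromStrings(c("GGAGAUG", "UGGAGACU"), set))
  combos <- mineClosedCombinations(expandDuplicates(tab), 1)
  tuples <- deriveOrderedTuples(combos, set, 1)
  expect_true(any(vapply(tupleMembers(tuples), identical,
                         TRUE, c("GGAGAUG", "UGGAGACU"))))
  k <- which(vapply(tupleMembers(tuples), identical,
                    TRUE, c("GGAGAUG", "UGGAGACU")))
  expect_equal(tupleFrequency(tuples)[k], 1L)

  # single-symbol combination: frequency equals the total occurrence count
  set2 <- SequenceSet(c("a", "b"), c("ACGACGACGTT", "TTACG"))
  tab2 <- buildOccurrenceTable(set2, .fsFromStrings("ACG", set2))
  tuples2 <- deriveOrderedTuples(mineClosedCombinations(expandDuplicates(tab2), 2),
                                 set2, 1)
  k2 <- which(vapply(tupleMembers(tuples2), identical, TRUE, "ACG"))
  expect_equal(tupleFrequency(tuples2)[k2], 4L)
})

test_that("opposite member orders become distinct tuples with split counts", {
  alpha <- "GGAGAUGCC"; beta <- "UUGGAGACU"
  mk <- function(first, second, i)
    paste0("AAAA", first, "CAGUC", second, "GGGG")
  seqs <- c(vapply(1:10, function(i) mk(alpha, beta, i), ""),
            vapply(1:10, function(i) mk(beta, alpha, i), ""))
  set <- SequenceSet(paste0("q", 1:20), seqs, alphabet = "RNA")
  tab <- buildOccurrenceTable(set, .fsFromStrings(c(alpha, beta), set))
  combos <- mineClosedCombinations(expandDuplicates(tab), 2)
  tuples <- deriveOrderedTuples(combos, set, 1)
  ab <- which(vapply(tupleMembers(tuples), identical, TRUE, c(alpha, beta)))
  ba <- which(vapply(tupleMembers(tuples), identical, TRUE, c(beta, alpha)))
  expect_equal(tupleFrequency(tuples)[ab], 10L)
  expect_equal(tupleFrequency(tuples)[ba], 10L)
  # permutation frequencies of one combination sum to its total placements
  expect_equal(sum(tupleFrequency(tuples)[c(ab, ba)]), 20L)
})

test_that("every tuple's member multiset is an emitted combination", {
  set.seed(422)
  set <- randomSeqSet(12, c(20, 40))
  fs <- closureFilter(mineFrequentSubstrings(set,
    minerConfig(minSupport = 4, minLen = 2, maxLen = 6)))
  combos <- mineClosedCombinations(expandDuplicates(buildOccurrenceTable(set, fs)), 4)
  tuples <- deriveOrderedTuples(combos, set, 1)
  comboKeys <- vapply(combinationSymbols(combos), comboKey, "")
  for (mem in tupleMembers(tuples)) {
    tabm <- table(mem)
    ms <- setNames(as.integer(tabm), names(tabm))
    expect_true(comboKey(ms[order(names(ms))]) %in% comboKeys)
  }
})

test_that("gaps between tuple members are unbounded", {
  alpha <- "GGAGAUGCCUGA"; beta <- "UUGGAGACUCAG"
  near <- generateSyntheticDataset(10, c(alpha, beta), exactFraction = 1,
                                   gapRange = c(5, 5), seed = 423)
  far <- generateSyntheticDataset(10, c(alpha, beta), exactFraction = 1,
                                  gapRange = c(500, 500), seed = 424)
  tupleOf <- function(set) {
    tab <- buildOccurrenceTable(set, .fsFromStrings(c(alpha, beta), set))
    tuples <- deriveOrderedTuples(
      mineClosedCombinations(expandDuplicates(tab), 10), set, 10)
    tupleMembers(tuples)[[which(tupleFrequency(tuples) == 10L)[1]]]
  }
  expect_equal(tupleOf(near$sequences), c(alpha, beta))
  expect_equal(tupleOf(far$sequences), c(alpha, beta))
})
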