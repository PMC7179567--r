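workedTuple <- c("GGAGAUG", "UGGAGACU")
workedRecord <- "SUB 0 5 U C DEL 1 6 C"

workedProfileSet <- function(seed = 501) {
  generateSyntheticDataset(23, workedTuple, exactFraction = 16 / 23,
                           variantSpecs = list(list(record = workedRecord,
                                                    fraction = 7 / 23)),
                           seed = seed)
}

test_that("profiling counts exact placements and per-record frequencies", {
  g <- workedProfileSet()
  prof <- buildProfiles(list(workedTuple), g$sequences)
  expect_equal(exactFrequency(prof), 16L)
  e <- profileEntries(prof)[[1]]
  expect_equal(e$record, workedRecord)
  expect_equal(e$frequency, 7L)

  # no approximate placements -> no entries
  g2 <- generateSyntheticDataset(10, workedTuple, exactFraction = 1,
                                 seed = 502)
  prof2 <- buildProfiles(list(workedTuple), g2$sequences)
  expect_equal(exactFrequency(prof2), 10L)
  expect_equal(nrow(profileEntries(prof2)[[1]]), 0L)
})

test_that("planted variant fractions are recovered exactly from the manifest", {
  g <- generateSyntheticDataset(40, c("GGAGAUGCA", "UCUGGAGACU"),
    exactFraction = 0.5,
    variantSpecs = list(list(record = "SUB 0 4 A G", fraction = 0.25),
                        list(record = "DEL 1 3 G", fraction = 0.125)),
    seed = 503)
  prof <- buildProfiles(list(c("GGAGAUGCA", "UCUGGAGACU")), g$sequences)
  expect_equal(exactFrequency(prof), sum(g$manifest$role == "exact"))
  e <- profileEntries(prof)[[1]]
  for (v in 1:2) {
    rec <- unique(g$manifest$record[which(g$manifest$variant == v)])
    expect_equal(e$frequency[e$record == rec],
                 sum(g$manifest$variant == v, na.rm = TRUE))
  }
})

test_that("the descriptor component follows the exact/approximate/otherwise rule", {
  g <- workedProfileSet()
  prof <- buildProfiles(list(workedTuple), g$sequences)
  # exact match -> 1.0
  expect_identical(encodeSequence("GGAGGAGAUGGGGUCCUGGAGACUAAG", prof), 1)
  # recognised approximate match -> record frequency / exact frequency
  expect_identical(encodeSequence("GGAGGAGACGGGUCCUGGAGAUAAG", prof),
                   7 / 16)
  # sequence containing neither member -> 0
  expect_identical(encodeSequence("CCCCCCCCCCCCCCCCCCCC", prof), 0)
  # approximate match whose record is not in the profile -> 0
  other <- applyRecord(workedTuple, "SUB 0 0 G A SUB 1 0 U A")
  expect_identical(encodeSequence(paste0("AAAA", other[1], "CCCCC", other[2]),
                                  prof), 0)
})

test_that("sequences that contributed exact placements encode to 1", {
  g <- workedProfileSet(seed = 504)
  prof <- buildProfiles(list(workedTuple), g$sequences)
  vec <- encodeSequences(g$sequences, prof)
  exactIds <- g$manifest$id[g$manifest$role == "exact"]
  expect_true(all(vec[exactIds, 1] == 1))
  varIds <- g$manifest$id[g$manifest$role == "variant"]
  expect_true(all(vec[varIds, 1] == 7 / 16))
  bgIds <- g$manifest$id[g$manifest$role == "background"]
  expect_true(all(vec[bgIds, 1] == 0))
})

test_that("an approximate match with zero exact frequency scores 0", {
  prof <- new("MutationProfiles", tuples = list(workedTuple),
              exactFrequency = 0L,
              entries = list(data.frame(record = workedRecord,
                                        frequency = 3L)))
  v <- applyRecord(workedTuple, workedRecord)
  expect_identical(encodeSequence(paste0("AA", v[1], "CCCCC", v[2], "AA"),
                                  prof), 0)
})

test_that("libsvm output matches the sparse format and parses back", {
  f <- withr::local_tempfile(fileext = ".libsvm")
  writeLibsvm(rbind(c(1.0, 0, 0.4375), c(0, 0, 0)), c("+1", "-1"), f)
  expect_identical(readLines(f), c("+1 1:1.0 3:0.4375", "-1"))

  set.seed(505)
  m <- matrix(round(runif(60), 4), nrow = 10)
  m[m < 0.4] <- 0
  lab <- sample(c("+1", "-1"), 10, replace = TRUE)
  writeLibsvm(m, lab, f)
  back <- readLibsvm(f, nFeatures = ncol(m))
  expect_equal(back$values, unname(m))
  expect_equal(back$labels, as.numeric(lab))
  # independent parse with base R
  line1 <- strsplit(readLines(f)[1], " ")[[1]]
  expect_equal(line1[1], lab[1])
  kv <- do.call(rbind, strsplit(line1[-1], ":"))
  expect_equal(as.numeric(kv[, 2]), unname(m[1, m[1, ] != 0]))
  expect_equal(as.integer(kv[, 1]), which(m[1, ] != 0))

  expect_error(writeLibsvm(m, lab[-1], f), "labels")
  expect_error(writeLibsvm(m, rep("x", 10), f), "labels")
})

test_that("feature and profile files round-trip bit-exactly", {
  g <- workedProfileSet(seed = 506)
  prof <- buildProfiles(list(workedTuple), g$sequences)
  ff <- withr::local_tempfile(fileext = ".Feature")
  pf <- withr::local_tempfile(fileext = ".FeatureProfile")
  writeFeatureFile(list(workedTuple), ff)
  writeProfileFile(prof, pf)
  expect_identical(readFeatureFile(ff), list(workedTuple))
  back <- readProfileFile(pf)
  expect_identical(tupleMembers(back), tupleMembers(prof))
  expect_identical(exactFrequency(back), exactFrequency(prof))
  expect_identical(profileEntries(back)[[1]]$record,
                   profileEntries(prof)[[1]]$record)
  expect_identical(profileEntries(back)[[1]]$frequency,
                   profileEntries(prof)[[1]]$frequency)
  # writing the reread object reproduces the file byte for byte
  pf2 <- withr::local_tempfile()
  writeProfileFile(back, pf2)
  expect_identical(readLines(pf2), readLines(pf))
})

test_that("PSSM conversion reflects exact and substitution counts", {
  g <- workedProfileSet()
  prof <- buildProfiles(list(workedTuple), g$sequences)
  mats <- toPSSM(prof)
  expect_length(mats, 2L)
  m0 <- mats[[1]]
  expect_equal(attr(m0, "member"), "GGAGAUG")
  # position 5 of member 0: consensus U seen 16x, substituted C seen 7x
  expect_equal(m0["U", "5"], 16)
  expect_equal(m0["C", "5"], 7)
  # untouched positions accumulate the entry frequency on the consensus
  expect_equal(m0["G", "0"], 23)
  # member 1 position 6 is deleted in the only entry: count stays 16
  m1 <- mats[[2]]
  expect_equal(m1["C", "6"], 16)
  expect_equal(sum(m1[, "6"]), 16)

  # conservation invariant: column sum = exact + SUB-at-position + untouched
  ef <- exactFrequency(prof)[1]
  e <- profileEntries(prof)[[1]]
  for (mem in 1:2) {
    L <- nchar(workedTuple[mem])
    for (p in 0:(L - 1)) {
      contrib <- ef
      for (k in seq_len(nrow(e))) {
        ev <- parseRecord(e$record[k])
        ev <- ev[ev$member == mem - 1L & ev$position == p &
                 ev$kind %in% c("SUB", "DEL"), , drop = FALSE]
        if (nrow(ev) == 0L || ev$kind[1] == "SUB")
          contrib <- contrib + e$frequency[k]
      }
      expect_equal(sum(mats[[mem]][, as.character(p)]), contrib)
    }
  }
})

test_that("degenerate profiles and normalization behave as specified", {
  g <- generateSyntheticDataset(6, workedTuple, exactFraction = 1, seed = 507)
  prof <- buildProfiles(list(workedTuple), g$sequences)
  mats <- toPSSM(prof)
  # no entries: one-hot consensus columns scaled by the exact frequency
  expect_true(all(colSums(mats[[1]] > 0) == 1))
  expect_true(all(colSums(mats[[1]]) == 6))

  norm <- toPSSM(prof, normalize = TRUE, pseudocount = 0.5)
  expect_true(all(abs(colSums(norm[[1]]) - 1) < 1e-9))

  empty <- new("MutationProfiles", tuples = list(workedTuple),
               exactFrequency = 0L,
               entries = list(data.frame(record = character(),
                                         frequency = integer())))
  expect_error(toPSSM(empty), "empty profile")
})
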