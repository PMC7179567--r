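.asSequenceSet <- function(x, alphabet, labels = "unlabeled") {
  if (is(x, "SequenceSet")) x else readFastaSet(x, alphabet, labels)
}

#' Generate feature and profile files from a feature dataset
#'
#' Runs the full discovery pipeline on one (unlabeled) sequence set:
#' frequent-substring mining, closure filtering, occurrence table,
#' duplicate expansion, closed combination mining, ordered tuple
#' derivation, and mutation profiling. Writes `<outPrefix>.Feature` (the
#' tuple list) and `<outPrefix>.FeatureProfile` (the mutation profiles)
#' and logs the size of every stage to standard error.
#'
#' @param fasta Path to a FASTA file, or a [SequenceSet-class].
#' @param outPrefix Output path prefix.
#' @param alphabet Alphabet of the FASTA input.
#' @param minSupport,supportRatio,minLen,maxLen,keepLongestAbove Miner
#'   settings; see [minerConfig()].
#' @param combinationSupport Support threshold for combination mining;
#'   defaults to the resolved miner threshold.
#' @param tupleMinFrequency Minimum placement count for a permutation to
#'   become a tuple; defaults to `combinationSupport`.
#' @param scoring [ScoringScheme-class] for profiling (`maxEdits` edits at
#'   unit penalties correspond to `minScore = -maxEdits`).
#' @param verbose Log stage counts via [message()].
#' @return Invisibly, a list with every intermediate stage and the two
#'   output paths (`featureFile`, `profileFile`).
#' @export
featureGen <- function(fasta, outPrefix, alphabet = "DNA",
                       minSupport = NA, supportRatio = NA,
                       minLen = 1L, maxLen = 30L, keepLongestAbove = Inf,
                       combinationSupport = NULL, tupleMinFrequency = NULL,
                       scoring = scoringScheme(), verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  x <- .asSequenceSet(fasta, alphabet)
  say("read %d sequence(s)", length(x))
  config <- minerConfig(minSupport = minSupport, supportRatio = supportRatio,
                        minLen = minLen, maxLen = maxLen,
                        keepLongestAbove = keepLongestAbove)
  thr <- .resolveMinSupport(config, length(x))
  fs <- mineFrequentSubstrings(x, config)
  say("mined %d frequent substring(s) at support >= %d", length(fs), thr)
  if (length(fs) == 0L)
    stop("no frequent subsequences found; lower the support threshold or ",
         "widen the length range")
  closed <- closureFilter(fs, keepLongestAbove = config@keepLongestAbove)
  say("%d closed subsequence(s) after closure filtering", length(closed))
  tab <- buildOccurrenceTable(x, closed)
  tx <- expandDuplicates(tab)
  if (is.null(combinationSupport)) combinationSupport <- thr
  combos <- mineClosedCombinations(tx, combinationSupport)
  say("%d closed frequent combination(s) at support >= %d", length(combos),
      combinationSupport)
  if (is.null(tupleMinFrequency)) tupleMinFrequency <- combinationSupport
  tuples <- deriveOrderedTuples(combos, x, tupleMinFrequency)
  say("%d ordered tuple(s) at frequency >= %d", length(tuples),
      tupleMinFrequency)
  if (length(tuples) == 0L)
    stop("no frequent tuples survive; lower the support threshold")
  profiles <- buildProfiles(tuples, x, scoring)
  say("profiled %d tuple(s); %d mutation record entr(ies) in total",
      length(profiles), sum(vapply(profiles@entries, nrow, 1L)))
  featureFile <- paste0(outPrefix, ".Feature")
  profileFile <- paste0(outPrefix, ".FeatureProfile")
  writeFeatureFile(tuples, featureFile)
  writeProfileFile(profiles, profileFile)
  say("wrote %s and %s", featureFile, profileFile)
  invisible(list(sequences = x, subsequences = fs, closed = closed,
                 table = tab, combinations = combos, tuples = tuples,
                 profiles = profiles, featureFile = featureFile,
                 profileFile = profileFile))
}

.readValidatedProfiles <- function(featureFile, profileFile) {
  tuples <- readFeatureFile(featureFile)
  profiles <- readProfileFile(profileFile)
  if (!identical(tuples, profiles@tuples))
    stop("feature file and profile file disagree on the tuple set")
  profiles
}

#' Generate a labeled libsvm file from feature/profile files
#'
#' Encodes a positive and a negative FASTA set against previously
#' generated tuples and profiles and writes the labeled sparse matrix:
#' positives first with label +1, then negatives with label -1.
#'
#' @param featureFile,profileFile Paths written by [featureGen()].
#' @param positiveFasta,negativeFasta FASTA paths (or
#'   [SequenceSet-class]s).
#' @param out Output libsvm path.
#' @param alphabet Alphabet of the FASTA inputs.
#' @param scoring [ScoringScheme-class] used for matching.
#' @return Invisibly, `out`.
#' @export
libsvmGenWithFeature <- function(featureFile, profileFile, positiveFasta,
                                 negativeFasta, out, alphabet = "DNA",
                                 scoring = scoringScheme()) {
  profiles <- .readValidatedProfiles(featureFile, profileFile)
  pos <- .asSequenceSet(positiveFasta, alphabet, "positive")
  neg <- .asSequenceSet(negativeFasta, alphabet, "negative")
  if (length(pos) == 0L) stop("positive dataset is empty")
  if (length(neg) == 0L) stop("negative dataset is empty")
  values <- rbind(encodeSequences(pos, profiles, scoring),
                  encodeSequences(neg, profiles, scoring))
  labels <- c(rep("+1", length(pos)), rep("-1", length(neg)))
  writeLibsvm(values, labels, out)
  invisible(out)
}

#' Convert feature/profile files to a PSSM file
#'
#' @param featureFile,profileFile Paths written by [featureGen()].
#' @param out Output PSSM path.
#' @param normalize,pseudocount,alphabet Passed to [toPSSM()].
#' @return Invisibly, `out`.
#' @export
motifToPSSM <- function(featureFile, profileFile, out, normalize = FALSE,
                        pseudocount = 0, alphabet = NULL) {
  profiles <- .readValidatedProfiles(featureFile, profileFile)
  writePSSMFile(profiles, out, normalize = normalize,
                pseudocount = pseudocount, alphabet = alphabet)
  invisible(out)
}
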