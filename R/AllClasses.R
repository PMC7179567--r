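#' @import methods
#' @importFrom stats setNames
NULL

.ALPHABETS <- list(
  DNA     = c("A", "C", "G", "T"),
  RNA     = c("A", "C", "G", "U"),
  protein = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
              "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
)

#' Residue symbols of a named alphabet
#'
#' @param name One of `"DNA"`, `"RNA"` or `"protein"`.
#' @return Character vector of residue symbols in canonical order.
#' @examples
#' alphabetResidues("RNA")
#' @export
alphabetResidues <- function(name) {
  name <- match.arg(name, names(.ALPHABETS))
  .ALPHABETS[[name]]
}

#' SequenceSet: a validated set of sequences
#'
#' Container for one dataset of same-alphabet sequences. Residues are
#' uppercase; T and U are never interconverted, so a dataset is either DNA
#' or RNA (or protein), never a mixture.
#'
#' @slot ids Character vector of unique sequence identifiers.
#' @slot residues Character vector of residue strings, parallel to `ids`.
#' @slot alphabet Alphabet name, one of `"DNA"`, `"RNA"`, `"protein"`.
#' @slot labels Character vector parallel to `ids`; each element one of
#'   `"positive"`, `"negative"`, `"unlabeled"`.
#' @export
setClass("SequenceSet",
  representation(ids = "character", residues = "character",
                 alphabet = "character", labels = "character"),
  prototype(alphabet = "DNA")
)

setValidity("SequenceSet", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (length(object@residues) != n)
    msg <- c(msg, "ids and residues must have equal length")
  if (length(object@labels) != n)
    msg <- c(msg, "labels must be parallel to ids")
  if (anyDuplicated(object@ids))
    msg <- c(msg, sprintf("duplicate sequence id: %s",
                          object@ids[duplicated(object@ids)][1L]))
  if (length(object@alphabet) != 1L ||
      !object@alphabet %in% names(.ALPHABETS))
    msg <- c(msg, "alphabet must be one of DNA, RNA, protein")
  else if (n > 0L) {
    if (any(!nzchar(object@residues)))
      msg <- c(msg, sprintf("empty residue string for record '%s'",
                            object@ids[!nzchar(object@residues)][1L]))
    ok <- .ALPHABETS[[object@alphabet]]
    bad <- vapply(strsplit(object@residues, "", fixed = TRUE),
                  function(ch) any(!ch %in% ok), logical(1L))
    if (any(bad))
      msg <- c(msg, sprintf(
        "record '%s' contains residues outside the %s alphabet",
        object@ids[bad][1L], object@alphabet))
  }
  if (n > 0L && any(!object@labels %in% c("positive", "negative", "unlabeled")))
    msg <- c(msg, "labels must be positive/negative/unlabeled")
  if (length(msg)) msg else TRUE
})

#' Construct a SequenceSet
#'
#' @param ids Character vector of unique identifiers.
#' @param residues Character vector of residue strings (uppercased on
#'   construction).
#' @param alphabet `"DNA"`, `"RNA"` or `"protein"`.
#' @param labels Optional labels (`"positive"`, `"negative"`,
#'   `"unlabeled"`); recycled scalar allowed.
#' @return A [SequenceSet-class] object.
#' @examples
#' SequenceSet(c("s1", "s2"), c("ACGT", "ACGACG"))
#' @export
SequenceSet <- function(ids, residues, alphabet = "DNA",
                        labels = "unlabeled") {
  ids <- as.character(ids)
  residues <- toupper(as.character(residues))
  if (length(labels) == 1L) labels <- rep(labels, length(ids))
  new("SequenceSet", ids = ids, residues = residues,
      alphabet = alphabet, labels = labels)
}

#' MinerConfig: thresholds for frequent-substring mining
#'
#' Exactly one of an absolute support count or a support ratio is set;
#' lengths bound the mined substrings; `keepLongestAbove` exempts long
#' subsequences from closure elimination.
#'
#' @slot minSupport Absolute minimum number of supporting sequences
#'   (`NA` when `supportRatio` is used).
#' @slot supportRatio Minimum fraction of the dataset (`NA` when
#'   `minSupport` is used).
#' @slot minLen,maxLen Inclusive residue-length bounds.
#' @slot keepLongestAbove Length above which a subsequence is retained
#'   unconditionally (never closure-eliminated); `Inf` disables.
#' @export
setClass("MinerConfig",
  representation(minSupport = "numeric", supportRatio = "numeric",
                 minLen = "integer", maxLen = "integer",
                 keepLongestAbove = "numeric"))

setValidity("MinerConfig", function(object) {
  msg <- character()
  if (is.na(object@minSupport) == is.na(object@supportRatio))
    msg <- c(msg, "exactly one of minSupport / supportRatio must be set")
  if (!is.na(object@minSupport) && object@minSupport < 1)
    msg <- c(msg, "minSupport must be >= 1")
  if (!is.na(object@supportRatio) &&
      (object@supportRatio <= 0 || object@supportRatio > 1))
    msg <- c(msg, "supportRatio must lie in (0, 1]")
  if (object@minLen < 1L) msg <- c(msg, "minLen must be >= 1")
  if (object@maxLen < object@minLen) msg <- c(msg, "maxLen must be >= minLen")
  if (length(msg)) msg else TRUE
})

#' Construct a MinerConfig
#'
#' @param minSupport Absolute support threshold (count of sequences).
#' @param supportRatio Fractional support threshold; mutually exclusive
#'   with `minSupport`.
#' @param minLen,maxLen Length bounds on mined substrings.
#' @param keepLongestAbove Length above which closure elimination is
#'   skipped; default `Inf` (disabled).
#' @return A [MinerConfig-class] object.
#' @examples
#' minerConfig(minSupport = 2, minLen = 2, maxLen = 8)
#' @export
minerConfig <- function(minSupport = NA_real_, supportRatio = NA_real_,
                        minLen = 1L, maxLen = 30L,
                        keepLongestAbove = Inf) {
  new("MinerConfig", minSupport = as.numeric(minSupport),
      supportRatio = as.numeric(supportRatio),
      minLen = as.integer(minLen), maxLen = as.integer(maxLen),
      keepLongestAbove = as.numeric(keepLongestAbove))
}

#' FrequentSubsequences: mined frequent substrings with support sets
#'
#' @slot residues Character vector of substring strings (lexicographic).
#' @slot supportIds List of character vectors: ids of the sequences each
#'   substring occurs in.
#' @slot occurrenceTotal Integer vector: total leftmost-greedy
#'   non-overlapping occurrence count of each substring over the dataset.
#' @export
setClass("FrequentSubsequences",
  representation(residues = "character", supportIds = "list",
                 occurrenceTotal = "integer"))

setValidity("FrequentSubsequences", function(object) {
  n <- length(object@residues)
  if (length(object@supportIds) != n || length(object@occurrenceTotal) != n)
    return("slots must be parallel vectors")
  if (anyDuplicated(object@residues)) return("duplicate subsequences")
  TRUE
})

#' OccurrenceTable: sparse sequence-by-subsequence occurrence counts
#'
#' Rows are sequence ids, columns are frequent subsequences; cells count
#' leftmost-greedy non-overlapping exact occurrences.
#'
#' @slot counts A sparse `Matrix::dgCMatrix` with dimnames
#'   (sequence ids, subsequence strings).
#' @export
setClass("OccurrenceTable", representation(counts = "ANY"))

setValidity("OccurrenceTable", function(object) {
  m <- object@counts
  if (!methods::is(m, "Matrix") && !is.matrix(m))
    return("counts must be a matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("counts must carry sequence ids and subsequence names")
  if (any(m < 0)) return("occurrence counts must be non-negative")
  TRUE
})

#' SymbolCombinations: closed frequent multisets of subsequences
#'
#' Each combination is a multiset of frequent-subsequence symbols
#' (duplicates allowed), closed with respect to support-set equality.
#'
#' @slot symbols List of named integer vectors; names are subsequence
#'   strings, values their multiplicities.
#' @slot supportIds List of character vectors of supporting sequence ids.
#' @export
setClass("SymbolCombinations",
  representation(symbols = "list", supportIds = "list"))

setValidity("SymbolCombinations", function(object) {
  if (length(object@symbols) != length(object@supportIds))
    return("symbols and supportIds must be parallel")
  TRUE
})

#' FrequentTuples: ordered frequent-sequence tuples
#'
#' An ordered arrangement of subsequences as observed left-to-right in the
#' dataset, with its exact-occurrence frequency.
#'
#' @slot members List of character vectors (ordered tuple members).
#' @slot frequency Integer vector of exact in-order non-overlapping
#'   placement counts over the dataset.
#' @export
setClass("FrequentTuples",
  representation(members = "list", frequency = "integer"))

setValidity("FrequentTuples", function(object) {
  if (length(object@members) != length(object@frequency))
    return("members and frequency must be parallel")
  if (length(object@frequency) && any(object@frequency < 1L))
    return("tuple frequency must be >= 1")
  if (any(vapply(object@members, length, 1L) < 1L))
    return("tuples must have at least one member")
  TRUE
})

#' ScoringScheme: edit-event scores for approximate matching
#'
#' Matching a residue scores 0; substitution, insertion and deletion score
#' strictly negative amounts. An alignment whose total score falls below
#' `minScore` is a matching failure.
#'
#' @slot sub,ins,del Negative penalties per event.
#' @slot minScore Failure threshold (non-positive).
#' @export
setClass("ScoringScheme",
  representation(sub = "numeric", ins = "numeric", del = "numeric",
                 minScore = "numeric"))

setValidity("ScoringScheme", function(object) {
  msg <- character()
  if (object@sub >= 0 || object@ins >= 0 || object@del >= 0)
    msg <- c(msg, "all penalties must be < 0")
  if (object@minScore > 0) msg <- c(msg, "minScore must be <= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a ScoringScheme
#'
#' Defaults are unit penalties with at most two edit events per pattern
#' (`minScore = -2`).
#'
#' @param sub,ins,del Penalties (negative) for substitution, insertion,
#'   deletion.
#' @param minScore Minimum acceptable alignment score.
#' @return A [ScoringScheme-class] object.
#' @examples
#' scoringScheme()                     # unit penalties, two edits allowed
#' scoringScheme(minScore = -1)        # at most one edit
#' @export
scoringScheme <- function(sub = -1, ins = -1, del = -1, minScore = -2) {
  new("ScoringScheme", sub = as.numeric(sub), ins = as.numeric(ins),
      del = as.numeric(del), minScore = as.numeric(minScore))
}

#' MutationProfiles: per-tuple exact frequencies and mutation records
#'
#' For each tuple: the count of exact placements in the profiling dataset
#' and the frequency of each observed canonical mutation record.
#'
#' @slot tuples List of character vectors (ordered tuple members).
#' @slot exactFrequency Integer vector of exact placement counts.
#' @slot entries List of data.frames with columns `record` (canonical
#'   mutation record string) and `frequency`.
#' @export
setClass("MutationProfiles",
  representation(tuples = "list", exactFrequency = "integer",
                 entries = "list"))

setValidity("MutationProfiles", function(object) {
  n <- length(object@tuples)
  if (length(object@exactFrequency) != n || length(object@entries) != n)
    return("slots must be parallel")
  for (e in object@entries) {
    if (!is.data.frame(e) || !all(c("record", "frequency") %in% names(e)))
      return("entries must be data.frames with record and frequency")
    if (nrow(e) && any(e$frequency < 1L)) return("entry frequency must be >= 1")
    if (anyDuplicated(e$record)) return("duplicate mutation records in a profile")
  }
  if (length(object@exactFrequency) && any(object@exactFrequency < 0L))
    return("exactFrequency must be >= 0")
  TRUE
})
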