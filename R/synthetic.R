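.withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.randomResidues <- function(n, residues) {
  if (n <= 0L) return("")
  paste(sample(residues, n, replace = TRUE), collapse = "")
}

## every (possibly overlapping) occurrence start of `pattern` in `text`
.allOccurrenceStarts <- function(pattern, text) {
  m <- gregexpr(paste0("(?=", pattern, ")"), text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

## all distinct substrings of `strings` with length >= guardLen
.guardPatterns <- function(strings, guardLen) {
  unique(unlist(lapply(strings, function(s) {
    n <- nchar(s)
    if (n < guardLen) return(character(0))
    unlist(lapply(guardLen:n, function(L) substring(s, 1:(n - L + 1L), L:n)))
  })))
}

## TRUE when every occurrence of every guarded pattern lies fully inside
## one of the planted spans (starts/ends 1-based inclusive)
.guardHolds <- function(patterns, text, starts, ends) {
  for (p in patterns) {
    occ <- .allOccurrenceStarts(p, text)
    for (o in occ) {
      if (!any(o >= starts & (o + nchar(p) - 1L) <= ends)) return(FALSE)
    }
  }
  TRUE
}

#' Generate a synthetic sequence set with a planted motif tuple
#'
#' Emulates a benchmark dataset: a fraction of sequences carries an exact
#' in-order placement of the planted tuple (members separated by random
#' gaps drawn from `gapRange`, flanked by random background), further
#' fractions carry variant placements obtained by applying a mutation
#' record to the members, and the remainder is pure background. Background
#' and gap segments are rejection-sampled so that scanning a generated
#' sequence with [matchTuple()] under `scoring` recovers exactly the
#' planted placement and record: the returned manifest is therefore an
#' exact oracle for mining and profiling tests. Real datasets carry no
#' such guarantee.
#'
#' All randomness is fixed by `seed`; the global RNG state is left
#' untouched.
#'
#' @param nSequences Number of sequences.
#' @param members Character vector: the ordered planted tuple.
#' @param exactFraction Fraction of sequences with an exact placement.
#' @param variantSpecs List of `list(record = <canonical record string>,
#'   fraction = <fraction>)`; each record is applied to the members via
#'   [applyRecord()]. `exactFraction + sum(fractions)` must be <= 1.
#' @param gapRange Integer range (min, max) of gap lengths between
#'   consecutive members.
#' @param flankRange Integer range of flank lengths on either side.
#' @param alphabet `"DNA"`, `"RNA"` or `"protein"`.
#' @param seqLength If given, every sequence has exactly this length;
#'   planted content longer than it is a configuration error. Gaps are
#'   then clamped to fit and flanks absorb the remainder.
#' @param seed Integer seed fixing all randomness.
#' @param scoring [ScoringScheme-class] used for the oracle guarantee.
#' @param guardLen Background and junction segments are additionally
#'   resampled until no substring of a planted (or variant) member of at
#'   least this length occurs outside a planted span; this keeps
#'   substring-support counts free of junction artifacts so that mined
#'   supports equal the planted counts. Set to `Inf` to disable.
#' @param idPrefix Prefix for sequence ids.
#' @param maxTries Resampling attempts per sequence before giving up.
#' @return List with `sequences` (a [SequenceSet-class]) and `manifest`
#'   (data.frame with columns id, role (exact/variant/background), record,
#'   and memberStarts: 1-based comma-separated planted member start
#'   positions). The planted tuple is attached as attribute `"members"`
#'   of the manifest.
#' @examples
#' g <- generateSyntheticDataset(10, c("GGAGAUG", "UGGAGACU"),
#'                               exactFraction = 0.8, seed = 7)
#' table(g$manifest$role)
#' @export
generateSyntheticDataset <- function(nSequences,
                                     members = c("GGAGAUG", "UGGAGACU"),
                                     exactFraction = 0.5,
                                     variantSpecs = list(),
                                     gapRange = c(5L, 20L),
                                     flankRange = c(5L, 15L),
                                     alphabet = "RNA",
                                     seqLength = NULL,
                                     seed = 1L,
                                     scoring = scoringScheme(),
                                     guardLen = 7L,
                                     idPrefix = "s",
                                     maxTries = 200L) {
  stopifnot(nSequences >= 1L, length(members) >= 1L,
            exactFraction >= 0, exactFraction <= 1)
  residues <- .ALPHABETS[[match.arg(alphabet, names(.ALPHABETS))]]
  fracs <- vapply(variantSpecs, function(v) v$fraction, 0)
  if (exactFraction + sum(fracs) > 1 + 1e-12)
    stop("exactFraction plus variant fractions exceeds 1")
  plantedLen <- sum(nchar(members))
  if (!is.null(seqLength)) {
    minTotal <- plantedLen + (length(members) - 1L) * gapRange[1L]
    if (seqLength < plantedLen)
      stop(sprintf("planted members (%d residues) exceed seqLength %d",
                   plantedLen, seqLength))
    if (seqLength < minTotal)
      stop(sprintf("planted members plus minimum gaps (%d) exceed seqLength %d",
                   minTotal, seqLength))
  }

  ## the planted record must be what the matcher itself would report,
  ## otherwise the manifest could never be an oracle
  variantMembers <- vector("list", length(variantSpecs))
  for (v in seq_along(variantSpecs)) {
    rec <- variantSpecs[[v]]$record
    variantMembers[[v]] <- applyRecord(members, rec)
    canon <- parseRecord(rec)
    for (m in seq_along(members)) {
      r <- approxMatch(members[m], variantMembers[[v]][m], scoring)
      got <- r$events
      if (nrow(got)) got$member <- m - 1L
      want <- canon[canon$member == m - 1L, , drop = FALSE]
      if (is.null(r) || r$start != 0L ||
          r$end != nchar(variantMembers[[v]][m]) ||
          !identical(serializeRecord(got), serializeRecord(want)))
        stop(sprintf(
          "variant record '%s' is not canonical for member %d: the matcher reports '%s'",
          rec, m - 1L, if (is.null(r)) "<failure>" else serializeRecord(got)))
    }
  }

  guardPats <- if (is.finite(guardLen))
    .guardPatterns(unique(c(members, unlist(variantMembers))), guardLen)
  else character(0)

  nExact <- round(exactFraction * nSequences)
  nVar <- vapply(fracs, function(f) round(f * nSequences), 0)
  if (nExact + sum(nVar) > nSequences)
    stop("rounded fractions exceed the number of sequences")
  roles <- c(rep("exact", nExact),
             unlist(lapply(seq_along(nVar), function(v)
               rep(paste0("variant", v), nVar[v]))),
             rep("background", nSequences - nExact - sum(nVar)))

  ids <- paste0(idPrefix, seq_len(nSequences))
  seqsOut <- character(nSequences)
  recordOut <- character(nSequences)
  startsOut <- character(nSequences)

  buildOne <- function(parts) {
    k <- length(parts)          # planted member strings for this role
    gaps <- if (k > 1L)
      sample(seq.int(gapRange[1L], gapRange[2L]), k - 1L, replace = TRUE)
    else integer(0)
    if (is.null(seqLength)) {
      fl <- sample(seq.int(flankRange[1L], flankRange[2L]), 2L,
                   replace = TRUE)
    } else {
      room <- seqLength - sum(nchar(parts))
      while (sum(gaps) > room - 0L && k > 1L)
        gaps[which.max(gaps)] <- gaps[which.max(gaps)] - 1L
      rest <- room - sum(gaps)
      left <- if (rest > 0L) sample.int(rest + 1L, 1L) - 1L else 0L
      fl <- c(left, rest - left)
    }
    segs <- character(0)
    starts <- integer(k)
    pos <- fl[1L]
    segs <- .randomResidues(fl[1L], residues)
    for (m in seq_len(k)) {
      starts[m] <- pos + 1L
      segs <- paste0(segs, parts[m])
      pos <- pos + nchar(parts[m])
      if (m < k) {
        segs <- paste0(segs, .randomResidues(gaps[m], residues))
        pos <- pos + gaps[m]
      }
    }
    segs <- paste0(segs, .randomResidues(fl[2L], residues))
    list(text = segs, starts = starts)
  }

  .withSeed(seed, {
    for (i in seq_len(nSequences)) {
      role <- roles[i]
      wantRecord <- if (role == "exact") "" else if (role == "background")
        NA_character_
      else variantSpecs[[as.integer(sub("variant", "", role))]]$record
      parts <- if (role == "exact") members else if (role == "background")
        character(0)
      else variantMembers[[as.integer(sub("variant", "", role))]]
      done <- FALSE
      for (try in seq_len(maxTries)) {
        if (role == "background") {
          len <- if (!is.null(seqLength)) seqLength else
            sum(nchar(members)) +
              sum(sample(seq.int(gapRange[1L], gapRange[2L]),
                         max(0L, length(members) - 1L), replace = TRUE)) +
              sum(sample(seq.int(flankRange[1L], flankRange[2L]), 2L,
                         replace = TRUE))
          text <- .randomResidues(len, residues)
          scan <- .scanTuplePlacements(members, text, scoring)
          if (length(scan) == 0L &&
              .guardHolds(guardPats, text, integer(0), integer(0))) {
            seqsOut[i] <- text; recordOut[i] <- ""; startsOut[i] <- ""
            done <- TRUE; break
          }
        } else {
          b <- buildOne(parts)
          scan <- .scanTuplePlacements(members, b$text, scoring)
          if (length(scan) == 1L && identical(scan, wantRecord) &&
              .guardHolds(guardPats, b$text, b$starts,
                          b$starts + nchar(parts) - 1L)) {
            seqsOut[i] <- b$text
            recordOut[i] <- wantRecord
            startsOut[i] <- paste(b$starts, collapse = ",")
            done <- TRUE; break
          }
        }
      }
      if (!done)
        stop(sprintf(
          "could not realize a '%s' sequence in %d attempts; background keeps colliding with the planted tuple",
          role, maxTries))
    }
  })

  variantIdx <- rep(NA_integer_, nSequences)
  isVar <- grepl("^variant", roles)
  variantIdx[isVar] <- as.integer(sub("variant", "", roles[isVar]))
  manifest <- data.frame(id = ids, role = sub("[0-9]+$", "", roles),
                         variant = variantIdx,
                         record = recordOut, memberStarts = startsOut,
                         stringsAsFactors = FALSE)
  attr(manifest, "members") <- members
  list(sequences = SequenceSet(ids, seqsOut, alphabet = alphabet),
       manifest = manifest)
}

#' Concatenate SequenceSets
#'
#' @param ... [SequenceSet-class] objects over the same alphabet with
#'   disjoint ids.
#' @return A single combined [SequenceSet-class].
#' @export
bindSequenceSets <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, function(s) is(s, "SequenceSet"), TRUE)))
  alpha <- unique(vapply(sets, function(s) s@alphabet, ""))
  if (length(alpha) != 1L) stop("sets use different alphabets")
  new("SequenceSet",
      ids = unlist(lapply(sets, function(s) s@ids)),
      residues = unlist(lapply(sets, function(s) s@residues)),
      alphabet = alpha,
      labels = unlist(lapply(sets, function(s) s@labels)))
}
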