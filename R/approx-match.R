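## Vectorized preference test: TRUE where candidate b beats a.
## Order: higher score, then fewer events, then move preference
## (match < SUB < DEL < INS), then smaller (leftmost) alignment start.
.beats <- function(aS, aE, aM, aT, bS, bE, bM, bT) {
  (bS > aS) |
    (bS == aS & bE < aE) |
    (bS == aS & bE == aE & bM < aM) |
    (bS == aS & bE == aE & bM == aM & bT < aT)
}

.emptyEvents <- function() {
  data.frame(kind = character(), member = integer(), position = integer(),
             patternBase = character(), observedBase = character(),
             stringsAsFactors = FALSE)
}

#' Approximate matching of a pattern against a text
#'
#' Finds the maximum-score alignment of the whole `pattern` against any
#' substring of `text` under an edit-event automaton: matches score 0,
#' substitutions, insertions and deletions score their (negative)
#' penalties. The alignment with the maximum score is returned; on ties
#' the result with fewer events wins, then substitutions are preferred
#' over deletions over insertions, then the leftmost span. If the best
#' score falls below `minScore` the match fails.
#'
#' Edit events are anchored to 0-based pattern coordinates: a substitution
#' or deletion names the pattern base at its position; an insertion means
#' the observed base is inserted in front of that pattern position.
#'
#' @param pattern Non-empty residue string.
#' @param text Residue string to scan.
#' @param scoring A [ScoringScheme-class].
#' @return `NULL` on matching failure, otherwise a list with elements
#'   `score`, `events` (data.frame with columns kind, member, position,
#'   patternBase, observedBase), and 0-based half-open `start`/`end` of
#'   the matched region in `text`.
#' @examples
#' approxMatch("GGAGAUG", "AAGGAGACGAA", scoringScheme())
#' @export
approxMatch <- function(pattern, text, scoring = scoringScheme()) {
  stopifnot(is(scoring, "ScoringScheme"))
  m <- nchar(pattern)
  n <- nchar(text)
  if (m < 1L) stop("pattern must be non-empty")
  p <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  tch <- if (n) strsplit(text, "", fixed = TRUE)[[1L]] else character(0)
  NEG <- -Inf
  BIGE <- 1e9
  minS <- scoring@minScore

  S <- rep(0, n + 1L); E <- rep(0, n + 1L); St <- as.numeric(0:n)
  moves <- matrix(-1L, nrow = m + 1L, ncol = n + 1L)
  for (i in seq_len(m)) {
    mismatch <- if (n) p[i] != tch else logical(0)
    dS <- c(NEG, S[seq_len(n)] + ifelse(mismatch, scoring@sub, 0))
    dE <- c(BIGE, E[seq_len(n)] + ifelse(mismatch, 1, 0))
    dSt <- c(0, St[seq_len(n)])
    dMv <- c(3L, ifelse(mismatch, 1L, 0L))
    uS <- S + scoring@del; uE <- E + 1; uSt <- St
    pickU <- .beats(dS, dE, dMv, dSt, uS, uE, rep(2L, n + 1L), uSt)
    S2 <- ifelse(pickU, uS, dS)
    E2 <- ifelse(pickU, uE, dE)
    St2 <- ifelse(pickU, uSt, dSt)
    Mv2 <- ifelse(pickU, 2L, dMv)
    ## insertions propagate within the row; iterate to a fixed point,
    ## pruning cells that already fell below the failure threshold
    S2[S2 < minS] <- NEG
    repeat {
      lS <- c(NEG, S2[seq_len(n)] + scoring@ins)
      lS[lS < minS] <- NEG
      lE <- c(BIGE, E2[seq_len(n)] + 1)
      lSt <- c(0, St2[seq_len(n)])
      upd <- .beats(S2, E2, Mv2, St2, lS, lE, rep(3L, n + 1L), lSt)
      if (!any(upd)) break
      S2[upd] <- lS[upd]; E2[upd] <- lE[upd]
      St2[upd] <- lSt[upd]; Mv2[upd] <- 3L
    }
    moves[i + 1L, ] <- Mv2
    S <- S2; E <- E2; St <- St2
  }

  ok <- which(S >= minS)
  if (length(ok) == 0L) return(NULL)
  ord <- ok[order(-S[ok], E[ok], St[ok], ok, method = "radix")]
  jEnd <- ord[1L] - 1L            # 0-based end column
  score <- S[jEnd + 1L]

  ## traceback
  kinds <- character(); poss <- integer()
  pbase <- character(); obase <- character()
  i <- m; j <- jEnd
  while (i > 0L) {
    mv <- moves[i + 1L, j + 1L]
    if (mv == 0L) {
      i <- i - 1L; j <- j - 1L
    } else if (mv == 1L) {
      kinds <- c(kinds, "SUB"); poss <- c(poss, i - 1L)
      pbase <- c(pbase, p[i]); obase <- c(obase, tch[j])
      i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) {
      kinds <- c(kinds, "DEL"); poss <- c(poss, i - 1L)
      pbase <- c(pbase, p[i]); obase <- c(obase, NA_character_)
      i <- i - 1L
    } else {
      kinds <- c(kinds, "INS"); poss <- c(poss, i)
      pbase <- c(pbase, NA_character_); obase <- c(obase, tch[j])
      j <- j - 1L
    }
  }
  events <- if (length(kinds) == 0L) .emptyEvents() else {
    rev_ <- rev(seq_along(kinds))
    data.frame(kind = kinds[rev_], member = 0L, position = poss[rev_],
               patternBase = pbase[rev_], observedBase = obase[rev_],
               stringsAsFactors = FALSE)
  }
  list(score = score, events = events, start = j, end = jEnd)
}

#' Match an ordered tuple against a sequence
#'
#' Members are matched left-to-right in tuple order, without overlap and
#' with unbounded gaps: each member is approximately matched against the
#' text remaining after the previous member's span. The tuple match fails
#' if any member fails its score threshold.
#'
#' @param members Character vector of ordered tuple member strings.
#' @param text Residue string (or a [SequenceSet-class] of length 1).
#' @param scoring A [ScoringScheme-class].
#' @return `NULL` on failure, otherwise a list with `results` (one
#'   [approxMatch()] result per member, spans in text coordinates, event
#'   `member` fields set to the 0-based member index), `events` (the
#'   combined event data.frame), `score` (summed) and the canonical
#'   `record` string (empty on an exact match).
#' @examples
#' matchTuple(c("GGAGAUG", "UGGAGACU"), "GGAGGAGAUGGGGUCCUGGAGACUAAG")
#' @export
matchTuple <- function(members, text, scoring = scoringScheme()) {
  if (is(text, "SequenceSet")) {
    stopifnot(length(text) == 1L)
    text <- text@residues
  }
  stopifnot(length(members) >= 1L)
  offset <- 0L
  results <- vector("list", length(members))
  for (k in seq_along(members)) {
    suffix <- substring(text, offset + 1L)
    r <- approxMatch(members[k], suffix, scoring)
    if (is.null(r)) return(NULL)
    r$start <- r$start + offset
    r$end <- r$end + offset
    if (nrow(r$events)) r$events$member <- k - 1L
    results[[k]] <- r
    offset <- r$end
  }
  events <- do.call(rbind, lapply(results, `[[`, "events"))
  events <- .sortEvents(events)
  list(results = results, events = events,
       score = sum(vapply(results, `[[`, 0, "score")),
       record = serializeRecord(events))
}
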