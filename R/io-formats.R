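#' Read and write the FeatureFile dialect
#'
#' A FeatureFile lists the frequent-sequence tuples, one tuple per line,
#' members tab-separated.
#'
#' @param tuples A [FrequentTuples-class] or list of character vectors.
#' @param path File path.
#' @return `writeFeatureFile` returns `path` invisibly; `readFeatureFile`
#'   returns a list of character member vectors.
#' @export
writeFeatureFile <- function(tuples, path) {
  members <- if (is(tuples, "FrequentTuples")) tuples@members else tuples
  writeLines(vapply(members, paste, "", collapse = "\t"), path)
  invisible(path)
}

#' @rdname writeFeatureFile
#' @export
readFeatureFile <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1L]])
}

#' Read and write the FeatureProfile dialect
#'
#' One block per tuple: a header line
#' `TUPLE <member1> <member2> ... FREQ <exactFrequency>` followed by one
#' line per mutation-record entry, `<record>\t<frequency>`. Writing then
#' reading reproduces the profiles exactly.
#'
#' @param profiles A [MutationProfiles-class].
#' @param path File path.
#' @return `writeProfileFile` returns `path` invisibly; `readProfileFile`
#'   returns a [MutationProfiles-class].
#' @export
writeProfileFile <- function(profiles, path) {
  stopifnot(is(profiles, "MutationProfiles"))
  con <- file(path, open = "w")
  on.exit(close(con))
  for (j in seq_along(profiles@tuples)) {
    writeLines(paste("TUPLE", paste(profiles@tuples[[j]], collapse = " "),
                     "FREQ", profiles@exactFrequency[j]), con)
    e <- profiles@entries[[j]]
    if (nrow(e))
      writeLines(paste0(e$record, "\t", e$frequency), con)
  }
  invisible(path)
}

#' @rdname writeProfileFile
#' @export
readProfileFile <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  heads <- grep("^TUPLE ", lines)
  if (length(heads) == 0L && length(lines) > 0L)
    stop("malformed profile file: no TUPLE header")
  tuples <- list(); exact <- integer(); entries <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (b in seq_along(heads)) {
    toks <- strsplit(lines[heads[b]], " ", fixed = TRUE)[[1L]]
    fq <- which(toks == "FREQ")
    if (length(fq) != 1L || fq < 3L || fq + 1L != length(toks))
      stop("malformed TUPLE header: ", lines[heads[b]])
    tuples[[b]] <- toks[2:(fq - 1L)]
    exact[b] <- as.integer(toks[fq + 1L])
    nb <- bounds[b + 1L] - heads[b] - 1L
    body <- if (nb > 0L) lines[heads[b] + seq_len(nb)] else character(0)
    if (length(body)) {
      parts <- strsplit(body, "\t", fixed = TRUE)
      bad <- vapply(parts, length, 1L) != 2L
      if (any(bad)) stop("malformed profile entry: ", body[bad][1L])
      entries[[b]] <- data.frame(
        record = vapply(parts, `[[`, "", 1L),
        frequency = as.integer(vapply(parts, `[[`, "", 2L)),
        stringsAsFactors = FALSE)
    } else {
      entries[[b]] <- data.frame(record = character(), frequency = integer(),
                                 stringsAsFactors = FALSE)
    }
  }
  new("MutationProfiles", tuples = tuples, exactFrequency = exact,
      entries = entries)
}

.fmtValue <- function(v) {
  s <- vapply(v, function(x)
    format(x, digits = 10L, scientific = FALSE, trim = TRUE), "")
  ifelse(grepl(".", s, fixed = TRUE), s, paste0(s, ".0"))
}

#' Write feature vectors in labeled sparse (libsvm) format
#'
#' One line per sequence: `<label> <index>:<value> ...` with 1-based
#' ascending indices and zero components omitted; an all-zero vector
#' yields the bare label.
#'
#' @param values Numeric matrix, rows = sequences, columns = tuples.
#' @param labels Vector of labels, one per row: +1/-1 (numeric or
#'   character) or "positive"/"negative".
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeLibsvm <- function(values, labels, path) {
  values <- as.matrix(values)
  if (length(labels) != nrow(values))
    stop(sprintf("%d labels for %d feature vectors", length(labels),
                 nrow(values)))
  lab <- as.character(labels)
  lab[lab %in% c("positive", "1", "+1")] <- "+1"
  lab[lab %in% c("negative", "-1")] <- "-1"
  if (any(!lab %in% c("+1", "-1")))
    stop("labels must be +1/-1 (or positive/negative)")
  lines <- vapply(seq_len(nrow(values)), function(r) {
    nz <- which(values[r, ] != 0)
    if (length(nz) == 0L) return(lab[r])
    paste(lab[r], paste0(nz, ":", .fmtValue(values[r, nz]), collapse = " "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a libsvm-format file back into labels and a dense matrix
#'
#' @param path File path.
#' @param nFeatures Number of columns; defaults to the largest index seen.
#' @return List with `labels` (numeric +1/-1) and `values` (dense matrix).
#' @export
readLibsvm <- function(path, nFeatures = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, " ", fixed = TRUE)
  labels <- as.numeric(vapply(toks, `[[`, "", 1L))
  pairs <- lapply(toks, function(t) {
    if (length(t) < 2L) return(matrix(numeric(), ncol = 2L))
    kv <- strsplit(t[-1L], ":", fixed = TRUE)
    cbind(as.numeric(vapply(kv, `[[`, "", 1L)),
          as.numeric(vapply(kv, `[[`, "", 2L)))
  })
  if (is.null(nFeatures)) {
    idx <- unlist(lapply(pairs, function(p) p[, 1L]))
    nFeatures <- if (length(idx)) max(idx) else 0L
  }
  values <- matrix(0, nrow = length(lines), ncol = nFeatures)
  for (r in seq_along(pairs)) {
    p <- pairs[[r]]
    if (nrow(p)) values[r, p[, 1L]] <- p[, 2L]
  }
  list(labels = labels, values = values)
}

#' Write mutation profiles as PSSM blocks
#'
#' One block per tuple member across all profiles. Each block has a header
#' `>TUPLE <j> MEMBER <k> <member string>` followed by one row per
#' alphabet residue: `<residue>\t<count at position 0>\t...`.
#'
#' @param profiles A [MutationProfiles-class].
#' @param path File path.
#' @param normalize,pseudocount,alphabet Passed to [toPSSM()].
#' @return `path`, invisibly.
#' @export
writePSSMFile <- function(profiles, path, normalize = FALSE,
                          pseudocount = 0, alphabet = NULL) {
  stopifnot(is(profiles, "MutationProfiles"))
  con <- file(path, open = "w")
  on.exit(close(con))
  for (j in seq_along(profiles@tuples)) {
    mats <- toPSSM(profiles, index = j, normalize = normalize,
                   pseudocount = pseudocount, alphabet = alphabet)
    for (k in seq_along(mats)) {
      writeLines(sprintf(">TUPLE %d MEMBER %d %s", j, k,
                         attr(mats[[k]], "member")), con)
      m <- mats[[k]]
      for (r in rownames(m))
        writeLines(paste(c(r, .fmtValue(m[r, ])), collapse = "\t"), con)
    }
  }
  invisible(path)
}
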