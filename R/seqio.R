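#' Read a FASTA file into a SequenceSet
#'
#' Records are returned in file order, residues uppercased. T and U are
#' never interconverted: a file read with the RNA alphabet must not
#' contain T, and vice versa. Multi-line record bodies are accepted.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"DNA"`, `"RNA"` or `"protein"`.
#' @param labels Label to assign to every record (`"unlabeled"`,
#'   `"positive"` or `"negative"`).
#' @return A [SequenceSet-class].
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGT"), f)
#' readFastaSet(f, "DNA")
#' @export
readFastaSet <- function(path, alphabet = "DNA", labels = "unlabeled") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path)
  firstContent <- which(nzchar(trimws(lines)))[1]
  if (!is.na(firstContent) && !startsWith(lines[firstContent], ">"))
    stop(sprintf("malformed FASTA in '%s': line %d does not start a '>' record",
                 path, firstContent))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop(sprintf("malformed FASTA in '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  ids <- sub("\\s.*$", "", names(set))
  SequenceSet(ids = ids, residues = as.character(set),
              alphabet = alphabet, labels = labels)
}

#' Write a SequenceSet to FASTA
#'
#' Output is deterministic: record order is preserved and bodies are
#' wrapped at 80 columns, so reading the file back reproduces ids and
#' residues exactly.
#'
#' @param x A [SequenceSet-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeFastaSet <- function(x, path) {
  stopifnot(is(x, "SequenceSet"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write FASTA, no such directory: ", dir)
  set <- Biostrings::BStringSet(setNames(x@residues, x@ids))
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}
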