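# FASTA / FASTQ readers and writers (thin wrappers over Biostrings).

#' Read a FASTA file
#'
#' Sequences are uppercased and RNA U is normalized to T; characters outside
#' the IUPAC DNA alphabet are rejected.
#'
#' @param path FASTA file (gzip-transparent).
#' @param single If `TRUE` (default) the file must contain exactly one
#'   record.
#' @return Tibble with columns `name` and `seq`.
#' @export
read_fasta <- function(path, single = TRUE) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(x) == 0L) abort(sprintf("No FASTA records in '%s'.", path))
  if (single && length(x) > 1L) {
    abort(sprintf("Expected a single FASTA record in '%s', found %d.",
                  path, length(x)))
  }
  seqs <- chartr("U", "T", toupper(as.character(x)))
  iupac <- "ACGTRYSWKMBDHVN"
  bad <- grepl(sprintf("[^%s]", iupac), seqs)
  if (any(bad)) {
    abort(sprintf("Record '%s' contains characters outside the IUPAC DNA alphabet.",
                  names(x)[which(bad)[1]]))
  }
  tibble(name = sub("\\s.*$", "", names(x)), seq = unname(seqs))
}

#' Read a FASTQ file
#'
#' @param path FASTQ file, Phred+33, gzip-transparent.
#' @return Tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      abort(sprintf("Malformed FASTQ '%s': %s", path, conditionMessage(e)))
    }
  )
  quals <- S4Vectors::mcols(x)$qualities
  # the underlying reader does not validate record structure
  bad <- which(Biostrings::width(quals) != Biostrings::width(x))
  if (length(bad)) {
    abort(sprintf("Malformed FASTQ '%s': sequence/quality length mismatch at record %d.",
                  path, bad[1]))
  }
  # short quality lines are nul-padded in memory and only fail at decode
  qual <- tryCatch(unname(as.character(quals)), error = function(e) {
    abort(sprintf("Malformed FASTQ '%s': invalid quality string (%s).",
                  path, conditionMessage(e)))
  })
  if (anyNA(qual) || any(grepl("[^\x21-\x7e]", qual, useBytes = TRUE))) {
    abort(sprintf("Malformed FASTQ '%s': invalid quality string.", path))
  }
  tibble(
    id = sub("\\s.*$", "", names(x)),
    seq = unname(as.character(x)),
    qual = qual
  )
}

#' Write reads to a FASTQ file
#'
#' @param reads Tibble with columns `id`, `seq`, `qual`.
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}
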