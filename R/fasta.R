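#' Read / write FASTA files
#'
#' Thin wrappers around Biostrings that preserve record order and IUPAC
#' letters and wrap sequence lines at 80 columns. Duplicate record
#' identifiers are an error.
#'
#' @param path file path.
#' @param x named character vector of sequences.
#' @return `read_fasta()` returns a named character vector (possibly empty);
#'   `write_fasta()` returns the path invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("read_fasta: no such file: %s", path)
  if (file.size(path) == 0L) return(stats::setNames(character(), character()))
  ss <- Biostrings::readBStringSet(path)
  out <- stats::setNames(toupper(as.character(ss)), names(ss))
  if (anyDuplicated(names(out)))
    stopf("read_fasta: duplicate record identifiers in %s", path)
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  if (length(x) && (is.null(names(x)) || anyDuplicated(names(x))))
    stopf("write_fasta: records must carry unique names")
  Biostrings::writeXStringSet(Biostrings::BStringSet(x), path, width = 80L)
  invisible(path)
}
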