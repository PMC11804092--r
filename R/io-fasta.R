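#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and any character outside `A`, `C`, `G`, `T`, `N`
#' is mapped to `N` (a warning reports how many bases were replaced). Names
#' must be unique and non-empty.
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no records in ", path)
  nm <- names(set)
  nm <- sub("\\s.*$", "", nm)
  if (any(!nzchar(nm))) stop("empty FASTA header in ", path)
  dup <- nm[duplicated(nm)]
  if (length(dup)) stop("duplicate FASTA header: ", dup[[1L]])
  seqs <- toupper(as.character(set))
  n_bad <- sum(vapply(seqs, function(s) {
    nchar(gsub("[ACGTN]", "", s))
  }, integer(1)))
  if (n_bad > 0) {
    warning(n_bad, " non-ACGTN base(s) mapped to N")
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1),
                   USE.NAMES = FALSE)
  }
  names(seqs) <- nm
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param wrap line width (default 60).
#' @export
write_fasta <- function(seqs, path, wrap = 60) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = wrap)
  invisible(path)
}

#' Reverse complement
#'
#' @param seqs character vector of nucleotide sequences.
#' @return Character vector of reverse complements (names kept).
#' @export
revcomp <- function(seqs) cpp_revcomp(seqs)
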