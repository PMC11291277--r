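# Small shared utilities.

#' Round half away from zero
#'
#' Percentages reported in zooarchaeology tables use commercial rounding
#' (half away from zero), not banker's rounding; 386/2005 must print as
#' 19.3, not 19.2.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 0L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Read / write amino-acid FASTA
#'
#' Thin wrappers over Biostrings returning plain named character vectors.
#'
#' @param path FASTA path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' @rdname read_fasta
#' @param sequences named character vector.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}
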