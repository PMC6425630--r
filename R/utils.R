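# Shared helpers.

#' @importFrom data.table := .I data.table as.data.table setkey setorder
#'   setnames set fread fwrite
NULL

# Reverse-complement a character vector of DNA sequences.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' Header descriptions after the first whitespace are dropped from the
#' names.
#'
#' @param path FASTA path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

utils::globalVariables(c(
  "span", "qend", "qstart", "qname", "tname", "tstart",
  "from", "to", "eid", "from_id", "from_strand", "to_id", "to_strand",
  "overlap_len", "u", "v", "w", "o1", "o2", "lenv", "implied", "od",
  "pid", "col", "i.col", "x.col", "acol", "bcol",
  "chrom", "start", "end2", "read_id"
))
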