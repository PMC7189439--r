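# Shared low-level helpers.

#' Reverse complement of DNA character strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, case-insensitive).
#' @return character vector of reverse complements (uppercase).
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Parse a taxid from a sequence header
#'
#' Template headers must carry a taxonomy identifier, either as a
#' `taxid|<int>|` prefix token (NCBI nt style) or as a trailing
#' `taxid=<int>` attribute.
#'
#' @param headers character vector of FASTA headers / template names.
#' @return integer vector; `NA` where no taxid token is present.
#' @export
parse_taxid <- function(headers) {
  out <- rep(NA_integer_, length(headers))
  hit <- regexpr("taxid[|=]([0-9]+)", headers)
  tok <- regmatches(headers, hit)
  out[hit > 0] <- as.integer(sub("taxid[|=]", "", tok))
  out
}

# Read sequences (FASTA or FASTQ, optionally gzipped) as a named uppercase
# character vector. Format is sniffed from the first non-empty character.
read_seqs <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  first <- readLines(con, n = 1L)
  close(con)
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- toupper(as.character(ss))
  names(out) <- names(ss)
  out
}

# Write a FASTA file from a named character vector.
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# Write a FASTQ file (constant quality) from a named character vector;
# gzip-compressed when the path ends in .gz.
write_fastq <- function(seqs, path, qual_char = "I") {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  ids <- names(seqs)
  quals <- vapply(nchar(seqs), function(n) strrep(qual_char, n), "")
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
  invisible(path)
}
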