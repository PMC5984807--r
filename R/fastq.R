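# FASTQ I/O, thin wrappers over Biostrings. Reads come back as plain
# character vectors plus quality strings, which is what the vectorized
# demultiplexing and classification code operates on.

#' Read a FASTQ file
#' @param path FASTQ path (optionally gzipped).
#' @return list with `id`, `seq`, `qual` character vectors.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop_mpsa("missing_file", "file not found: %s", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  list(id = names(x),
       seq = as.character(x),
       qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' Write a FASTQ file
#' @param id,seq,qual read names, sequences, quality strings (equal length).
#' @param path output path; gzipped when it ends in `.gz`.
#' @export
write_fastq <- function(id, seq, qual, path) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              compress = grepl("\\.gz$", path),
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

# Phred+33 quality string -> integer scores.
qual_to_int <- function(q) {
  lapply(q, function(s) as.integer(charToRaw(s)) - 33L)
}
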