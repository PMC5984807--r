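# Barcode generation. Barcodes are 8-nt identifiers placed downstream of the
# last constitutive exon so that skipped transcripts remain attributable to
# their variant. Constraints: pool-wide uniqueness, no restriction motif (or
# its reverse complement) anywhere in the barcode, and pairwise Hamming
# distance >= 2 so a single substitution can never convert one designed
# barcode into another.
#
# Construction: candidates are drawn from the full single-parity code over
# {A,C,G,T}^len (digit sum == 0 mod 4), which has minimum Hamming distance 2
# by construction; motif-containing words are removed, and n survivors are
# sampled with the given seed. This is deterministic per seed and its
# capacity is known exactly, so infeasible requests fail immediately.

barcode_codebook <- function(cfg) {
  len <- cfg$barcode_len
  if (4^len > 4^10) stop_mpsa("config", "barcode length too large to enumerate")
  digits <- as.matrix(do.call(expand.grid, rep(list(0:3), len)))
  keep <- rowSums(digits) %% 4 == 0
  digits <- digits[keep, , drop = FALSE]
  words <- apply(digits, 1, function(d) paste(DNA_BASES[d + 1], collapse = ""))
  motifs <- unique(c(cfg$restriction_motifs, revcomp(cfg$restriction_motifs)))
  for (m in motifs) words <- words[!grepl(m, words, fixed = TRUE)]
  words
}

#' Generate pool barcodes
#'
#' Returns `n` distinct barcodes satisfying the design constraints: no
#' configured restriction motif (or its reverse complement) occurs inside any
#' barcode, and any two barcodes differ at two or more positions. Output is
#' deterministic for a fixed seed.
#'
#' @param n number of barcodes requested.
#' @param cfg a [design_config()].
#' @param seed integer seed.
#' @return character vector of `n` barcodes of length `cfg$barcode_len`.
#' @export
generate_barcodes <- function(n, cfg = design_config(), seed = 1L) {
  if (n < 1) stop_mpsa("config", "n must be >= 1")
  words <- barcode_codebook(cfg)
  if (n > length(words)) {
    stop_mpsa("infeasible",
              "%d barcodes requested but only %d length-%d words satisfy the constraints",
              n, length(words), cfg$barcode_len)
  }
  with_seed(seed, sample(words, n))
}
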