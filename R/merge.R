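#' Merge an overlapping read pair into a single sequence
#'
#' Minimal overlap merger for amplicon mates. Read 2 is supplied as sequenced
#' (reverse strand) and is reverse-complemented internally. All overlap sizes
#' are scanned; the merge uses the overlap maximizing the number of matched
#' bases among overlaps of at least `min_overlap` whose mismatch fraction is
#' at most `max_mismatch_frac`. Disagreeing overlap bases are resolved to the
#' higher-quality base, ties to read 1's base.
#'
#' @param r1_seq,r1_qual read 1 sequence and Phred+33 quality string.
#' @param r2_seq,r2_qual read 2 (as sequenced) and its quality string.
#' @param min_overlap minimum admissible overlap (nt).
#' @param max_mismatch_frac maximum mismatch fraction inside the overlap.
#' @return list with `sequence`, `quality`, `overlap_len`, or `NULL` when no
#'   admissible overlap exists (the pair should be excluded and counted).
#' @export
merge_pair <- function(r1_seq, r1_qual, r2_seq, r2_qual,
                       min_overlap = 10L, max_mismatch_frac = 0.1) {
  n1 <- nchar(r1_seq); n2 <- nchar(r2_seq)
  if (min(n1, n2) < min_overlap) return(NULL)
  x2 <- revcomp(r2_seq)
  q2 <- paste(rev(strsplit(r2_qual, "", fixed = TRUE)[[1]]), collapse = "")
  a1 <- as.integer(charToRaw(r1_seq))
  a2 <- as.integer(charToRaw(x2))
  best_o <- 0L; best_matches <- -1L
  for (o in seq.int(min_overlap, min(n1, n2))) {
    matches <- sum(a1[(n1 - o + 1L):n1] == a2[1:o])
    if ((o - matches) / o <= max_mismatch_frac && matches > best_matches) {
      best_matches <- matches
      best_o <- o
    }
  }
  if (best_o == 0L) return(NULL)
  o <- best_o
  i1 <- (n1 - o + 1L):n1
  b1 <- substring(r1_seq, i1, i1)
  b2 <- substring(x2, 1:o, 1:o)
  p1 <- as.integer(charToRaw(substr(r1_qual, n1 - o + 1L, n1)))
  p2 <- as.integer(charToRaw(substr(q2, 1L, o)))
  cons <- ifelse(b1 == b2 | p1 >= p2, b1, b2)
  consq <- ifelse(p1 >= p2, p1, p2)
  list(
    sequence = paste0(substr(r1_seq, 1L, n1 - o),
                      paste(cons, collapse = ""),
                      substr(x2, o + 1L, n2)),
    quality = paste0(substr(r1_qual, 1L, n1 - o),
                     rawToChar(as.raw(consq)),
                     substr(q2, o + 1L, n2)),
    overlap_len = o
  )
}
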