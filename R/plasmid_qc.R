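# Plasmid pool QC: verify that each barcode is physically linked to its
# designed variant. Merged amplicon reads are binned by barcode (anchored
# next to the MfeI+SpeI cassette), each read is called against the designed
# oligos of its exon, per-barcode fidelity is computed and low-fidelity
# barcodes dropped, and pool-level misassignment and depth skew reported.

plasmid_layout <- function(cfg = design_config()) {
  list(anchor = paste0(cfg$restriction_motifs[["MfeI"]],
                       cfg$restriction_motifs[["SpeI"]]),
       barcode_len = cfg$barcode_len)
}

#' Locate the barcode in a merged plasmid read
#'
#' Returns the 8-mer immediately following the restriction-site anchor when
#' it is present in the pool, otherwise an unassigned code: `no_anchor` when
#' the anchor is absent, `unknown_barcode` when the 8-mer at the anchored
#' position is not a designed barcode (no mismatch rescue).
#'
#' @param m_seq merged read sequence.
#' @param pool pool data.frame.
#' @param layout a [plasmid_layout()].
#' @return list with `barcode` (or NA) and `status` in
#'   `assigned`/`no_anchor`/`unknown_barcode`.
#' @export
assign_barcode <- function(m_seq, pool, layout = plasmid_layout()) {
  hit <- regexpr(layout$anchor, m_seq, fixed = TRUE)
  if (hit == -1L) return(list(barcode = NA_character_, status = "no_anchor"))
  start <- hit + nchar(layout$anchor)
  bc <- substr(m_seq, start, start + layout$barcode_len - 1L)
  if (bc %in% pool$barcode) list(barcode = bc, status = "assigned")
  else list(barcode = NA_character_, status = "unknown_barcode")
}

# Per-exon variant signatures: the set of insert positions at which any
# designed variant of the exon differs from the reference insert, plus each
# candidate's base pattern at those positions. Candidates whose insert length
# differs from the reference (indel variants) are listed separately.
group_signature <- function(pool_group) {
  one <- pool_group[!duplicated(pool_group$variant_id), , drop = FALSE]
  ins <- substr(one$oligo_sequence, one$insert_start,
                one$insert_start + one$up_len + one$exon_len + one$down_len - 1L)
  names(ins) <- one$variant_id
  ref_idx <- which(one$variant_class == "reference")
  if (!length(ref_idx)) ref_idx <- 1L
  ref <- ins[[ref_idx]]
  same_len <- nchar(ins) == nchar(ref)
  U <- integer(0)
  for (s in ins[same_len]) {
    if (identical(s, ref)) next
    U <- union(U, which(strsplit(s, "")[[1]] != strsplit(ref, "")[[1]]))
  }
  U <- sort(U)
  patterns <- vapply(ins[same_len], function(s) {
    paste(substring(s, U, U), collapse = "")
  }, character(1))
  list(inserts = ins, ref = ref, positions = U, patterns = patterns,
       insert_start = one$insert_start[ref_idx],
       variant_ids = names(ins), same_len = same_len)
}

#' Call the variant carried by a merged plasmid read
#'
#' Compares a barcode-assigned read against the designed oligos of its exon.
#' The read is called `expected` when its bases at the exon's designed edit
#' positions match the barcode's own variant exactly; `other_designed` when
#' they match a different designed variant of the same exon (misassignment);
#' `unrecognized` when the best identity against any designed oligo falls
#' below `min_identity` or the edit-site pattern matches no design; and
#' `indel_only` when the read aligns to the expected oligo with indels
#' outside the variant locus. Alignment uses match +1 / mismatch -1 /
#' gap open -2 / extend -1; equal-length read/oligo pairs take a direct
#' column-comparison fast path, which yields the same classification.
#'
#' @param m_seq merged read sequence.
#' @param expected pool row for the barcode's designed oligo.
#' @param pool full pool data.frame (supplies the exon's other designs).
#' @param min_identity identity floor below which a read is `unrecognized`.
#' @return character: `expected`, `other_designed`, `unrecognized`, or
#'   `indel_only`.
#' @export
call_read_variant <- function(m_seq, expected, pool, min_identity = 0.9) {
  grp <- pool[pool$exon_id == expected$exon_id, , drop = FALSE]
  sig <- group_signature(grp)
  call_with_signature(m_seq, expected, sig, min_identity)
}

call_with_signature <- function(m_seq, expected, sig, min_identity) {
  L_oligo <- nchar(expected$oligo_sequence)
  if (nchar(m_seq) == L_oligo) {
    ins_read <- substr(m_seq, expected$insert_start,
                       expected$insert_start + nchar(sig$ref) - 1L)
    d <- vapply(sig$inserts[sig$same_len], function(s) {
      sum(utf8ToInt(ins_read) != utf8ToInt(s))
    }, numeric(1))
    if (min(d) / nchar(sig$ref) > (1 - min_identity)) return("unrecognized")
    pat <- paste(substring(ins_read, sig$positions, sig$positions), collapse = "")
    hit <- names(sig$patterns)[sig$patterns == pat]
    if (!length(hit)) return("unrecognized")
    if (expected$variant_id %in% hit) return("expected")
    return("other_designed")
  }
  call_aligned(m_seq, expected, sig, min_identity)
}

# Vectorized per-exon-group calling. Reads whose length equals the group's
# common oligo length take the direct column-comparison path in one pass;
# anything else (designed indels, length-changing artifacts) falls back to
# the per-read alignment path.
call_group_vectorized <- function(seqs, expected_vids, expected_rows, sig,
                                  min_identity) {
  out <- character(length(seqs))
  ist <- sig$insert_start
  nL <- nchar(sig$ref)
  L <- nchar(expected_rows$oligo_sequence[1])
  fast <- all(sig$same_len) & nchar(seqs) == L
  if (any(fast)) {
    ins <- substr(seqs[fast], ist, ist + nL - 1L)
    m <- matrix(as.integer(charToRaw(paste(ins, collapse = ""))), nrow = nL)
    dmin <- rep(Inf, sum(fast))
    for (s in sig$inserts) {
      dmin <- pmin(dmin, colSums(m != as.integer(charToRaw(s))))
    }
    pat <- if (length(sig$positions)) {
      do.call(paste0, lapply(sig$positions, function(u) substr(ins, u, u)))
    } else rep("", sum(fast))
    hit <- match(pat, sig$patterns)
    vid_hit <- names(sig$patterns)[hit]
    out[fast] <- ifelse(dmin / nL > (1 - min_identity), "unrecognized",
                 ifelse(is.na(hit), "unrecognized",
                 ifelse(vid_hit == expected_vids[fast], "expected",
                        "other_designed")))
  }
  for (i in which(!fast)) {
    out[i] <- call_with_signature(seqs[i], expected_rows[i, ], sig, min_identity)
  }
  out
}

# Slow path: lengths differ (sequencing or designed indels); global alignment.
call_aligned <- function(m_seq, expected, sig, min_identity) {
  best <- NULL; best_score <- -Inf
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (vid in names(sig$inserts)) {
    chim <- sub_insert(expected, sig, vid)
    al <- Biostrings::pairwiseAlignment(m_seq, chim, type = "global",
                                        substitutionMatrix = mat,
                                        gapOpening = 2, gapExtension = 1)
    if (Biostrings::score(al) > best_score) {
      best_score <- Biostrings::score(al); best <- list(vid = vid, al = al)
    }
  }
  al <- best$al
  identity <- Biostrings::nmatch(al) /
    max(nchar(m_seq), nchar(sub_insert(expected, sig, best$vid)))
  if (identity < min_identity) return("unrecognized")
  has_indel <- Biostrings::nindel(al)@insertion[1, "WidthSum"] > 0 ||
    Biostrings::nindel(al)@deletion[1, "WidthSum"] > 0
  if (best$vid == expected$variant_id) {
    if (has_indel) return("indel_only")
    return("expected")
  }
  if (nchar(sig$inserts[[best$vid]]) != nchar(sig$ref) || !has_indel) {
    return("other_designed")
  }
  "indel_only"
}

# Oligo sequence carrying variant `vid`'s insert under `expected`'s scaffold
# and barcode (what a misassigned molecule looks like).
sub_insert <- function(expected, sig, vid) {
  seq <- expected$oligo_sequence
  paste0(substr(seq, 1L, expected$insert_start - 1L),
         sig$inserts[[vid]],
         substr(seq, expected$insert_start + nchar(sig$ref), nchar(seq)))
}

#' Per-barcode fidelity from read-level variant calls
#' @param calls data.frame with columns `barcode`, `call`.
#' @return data.frame: `barcode`, `n_reads`, `n_expected`, `frac_incorrect`.
#' @export
barcode_fidelity <- function(calls) {
  dt <- data.table::as.data.table(calls)
  out <- dt[, .(n_reads = .N, n_expected = sum(call == "expected")),
            by = barcode]
  out[, frac_incorrect := 1 - n_expected / n_reads]
  as.data.frame(out)
}

#' Drop low-fidelity barcodes
#'
#' A barcode is dropped when 15% or more of its reads do not carry the
#' correct variant (`frac_incorrect >= incorrect_threshold`, boundary
#' inclusive).
#'
#' @param fidelities output of [barcode_fidelity()].
#' @param incorrect_threshold inclusive drop threshold on `frac_incorrect`.
#' @return list with `kept` and `dropped` barcode character vectors.
#' @export
filter_barcodes <- function(fidelities, incorrect_threshold = 0.15) {
  drop <- fidelities$frac_incorrect >= incorrect_threshold
  list(kept = fidelities$barcode[!drop], dropped = fidelities$barcode[drop])
}

#' Pool-level misassignment rate
#'
#' Fraction of barcode-assigned reads whose insert carries a different
#' designed variant: `other_designed / (expected + other_designed +
#' indel_only + unrecognized)`.
#'
#' @param calls data.frame with a `call` column.
#' @return fraction in `[0, 1]`.
#' @export
misassignment_rate <- function(calls) {
  n <- nrow(calls)
  if (!n) stop_mpsa("undefined_rate", "no assigned reads")
  sum(calls$call == "other_designed") / n
}

#' Library depth skew ratio
#'
#' Ratio of the 90th to the 10th percentile of per-barcode read depth, with
#' percentiles by linear interpolation between closest ranks
#' (rank = 1 + (n-1) p; `stats::quantile` type 7). Equal depths give 1; a
#' zero 10th percentile gives `Inf` (infinite-skew signal).
#'
#' @param depths numeric vector of per-barcode read counts.
#' @return the skew ratio (>= 1 for non-constant depths).
#' @export
skew_ratio <- function(depths) {
  depths <- depths[!is.na(depths)]
  if (length(depths) < 2) stop_mpsa("undefined_rate", "need >= 2 barcode depths")
  q <- quantile(depths, c(0.1, 0.9), type = 7, names = FALSE)
  if (q[1] == 0) return(Inf)
  q[2] / q[1]
}

#' Plasmid QC pipeline
#'
#' Merges read pairs, bins them by barcode, calls each read's variant,
#' computes per-barcode fidelity, applies the incorrect-read filter, and
#' reports the pool misassignment rate and depth skew.
#'
#' @param r1,r2 FASTQ paths (optionally gzipped).
#' @param pool pool data.frame (or TSV path).
#' @param cfg a [design_config()].
#' @param min_overlap,max_mismatch_frac merge parameters (see [merge_pair()]).
#' @param incorrect_threshold barcode drop threshold (see [filter_barcodes()]).
#' @param min_identity read-call identity floor.
#' @return list of class `mpsa_qc_report`: `fidelity` (per-barcode table with
#'   `kept` flag), `kept`/`dropped` barcode sets, `misassignment_rate` (all
#'   assigned reads), `misassignment_rate_kept` (kept barcodes only),
#'   `skew_ratio`, `depths`, and a `counts` accounting of every read pair.
#' @export
qc_plasmid <- function(r1, r2, pool, cfg = design_config(),
                       min_overlap = 10L, max_mismatch_frac = 0.1,
                       incorrect_threshold = 0.15, min_identity = 0.9) {
  if (is.character(pool)) pool <- read_pool(pool)
  fq1 <- read_fastq(r1); fq2 <- read_fastq(r2)
  if (length(fq1$seq) != length(fq2$seq)) {
    stop_mpsa("malformed_input", "read files differ in record count")
  }
  layout <- plasmid_layout(cfg)
  n <- length(fq1$seq)
  merged <- character(n); ok <- logical(n)
  for (i in seq_len(n)) {
    m <- merge_pair(fq1$seq[i], fq1$qual[i], fq2$seq[i], fq2$qual[i],
                    min_overlap, max_mismatch_frac)
    if (!is.null(m)) { merged[i] <- m$sequence; ok[i] <- TRUE }
  }
  merged <- merged[ok]
  # vectorized anchor search + barcode extraction
  hit <- regexpr(layout$anchor, merged, fixed = TRUE)
  start <- hit + nchar(layout$anchor)
  bc <- substr(merged, start, start + layout$barcode_len - 1L)
  status <- ifelse(hit == -1L, "no_anchor",
                   ifelse(bc %in% pool$barcode, "assigned", "unknown_barcode"))
  assigned <- status == "assigned"
  calls <- data.frame(barcode = bc[assigned], seq = merged[assigned],
                      stringsAsFactors = FALSE)
  bc2var <- setNames(seq_len(nrow(pool)), pool$barcode)
  calls$row <- bc2var[calls$barcode]
  calls$exon_id <- pool$exon_id[calls$row]
  calls$call <- NA_character_
  for (ex in unique(calls$exon_id)) {
    grp <- pool[pool$exon_id == ex, , drop = FALSE]
    sig <- group_signature(grp)
    idx <- which(calls$exon_id == ex)
    calls$call[idx] <- call_group_vectorized(
      calls$seq[idx], pool$variant_id[calls$row[idx]],
      pool[calls$row[idx], , drop = FALSE], sig, min_identity)
  }
  fid <- barcode_fidelity(calls)
  fid$variant_id <- pool$variant_id[bc2var[fid$barcode]]
  flt <- filter_barcodes(fid, incorrect_threshold)
  fid$kept <- fid$barcode %in% flt$kept
  depths <- fid$n_reads
  names(depths) <- fid$barcode
  structure(list(
    fidelity = fid,
    kept = flt$kept,
    dropped = flt$dropped,
    misassignment_rate = misassignment_rate(calls),
    misassignment_rate_kept = if (any(calls$barcode %in% flt$kept))
      misassignment_rate(calls[calls$barcode %in% flt$kept, , drop = FALSE])
    else NA_real_,
    skew_ratio = skew_ratio(depths),
    depths = depths,
    counts = list(n_pairs = n,
                  n_unmerged = n - length(merged),
                  n_no_anchor = sum(status == "no_anchor"),
                  n_unknown_barcode = sum(status == "unknown_barcode"),
                  n_assigned = sum(assigned),
                  calls = table(calls$call))
  ), class = "mpsa_qc_report")
}

#' @export
print.mpsa_qc_report <- function(x, ...) {
  cat(sprintf("plasmid QC: %d pairs, %d assigned; %d/%d barcodes kept\n",
              x$counts$n_pairs, x$counts$n_assigned,
              length(x$kept), length(x$kept) + length(x$dropped)))
  cat(sprintf("  misassignment rate %.4f; skew ratio %.2f\n",
              x$misassignment_rate, x$skew_ratio))
  invisible(x)
}
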