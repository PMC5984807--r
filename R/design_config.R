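#' Design configuration for reporter oligo pools
#'
#' Collects the design rules for the barcoded test-exon reporter library:
#' flank minima, allowed exon lengths, barcode constraints, the common PCR
#' primers, the cloning restriction motifs, and the oligo part order.
#'
#' Defaults follow the published assay design: a minimum of 50 nt of upstream
#' intron (enough to retain most branchpoints), at least 20 nt of downstream
#' intron, test exons of 68-97 nt, at least three unique 8-nt barcodes per
#' variant, and a PstI/XbaI + SpeI/MfeI two-step cloning layout.
#'
#' @param min_up_flank minimum upstream-intron length kept in the insert (nt).
#' @param min_down_flank minimum downstream-intron length (nt).
#' @param min_exon_len,max_exon_len allowed test-exon length range (nt).
#' @param min_barcodes minimum barcodes per variant.
#' @param barcode_len barcode length (nt).
#' @param fwd_primer,rev_primer common amplification primers (5'->3'). The
#'   oligo carries the forward primer verbatim and the reverse complement of
#'   the reverse primer at its 3' end.
#' @param restriction_motifs named character vector of cloning site motifs;
#'   these may not occur anywhere in the oligo outside the designated sites.
#' @param max_oligo_len maximum synthesizable oligo length (nt).
#' @param pyrimidine_tract 20-nt pyrimidine run used by the consensus
#'   splice-site control; must match `[CT]{20}`.
#' @param barcode_min_hamming minimum pairwise Hamming distance among barcodes.
#' @param part_order order of oligo components.
#' @return a list of class `mpsa_design_config`.
#' @export
design_config <- function(min_up_flank = 50L,
                          min_down_flank = 20L,
                          min_exon_len = 68L,
                          max_exon_len = 97L,
                          min_barcodes = 3L,
                          barcode_len = 8L,
                          fwd_primer = "GTAGCGTCTGTCCGTCTGCA",
                          rev_primer = "CTGTAGTAGTAGTTGTCTAG",
                          restriction_motifs = c(PstI = "CTGCAG",
                                                 XbaI = "TCTAGA",
                                                 SpeI = "ACTAGT",
                                                 MfeI = "CAATTG"),
                          max_oligo_len = 260L,
                          pyrimidine_tract = strrep("TC", 10),
                          barcode_min_hamming = 2L,
                          part_order = c("fwd_primer", "site_5",
                                         "upstream_intron", "exon",
                                         "downstream_intron", "site_mid",
                                         "barcode", "site_3",
                                         "rev_primer_rc")) {
  assert_dna(fwd_primer, "fwd_primer")
  assert_dna(rev_primer, "rev_primer")
  assert_dna(restriction_motifs, "restriction motif")
  if (is.null(names(restriction_motifs)) || any(!nzchar(names(restriction_motifs)))) {
    stop_mpsa("config", "restriction motifs must be named")
  }
  if (!grepl("^[CT]+$", pyrimidine_tract) || nchar(pyrimidine_tract) != 20) {
    stop_mpsa("config", "pyrimidine tract must be 20 nt of C/T")
  }
  required <- c("fwd_primer", "site_5", "upstream_intron", "exon",
                "downstream_intron", "site_mid", "barcode", "site_3",
                "rev_primer_rc")
  if (!setequal(part_order, required)) {
    stop_mpsa("config", "part_order must be a permutation of the 9 components")
  }
  structure(list(
    min_up_flank = as.integer(min_up_flank),
    min_down_flank = as.integer(min_down_flank),
    min_exon_len = as.integer(min_exon_len),
    max_exon_len = as.integer(max_exon_len),
    min_barcodes = as.integer(min_barcodes),
    barcode_len = as.integer(barcode_len),
    fwd_primer = fwd_primer,
    rev_primer = rev_primer,
    restriction_motifs = restriction_motifs,
    max_oligo_len = as.integer(max_oligo_len),
    pyrimidine_tract = pyrimidine_tract,
    barcode_min_hamming = as.integer(barcode_min_hamming),
    part_order = part_order
  ), class = "mpsa_design_config")
}
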