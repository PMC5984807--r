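# RNA quantification: demultiplex UMI-tagged amplicon pairs by barcode,
# classify each molecule's splicing outcome against its variant-specific
# minigene reference, collapse PCR duplicates by UMI, and compute percent
# spliced in (PSI) and variant effects (delta PSI).
#
# The reporter transcript is: constitutive exon 1, optionally the test exon,
# constitutive exon 3, then an SpeI cassette carrying the 8-nt barcode and a
# short 3' UTR tail. Read 1 starts inside exon 1 and crosses the splice
# junction; read 2 starts with the 10-nt UMI added at reverse transcription
# and reads back through the UTR tail, barcode, and restriction site into
# exon 3. Because the amplicon has fixed structure, splicing outcomes are
# called by anchored junction comparison rather than full alignment.

#' Reporter backbone sequences
#'
#' The two constitutive exons and the 3' UTR tail of the minigene reporter,
#' used to build variant-specific references and the read-2 layout. The
#' defaults are a beta-globin-style synthetic backbone: read 1 begins at the
#' forward RT-PCR primer (GGCAAGGTGAACGTGGATGAAG) at the start of `exon1`.
#'
#' @param exon1 exon-1 suffix covered by read 1, ending at the 5' splice site.
#' @param exon3 exon-3 sequence following the test exon.
#' @param utr_tail 3' UTR tail downstream of the barcode (RT priming region).
#' @param orf_start 1-based offset of the reporter ATG within `exon1`.
#' @return list of class `mpsa_backbone`.
#' @export
reporter_backbone <- function(
    exon1 = "GGCAAGGTGAACGTGGATGAAGTTGGTGGTGAGGCCCTGG",
    exon3 = "CTCCTGGGCAACGTGCTGGTCTGTGTGCTGGCCCATCACTTTGGCAAAGAATTCACCCCA",
    utr_tail = "GCAACTAGAAGGCACAGTCGAGGCT",
    orf_start = 17L) {
  assert_dna(c(exon1, exon3, utr_tail), "backbone sequence")
  if (substr(exon1, orf_start, orf_start + 2L) != "ATG") {
    stop_mpsa("invalid_orf", "orf_start does not point at an ATG in exon1")
  }
  structure(list(exon1 = exon1, exon3 = exon3, utr_tail = utr_tail,
                 orf_start = as.integer(orf_start)),
            class = "mpsa_backbone")
}

#' Read layout for RNA amplicon pairs
#'
#' Derived from the backbone: expected offsets within read 2 of the 3'-UTR
#' anchor, the reverse-complemented barcode slot, the restriction-site motif
#' adjacent to the barcode, and the exon-3 check sequence. Offsets are
#' 1-based within the read.
#'
#' @param backbone a [reporter_backbone()].
#' @param cfg a [design_config()] (supplies barcode length and the SpeI motif).
#' @param umi_len UMI length (nt).
#' @param read_len read length (nt).
#' @param exon3_check_len length of the exon-3 check anchor (nt).
#' @param max_anchor_mismatch per-anchor mismatch tolerance for read 2.
#' @param anchor_k junction anchor length for read-1 classification (nt).
#' @param max_mismatch per-anchor mismatch tolerance for read 1.
#' @return list of class `mpsa_layout`.
#' @export
rna_layout <- function(backbone = reporter_backbone(), cfg = design_config(),
                       umi_len = 10L, read_len = 150L, exon3_check_len = 15L,
                       max_anchor_mismatch = 1L, anchor_k = 10L,
                       max_mismatch = 1L) {
  site <- cfg$restriction_motifs[["SpeI"]]
  utr_rc <- revcomp(backbone$utr_tail)
  n3 <- nchar(backbone$exon3)
  utr_off <- umi_len + 1L
  bc_off <- utr_off + nchar(utr_rc)
  site_off <- bc_off + cfg$barcode_len
  e3_off <- site_off + nchar(site)
  structure(list(
    umi_len = as.integer(umi_len),
    read_len = as.integer(read_len),
    utr_anchor = utr_rc, utr_offset = utr_off,
    barcode_offset = bc_off, barcode_len = cfg$barcode_len,
    site_anchor = revcomp(site), site_offset = site_off,
    exon3_anchor = revcomp(substr(backbone$exon3, n3 - exon3_check_len + 1L, n3)),
    exon3_offset = e3_off, exon3_check_len = as.integer(exon3_check_len),
    read1_exon1_len = nchar(backbone$exon1),
    max_anchor_mismatch = as.integer(max_anchor_mismatch),
    anchor_k = as.integer(anchor_k),
    max_mismatch = as.integer(max_mismatch)
  ), class = "mpsa_layout")
}

#' Build a variant-specific minigene reference
#'
#' @param pool_row one row of the pool table.
#' @param backbone a [reporter_backbone()].
#' @return list of class `mpsa_reference`: the test exon, exon-1 suffix,
#'   exon-3 prefix, both isoform sequences (inclusion and skipping), and the
#'   junction offsets of each isoform (position of the last base of the
#'   upstream exon).
#' @export
build_reference <- function(pool_row, backbone = reporter_backbone()) {
  if (is.null(backbone$exon1) || is.null(backbone$exon3)) {
    stop_mpsa("config", "backbone must supply exon1 and exon3 sequences")
  }
  test_exon <- substr(pool_row$oligo_sequence, pool_row$exon_start,
                      pool_row$exon_start + pool_row$exon_len - 1L)
  n1 <- nchar(backbone$exon1)
  inc <- paste0(backbone$exon1, test_exon, backbone$exon3)
  skp <- paste0(backbone$exon1, backbone$exon3)
  if (identical(inc, skp)) stop_mpsa("config", "isoform sequences identical")
  structure(list(
    variant_id = pool_row$variant_id,
    exon1_suffix = backbone$exon1,
    test_exon = test_exon,
    exon3_prefix = backbone$exon3,
    inclusion_seq = inc,
    skipping_seq = skp,
    junctions_inclusion = c(n1, n1 + nchar(test_exon)),
    junctions_skipping = n1
  ), class = "mpsa_reference")
}

#' Demultiplex a read 2
#'
#' Extracts the UMI (first `umi_len` bases) and accepts the read only when
#' the exon-3 check sequence and the restriction-site motif adjacent to the
#' barcode both match at their expected offsets within the configured
#' mismatch tolerance, and the (reverse-complemented) 8-mer at the barcode
#' slot is a designed barcode (exact match, no rescue).
#'
#' @param read2 read-2 sequence(s).
#' @param pool pool data.frame.
#' @param layout an [rna_layout()].
#' @return data.frame with columns `barcode`, `umi`, `status` (one of
#'   `ok`, `no_exon3`, `bad_site`, `unknown_barcode`).
#' @export
demux_read2 <- function(read2, pool, layout) {
  n <- length(read2)
  umi <- substr(read2, 1L, layout$umi_len)
  e3 <- substr(read2, layout$exon3_offset,
               layout$exon3_offset + layout$exon3_check_len - 1L)
  st <- substr(read2, layout$site_offset,
               layout$site_offset + nchar(layout$site_anchor) - 1L)
  bc_rc <- substr(read2, layout$barcode_offset,
                  layout$barcode_offset + layout$barcode_len - 1L)
  long_enough <- nchar(read2) >= layout$exon3_offset + layout$exon3_check_len - 1L
  d_e3 <- rep(Inf, n); d_st <- rep(Inf, n)
  d_e3[long_enough] <- hamming_to(e3[long_enough], layout$exon3_anchor)
  d_st[long_enough] <- hamming_to(st[long_enough], layout$site_anchor)
  bc <- rep(NA_character_, n)
  valid_bc <- long_enough & is_dna(bc_rc)
  bc[valid_bc] <- revcomp(bc_rc[valid_bc])
  status <- rep("ok", n)
  status[!(bc %in% pool$barcode)] <- "unknown_barcode"
  status[d_st > layout$max_anchor_mismatch] <- "bad_site"
  status[d_e3 > layout$max_anchor_mismatch] <- "no_exon3"
  bc[status != "ok"] <- NA_character_
  data.frame(barcode = bc, umi = umi, status = status, stringsAsFactors = FALSE)
}

#' Classify the splicing outcome of a read 1
#'
#' Read 1 starts at the beginning of the exon-1 suffix; the `anchor_k` bases
#' after the exon-1 boundary are compared against the start of the test exon
#' (inclusion) and the start of exon 3 (skipping). The unique label within
#' `max_mismatch` mismatches wins; if both or neither match, or the read is
#' too short, the molecule spans an unannotated junction and is discarded
#' from PSI.
#'
#' @param read1 read-1 sequence.
#' @param ref an [build_reference()] object.
#' @param anchor_k anchor length (nt).
#' @param max_mismatch per-anchor mismatch tolerance.
#' @return one of `"INCLUSION"`, `"SKIPPING"`, `"UNANNOTATED"`.
#' @export
classify_outcome <- function(read1, ref, anchor_k = 10L, max_mismatch = 1L) {
  b <- nchar(ref$exon1_suffix)
  if (nchar(read1) < b + anchor_k) return("UNANNOTATED")
  w <- substr(read1, b + 1L, b + anchor_k)
  d_inc <- hamming_to(w, substr(ref$test_exon, 1L, anchor_k))
  d_skp <- hamming_to(w, substr(ref$exon3_prefix, 1L, anchor_k))
  inc_ok <- d_inc <= max_mismatch
  skp_ok <- d_skp <= max_mismatch
  if (inc_ok && !skp_ok) return("INCLUSION")
  if (skp_ok && !inc_ok) return("SKIPPING")
  "UNANNOTATED"
}

#' Collapse PCR duplicates by UMI
#'
#' One molecule per (barcode, UMI) pair; the molecule's outcome is the
#' majority vote over its reads, and exact ties are discarded (counted in the
#' `n_ties` attribute). UMI matching is exact.
#'
#' @param records data.frame with columns `barcode`, `umi`, `outcome`.
#' @return data.frame of molecules (`barcode`, `umi`, `outcome`, `support`)
#'   with attribute `n_ties`.
#' @export
collapse_umis <- function(records) {
  dt <- data.table::as.data.table(records)
  votes <- dt[, .(n = .N), by = .(barcode, umi, outcome)]
  data.table::setorder(votes, barcode, umi, -n)
  per_mol <- votes[, .(outcome = outcome[1],
                       support = sum(n),
                       tie = .N > 1L && n[1] == n[2]),
                   by = .(barcode, umi)]
  n_ties <- sum(per_mol$tie)
  out <- as.data.frame(per_mol[tie == FALSE, .(barcode, umi, outcome, support)])
  attr(out, "n_ties") <- n_ties
  out
}

#' Percent spliced in
#'
#' `100 * inclusion / (inclusion + skipping)`; `NA` (undefined) when both
#' counts are zero.
#'
#' @param n_inclusion,n_skipping molecule counts (vectorized).
#' @return numeric PSI in `[0, 100]`, `NA` where undefined.
#' @export
compute_psi <- function(n_inclusion, n_skipping) {
  tot <- n_inclusion + n_skipping
  ifelse(tot > 0, 100 * n_inclusion / tot, NA_real_)
}

#' Aggregate barcode-level PSI to variant level
#'
#' The variant PSI in a condition is the unweighted mean over its kept
#' barcodes with defined PSI (undefined barcode PSIs are excluded, never
#' imputed). Variants with no surviving barcode are excluded and listed in
#' the `excluded` attribute.
#'
#' @param barcode_psi data.frame with `barcode`, `variant_id`, `condition`,
#'   `n_inclusion`, `n_skipping`, `psi`.
#' @return data.frame with `variant_id`, `condition`, `n_barcodes`,
#'   `n_inclusion`, `n_skipping`, `psi` (barcode-mean) and `psi_pooled`
#'   (from pooled molecule counts).
#' @export
aggregate_psi <- function(barcode_psi) {
  dt <- data.table::as.data.table(barcode_psi)
  out <- dt[, .(n_barcodes = sum(!is.na(psi)),
                n_inclusion = sum(n_inclusion),
                n_skipping = sum(n_skipping),
                psi = mean(psi[!is.na(psi)]),
                psi_pooled = compute_psi(sum(n_inclusion), sum(n_skipping))),
            by = .(variant_id, condition)]
  excluded <- out$variant_id[out$n_barcodes == 0]
  out$psi[out$n_barcodes == 0] <- NA_real_
  res <- as.data.frame(out)
  attr(res, "excluded") <- excluded
  res
}

#' Hierarchical unweighted PSI means across conditions
#'
#' Averages variant PSI first over the replicates of each cell line, then
#' over cell-line means, matching the convention that a variant's summary PSI
#' is the mean of the per-cell-line means.
#'
#' @param variant_psi output of [aggregate_psi()].
#' @param condition_groups named list mapping cell line -> condition names.
#' @return data.frame `variant_id`, `psi`.
#' @export
combine_psi <- function(variant_psi, condition_groups) {
  dt <- data.table::as.data.table(variant_psi)
  per_line <- lapply(names(condition_groups), function(g) {
    sub <- dt[condition %in% condition_groups[[g]] & !is.na(psi),
              .(psi = mean(psi)), by = variant_id]
    sub[, line := g]
    sub
  })
  all <- data.table::rbindlist(per_line)
  as.data.frame(all[, .(psi = mean(psi)), by = variant_id])
}

#' Variant effects on splicing (delta PSI)
#'
#' `delta_psi = psi(variant) - psi(reference of the same exon, same
#' condition)`. Reference rows get 0 by construction; variants whose exon has
#' no reference PSI in that condition are excluded and listed in the
#' `excluded` attribute.
#'
#' @param variant_psi output of [aggregate_psi()] (or any table with
#'   `variant_id`, `condition`, `psi`).
#' @param pool pool data.frame (maps variants to exons and classes).
#' @return data.frame `variant_id`, `exon_id`, `variant_class`, `condition`,
#'   `psi`, `ref_psi`, `delta_psi`.
#' @export
delta_psi <- function(variant_psi, pool) {
  map <- unique(pool[, c("variant_id", "exon_id", "variant_class")])
  dt <- data.table::as.data.table(merge(variant_psi, map, by = "variant_id"))
  refs <- dt[variant_class == "reference" & !is.na(psi),
             .(ref_psi = psi[1]), by = .(exon_id, condition)]
  dt <- merge(dt, refs, by = c("exon_id", "condition"), all.x = TRUE)
  excluded <- unique(dt$variant_id[is.na(dt$ref_psi)])
  dt <- dt[!is.na(ref_psi)]
  dt[, delta_psi := psi - ref_psi]
  dt[variant_class == "reference", delta_psi := 0]
  res <- as.data.frame(dt[, .(variant_id, exon_id, variant_class, condition,
                              psi, ref_psi, delta_psi)])
  attr(res, "excluded") <- excluded
  res
}

#' Pearson and Spearman correlation between two paired PSI tables
#'
#' @param a,b numeric vectors of paired values.
#' @return list with `pearson`, `spearman`, `n`.
#' @export
correlation_report <- function(a, b) {
  keep <- is.finite(a) & is.finite(b)
  if (sum(keep) < 3) stop_mpsa("insufficient_data", "need >= 3 paired finite values")
  list(pearson = cor(a[keep], b[keep], method = "pearson"),
       spearman = cor(a[keep], b[keep], method = "spearman"),
       n = sum(keep))
}

#' Quantify splicing from RNA amplicon FASTQ pairs
#'
#' Full quantification pipeline: demultiplex read 2 by barcode (UMI + anchor
#' checks), classify read 1's splicing outcome against the variant-specific
#' reference, collapse PCR duplicates by UMI, and tabulate barcode- and
#' variant-level PSI. Barcodes dropped by plasmid QC can be excluded via
#' `kept_barcodes`.
#'
#' @param r1,r2 FASTQ paths (optionally gzipped), or character vectors of
#'   sequences when `paths = FALSE`.
#' @param pool pool data.frame or TSV path.
#' @param backbone a [reporter_backbone()].
#' @param condition condition label recorded in the output tables.
#' @param layout an [rna_layout()].
#' @param kept_barcodes optional barcode whitelist from plasmid QC.
#' @param cfg a [design_config()].
#' @param paths treat `r1`/`r2` as file paths (default) or raw sequences.
#' @return list of class `mpsa_quant`: `barcode_psi`, `variant_psi`,
#'   `molecules`, `counts_matrix` (per-variant inclusion/skipping counts,
#'   formatted for external differential-splicing tools), and `log` with
#'   full read accounting.
#' @export
quantify <- function(r1, r2, pool, backbone = reporter_backbone(),
                     condition = "cond1", layout = rna_layout(backbone, cfg),
                     kept_barcodes = NULL, cfg = design_config(),
                     paths = TRUE) {
  if (is.character(pool) && length(pool) == 1) pool <- read_pool(pool)
  if (paths) {
    r1 <- read_fastq(r1)$seq
    r2 <- read_fastq(r2)$seq
  }
  if (length(r1) != length(r2)) {
    stop_mpsa("malformed_input", "read files differ in record count")
  }
  dm <- demux_read2(r2, pool, layout)
  reject <- table(dm$status[dm$status != "ok"])
  keep <- dm$status == "ok"
  if (!is.null(kept_barcodes)) keep <- keep & dm$barcode %in% kept_barcodes
  # per-read anchors from the barcode's variant reference
  bc_map <- pool[match(dm$barcode[keep], pool$barcode), , drop = FALSE]
  test_exon <- substr(bc_map$oligo_sequence, bc_map$exon_start,
                      bc_map$exon_start + bc_map$exon_len - 1L)
  k <- layout$anchor_k
  b <- layout$read1_exon1_len
  r1k <- r1[keep]
  w <- substr(r1k, b + 1L, b + k)
  long <- nchar(r1k) >= b + k
  anchor_inc <- substr(test_exon, 1L, k)
  anchor_skp <- substr(backbone$exon3, 1L, k)
  outcome <- rep("UNANNOTATED", length(r1k))
  if (any(long)) {
    d_inc <- hamming_pair(w[long], anchor_inc[long])
    d_skp <- hamming_to(w[long], anchor_skp)
    oc <- rep("UNANNOTATED", sum(long))
    oc[d_inc <= layout$max_mismatch & d_skp > layout$max_mismatch] <- "INCLUSION"
    oc[d_skp <= layout$max_mismatch & d_inc > layout$max_mismatch] <- "SKIPPING"
    outcome[long] <- oc
  }
  records <- data.frame(barcode = dm$barcode[keep], umi = dm$umi[keep],
                        outcome = outcome, stringsAsFactors = FALSE)
  molecules <- collapse_umis(records)
  dt <- data.table::as.data.table(molecules)
  per_bc <- dt[, .(n_inclusion = sum(outcome == "INCLUSION"),
                   n_skipping = sum(outcome == "SKIPPING"),
                   n_unannotated = sum(outcome == "UNANNOTATED")),
               by = barcode]
  per_bc <- merge(per_bc,
                  data.table::as.data.table(pool[, c("barcode", "variant_id", "exon_id")]),
                  by = "barcode")
  per_bc[, psi := compute_psi(n_inclusion, n_skipping)]
  per_bc[, condition := condition]
  barcode_psi <- as.data.frame(per_bc[, .(barcode, variant_id, exon_id,
                                          condition, n_inclusion, n_skipping,
                                          n_unannotated, psi)])
  variant_psi <- aggregate_psi(barcode_psi)
  cm <- variant_psi[, c("variant_id", "condition", "n_inclusion", "n_skipping")]
  structure(list(
    barcode_psi = barcode_psi,
    variant_psi = variant_psi,
    molecules = molecules,
    counts_matrix = cm,
    log = list(n_pairs = length(r2),
               rejected = as.list(reject),
               n_accepted = sum(keep),
               n_molecules = nrow(molecules),
               n_umi_ties = attr(molecules, "n_ties"),
               outcomes = table(outcome))
  ), class = "mpsa_quant")
}

#' @export
print.mpsa_quant <- function(x, ...) {
  cat(sprintf("splicing quantification: %d pairs -> %d molecules over %d barcodes (%d variants)\n",
              x$log$n_pairs, x$log$n_molecules, nrow(x$barcode_psi),
              nrow(x$variant_psi)))
  invisible(x)
}
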