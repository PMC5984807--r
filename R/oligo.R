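# Oligo assembly and the pool table, the interchange format consumed by the
# QC and quantification modules.

oligo_parts <- function(region, barcode, cfg) {
  motifs <- cfg$restriction_motifs
  c(fwd_primer = cfg$fwd_primer,
    site_5 = unname(motifs[["PstI"]]),
    upstream_intron = region$upstream_intron_seq,
    exon = region$exon_seq,
    downstream_intron = region$downstream_intron_seq,
    site_mid = paste0(motifs[["MfeI"]], motifs[["SpeI"]]),
    barcode = barcode,
    site_3 = unname(motifs[["XbaI"]]),
    rev_primer_rc = revcomp(cfg$rev_primer))
}

#' Assemble a reporter oligo
#'
#' Concatenates the oligo components in the configured order:
#' forward primer, PstI site, upstream intron, test exon, downstream intron,
#' MfeI+SpeI sites, barcode, XbaI site, and the reverse complement of the
#' reverse primer. Validates that no cloning restriction motif occurs outside
#' its designated site part and that the oligo fits the synthesis length
#' limit.
#'
#' @param region an `mpsa_test_region` (after any variant application).
#' @param barcode the assigned barcode.
#' @param variant_id identifier of the variant carried by the region.
#' @param cfg a [design_config()].
#' @param oligo_id identifier for the oligo; default `variant_id_barcode`.
#' @param exon_id identifier of the parent exon.
#' @param variant_class one of `reference`, `SNV`, `insertion`, `deletion`,
#'   `MNV`, `control_mutated`, `control_consensus`.
#' @return a list of class `mpsa_oligo` with fields `oligo_id`, `sequence`,
#'   `parts`, `part_offsets`, `variant_id`, `barcode`, `exon_id`,
#'   `variant_class`.
#' @export
assemble_oligo <- function(region, barcode, variant_id, cfg = design_config(),
                           oligo_id = paste0(variant_id, "_", barcode),
                           exon_id = region$origin$id,
                           variant_class = "SNV") {
  assert_dna(barcode, "barcode")
  if (nchar(barcode) != cfg$barcode_len) {
    stop_mpsa("design_constraint", "barcode %s is not %d nt", barcode, cfg$barcode_len)
  }
  parts <- oligo_parts(region, barcode, cfg)[cfg$part_order]
  seq <- paste(parts, collapse = "")
  if (nchar(seq) > cfg$max_oligo_len) {
    stop_mpsa("length_overflow", "oligo %s is %d nt, exceeding max %d",
              oligo_id, nchar(seq), cfg$max_oligo_len)
  }
  offsets <- cumsum(c(1L, nchar(parts)))[seq_along(parts)]
  names(offsets) <- names(parts)
  site_parts <- intersect(names(parts), c("site_5", "site_mid", "site_3"))
  allowed <- lapply(site_parts, function(p) {
    c(offsets[[p]], offsets[[p]] + nchar(parts[[p]]) - 1L)
  })
  for (i in seq_along(cfg$restriction_motifs)) {
    motif <- cfg$restriction_motifs[[i]]
    hits <- gregexpr(motif, seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    for (h in hits) {
      inside <- any(vapply(allowed, function(iv) {
        h >= iv[1] && (h + nchar(motif) - 1L) <= iv[2]
      }, logical(1)))
      if (!inside) {
        stop_mpsa("stray_motif",
                  "oligo %s contains %s site (%s) at offset %d outside its designated position",
                  oligo_id, names(cfg$restriction_motifs)[i], motif, h)
      }
    }
  }
  structure(list(oligo_id = oligo_id, sequence = seq, parts = parts,
                 part_offsets = offsets, variant_id = variant_id,
                 barcode = barcode, exon_id = exon_id,
                 variant_class = variant_class),
            class = "mpsa_oligo")
}

# Assemble oligos for a list of design entries (variant_id/region/klass/
# exon_id), n_bc barcodes each. A barcode whose junction with the flanking
# site parts happens to recreate a restriction motif is skipped and the next
# spare barcode is used instead, so generate_barcodes' per-word motif filter
# is complemented by a whole-oligo check here.
assemble_pool_oligos <- function(entries, design_cfg, seed, n_bc) {
  total <- length(entries) * n_bc
  spare <- max(50L, ceiling(total * 0.1))
  barcodes <- tryCatch(
    generate_barcodes(total + spare, design_cfg, seed),
    mpsa_infeasible = function(e) generate_barcodes(total, design_cfg, seed))
  ptr <- 0L
  oligos <- vector("list", total)
  k <- 0L
  for (e in entries) {
    for (b in seq_len(n_bc)) {
      k <- k + 1L
      oligo <- NULL
      for (attempt in 1:20) {
        ptr <- ptr + 1L
        if (ptr > length(barcodes)) stop_mpsa("infeasible", "ran out of barcodes")
        oligo <- tryCatch(
          assemble_oligo(e$region, barcodes[ptr], e$variant_id, design_cfg,
                         exon_id = e$exon_id, variant_class = e$klass),
          mpsa_stray_motif = function(err) NULL)
        if (!is.null(oligo)) break
      }
      if (is.null(oligo)) {
        stop_mpsa("stray_motif",
                  "entry %s cannot be assembled under any barcode (region-internal motif?)",
                  e$variant_id)
      }
      oligos[[k]] <- oligo
    }
  }
  oligos
}

#' Build the pool table from assembled oligos
#'
#' The pool table is the package's tabular interchange format: one row per
#' oligo with the component offsets needed by the QC and quantification
#' modules. Optional variant columns (`var_offset`, `var_ref`, `var_alt`,
#' insert-relative, 1-based) carry the designed edit for plasmid variant
#' calling and hexamer analyses.
#'
#' @param oligos a list of `mpsa_oligo` objects.
#' @return data.frame with columns `oligo_id`, `variant_id`, `exon_id`,
#'   `barcode`, `variant_class`, `oligo_sequence`, `up_len`, `exon_len`,
#'   `down_len`, `insert_start`, `exon_start`, `barcode_start`.
#' @export
pool_table <- function(oligos) {
  rows <- lapply(oligos, function(o) {
    data.frame(oligo_id = o$oligo_id, variant_id = o$variant_id,
               exon_id = o$exon_id, barcode = o$barcode,
               variant_class = o$variant_class, oligo_sequence = o$sequence,
               up_len = nchar(o$parts[["upstream_intron"]]),
               exon_len = nchar(o$parts[["exon"]]),
               down_len = nchar(o$parts[["downstream_intron"]]),
               insert_start = unname(o$part_offsets[["upstream_intron"]]),
               exon_start = unname(o$part_offsets[["exon"]]),
               barcode_start = unname(o$part_offsets[["barcode"]]),
               stringsAsFactors = FALSE)
  })
  as.data.frame(data.table::rbindlist(rows))
}

#' Read / write a pool table
#'
#' TSV round-trip of the pool table; `read_pool` validates the required
#' columns, barcode uniqueness and that each sequence contains its barcode at
#' the recorded offset.
#'
#' @param pool pool data.frame.
#' @param path TSV path.
#' @return `read_pool` returns the validated pool data.frame.
#' @export
write_pool <- function(pool, path) write_tsv_file(pool, path)

#' @rdname write_pool
#' @export
read_pool <- function(path) {
  pool <- read_tsv_file(path)
  validate_pool(pool)
}

#' @rdname write_pool
#' @export
validate_pool <- function(pool) {
  need <- c("oligo_id", "variant_id", "exon_id", "barcode", "variant_class",
            "oligo_sequence", "up_len", "exon_len", "down_len",
            "insert_start", "exon_start", "barcode_start")
  miss <- setdiff(need, names(pool))
  if (length(miss)) stop_mpsa("malformed_input", "pool table missing columns: %s",
                              paste(miss, collapse = ", "))
  if (anyDuplicated(pool$barcode)) {
    stop_mpsa("malformed_input", "duplicate barcodes in pool: %s",
              pool$barcode[duplicated(pool$barcode)][1])
  }
  at <- substr(pool$oligo_sequence, pool$barcode_start,
               pool$barcode_start + nchar(pool$barcode) - 1L)
  if (any(at != pool$barcode)) {
    stop_mpsa("malformed_input", "barcode_start does not point at the barcode for oligo %s",
              pool$oligo_id[which(at != pool$barcode)[1]])
  }
  pool
}

#' Write pool oligo sequences as FASTA
#' @param pool pool data.frame.
#' @param path output FASTA path.
#' @export
write_pool_fasta <- function(pool, path) {
  x <- Biostrings::DNAStringSet(pool$oligo_sequence)
  names(x) <- pool$oligo_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Summarize a designed pool against the design rules
#'
#' Reports the design counts used to verify a pool table: distinct variants
#' (both including and excluding reference/control entries, since a pool's
#' printed "variant" count may be read either way), distinct exons, the
#' barcodes-per-variant range, the exon length range, minimum flank lengths,
#' and any rule violations (too few barcodes per variant, exon length outside
#' the allowed window, flanks below minima).
#'
#' @param pool pool data.frame.
#' @param cfg a [design_config()].
#' @return a list of class `mpsa_pool_summary`.
#' @export
summarize_pool <- function(pool, cfg = design_config()) {
  if (!nrow(pool)) stop_mpsa("malformed_input", "empty pool")
  dt <- data.table::as.data.table(pool)
  ctrl_classes <- c("reference", "control_mutated", "control_consensus")
  per_var <- dt[, .(n_barcodes = data.table::uniqueN(barcode),
                    exon_len = exon_len[1], up_len = up_len[1],
                    down_len = down_len[1], variant_class = variant_class[1]),
                by = variant_id]
  viol <- list(
    too_few_barcodes = per_var$variant_id[per_var$n_barcodes < cfg$min_barcodes],
    exon_len_out_of_range = unique(dt$variant_id[
      dt$exon_len < cfg$min_exon_len | dt$exon_len > cfg$max_exon_len]),
    flank_too_short = unique(dt$variant_id[
      dt$up_len < cfg$min_up_flank | dt$down_len < cfg$min_down_flank])
  )
  structure(list(
    n_oligos = nrow(dt),
    n_variants_incl_controls = data.table::uniqueN(dt$variant_id),
    n_variants_excl_controls = data.table::uniqueN(
      dt$variant_id[!dt$variant_class %in% ctrl_classes]),
    n_exons = data.table::uniqueN(dt$exon_id),
    barcodes_per_variant = range(per_var$n_barcodes),
    exon_len_range = range(per_var$exon_len),
    min_up_flank = min(per_var$up_len),
    min_down_flank = min(per_var$down_len),
    violations = viol,
    rules_pass = all(lengths(viol) == 0)
  ), class = "mpsa_pool_summary")
}

#' @export
print.mpsa_pool_summary <- function(x, ...) {
  cat(sprintf("pool: %d oligos, %d variants (%d excluding reference/controls), %d exons\n",
              x$n_oligos, x$n_variants_incl_controls,
              x$n_variants_excl_controls, x$n_exons))
  cat(sprintf("  barcodes/variant %d-%d; exon length %d-%d; min flanks %d/%d nt\n",
              x$barcodes_per_variant[1], x$barcodes_per_variant[2],
              x$exon_len_range[1], x$exon_len_range[2],
              x$min_up_flank, x$min_down_flank))
  cat(sprintf("  design rules %s\n",
              if (x$rules_pass) "satisfied" else
                paste("violated:", paste(names(x$violations)[lengths(x$violations) > 0],
                                         collapse = ", "))))
  invisible(x)
}
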