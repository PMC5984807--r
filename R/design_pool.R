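#' Design a barcoded reporter oligo pool
#'
#' End-to-end library design: for each exon, extract the test region (exon
#' plus intronic flanks), intersect the supplied variants with the region,
#' and emit oligos for the reference sequence, every applicable variant, and
#' the two splice-site controls (mutated and consensus), each under
#' `cfg$min_barcodes` unique barcodes.
#'
#' Exons outside the allowed length window and variants that fail to map,
#' mismatch the genome, or push the oligo over the synthesis limit are
#' skipped and reported in the `skipped` attribute rather than aborting the
#' whole design.
#'
#' @param exons data.frame from [read_exons_bed()] / [read_exons_gtf()].
#' @param genome genome source (see [extract_test_region()]).
#' @param variants data.frame from [read_variants_vcf()]; may be empty.
#' @param cfg a [design_config()].
#' @param seed integer seed for barcode generation.
#' @param controls add mutated/consensus splice-site controls per exon.
#' @return pool data.frame (see [pool_table()]) with extra columns
#'   `var_offset`, `var_ref`, `var_alt` giving the applied edit in
#'   insert-relative 1-based coordinates (NA for reference/controls), and a
#'   `skipped` attribute listing rejected exons/variants with reasons.
#' @export
design_pool <- function(exons, genome, variants = NULL, cfg = design_config(),
                        seed = 1L, controls = TRUE) {
  genome <- as_genome(genome)
  skipped <- list()
  entries <- list()   # one per variant-level entry: region + metadata
  for (i in seq_len(nrow(exons))) {
    exon <- as.list(exons[i, ])
    region <- tryCatch(extract_test_region(exon, genome, cfg), error = function(e) e)
    if (inherits(region, "error")) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        id = exon$id, kind = "exon", reason = conditionMessage(region))
      next
    }
    add <- function(vid, reg, klass, voff = NA_integer_,
                    vref = NA_character_, valt = NA_character_) {
      entries[[length(entries) + 1L]] <<- list(
        variant_id = vid, region = reg, klass = klass, exon_id = exon$id,
        var_offset = voff, var_ref = vref, var_alt = valt)
    }
    add(paste0(exon$id, "_ref"), region, "reference")
    if (controls) {
      mut <- tryCatch(make_mutated_control(region), error = function(e) e)
      if (inherits(mut, "error")) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          id = exon$id, kind = "control_mutated", reason = conditionMessage(mut))
      } else add(paste0(exon$id, "_mut"), mut, "control_mutated")
      add(paste0(exon$id, "_cons"), make_consensus_control(region, cfg),
          "control_consensus")
    }
    if (!is.null(variants) && nrow(variants)) {
      local_vars <- variants[variants$chrom == exon$chrom, , drop = FALSE]
      for (j in seq_len(nrow(local_vars))) {
        v <- as.list(local_vars[j, ])
        off <- region_offset_of(region, v$pos, nchar(v$ref_allele))
        if (is.na(off)) next   # variant does not intersect this region
        reg_v <- tryCatch(apply_variant(region, v, cfg, genome), error = function(e) e)
        if (inherits(reg_v, "error")) {
          skipped[[length(skipped) + 1L]] <- data.frame(
            id = v$id, kind = "variant", reason = conditionMessage(reg_v))
          next
        }
        minus <- identical(exon$strand, "-")
        add(paste0(exon$id, "_", v$id), reg_v, v$klass, off,
            if (minus) revcomp(v$ref_allele) else v$ref_allele,
            if (minus) revcomp(v$alt_allele) else v$alt_allele)
      }
    }
  }
  if (!length(entries)) stop_mpsa("design_constraint", "no designable entries")
  # pre-screen: entries whose region cannot assemble under any barcode
  # (region-internal stray motif, length overflow) are skipped, not fatal
  probe <- strrep("A", cfg$barcode_len)
  screened <- vapply(entries, function(e) {
    tryCatch({
      assemble_oligo(e$region, probe, e$variant_id, cfg,
                     exon_id = e$exon_id, variant_class = e$klass)
      NA_character_
    }, mpsa_error = function(err) conditionMessage(err))
  }, character(1))
  for (i in which(!is.na(screened))) {
    skipped[[length(skipped) + 1L]] <- data.frame(
      id = entries[[i]]$variant_id, kind = "assembly", reason = screened[i])
  }
  entries <- entries[is.na(screened)]
  if (!length(entries)) stop_mpsa("design_constraint", "no designable entries")
  oligos <- assemble_pool_oligos(entries, cfg, derive_seed(seed, "barcodes"),
                                 cfg$min_barcodes)
  pool <- pool_table(oligos)
  meta <- data.table::rbindlist(lapply(entries, function(e) data.frame(
    variant_id = e$variant_id, var_offset = e$var_offset,
    var_ref = e$var_ref, var_alt = e$var_alt, stringsAsFactors = FALSE)))
  pool <- merge(pool, as.data.frame(meta), by = "variant_id", sort = FALSE)
  pool <- pool[order(pool$oligo_id),
               c("oligo_id", "variant_id", "exon_id", "barcode",
                 "variant_class", "oligo_sequence", "up_len", "exon_len",
                 "down_len", "insert_start", "exon_start", "barcode_start",
                 "var_offset", "var_ref", "var_alt")]
  rownames(pool) <- NULL
  attr(pool, "skipped") <- if (length(skipped))
    as.data.frame(data.table::rbindlist(skipped)) else NULL
  pool
}
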