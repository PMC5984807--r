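# Test regions: the candidate exon plus its designed intronic flanks, always
# stored in splicing sense (minus-strand exons are reverse-complemented at
# extraction so everything downstream is strand-free). A region keeps a
# genomic-position map (`gpos`, one entry per base, NA for bases with no
# genomic origin) so variants given in genome coordinates can be placed, and
# indel bookkeeping falls out of the vector representation.

new_test_region <- function(upstream, exon, downstream, origin, gpos) {
  stopifnot(length(gpos) == nchar(upstream) + nchar(exon) + nchar(downstream))
  structure(list(
    upstream_intron_seq = upstream,
    exon_seq = exon,
    downstream_intron_seq = downstream,
    origin = origin,
    gpos = gpos
  ), class = "mpsa_test_region")
}

#' @export
print.mpsa_test_region <- function(x, ...) {
  cat(sprintf("test region for exon %s (%s:%d-%d %s)\n",
              x$origin$id, x$origin$chrom, x$origin$start, x$origin$end,
              x$origin$strand))
  cat(sprintf("  upstream %d nt | exon %d nt | downstream %d nt\n",
              nchar(x$upstream_intron_seq), nchar(x$exon_seq),
              nchar(x$downstream_intron_seq)))
  invisible(x)
}

#' Full insert sequence of a test region
#' @param region a test region.
#' @return character scalar: upstream intron + exon + downstream intron.
#' @export
region_sequence <- function(region) {
  paste0(region$upstream_intron_seq, region$exon_seq,
         region$downstream_intron_seq)
}

region_part_lengths <- function(region) {
  c(upstream = nchar(region$upstream_intron_seq),
    exon = nchar(region$exon_seq),
    downstream = nchar(region$downstream_intron_seq))
}

# Normalize a genome argument: FASTA path, DNAStringSet, or named character.
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome) &&
      is.null(names(genome))) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(genome))
    return(out)
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  stop_mpsa("config", "genome must be a FASTA path, DNAStringSet, or named character vector")
}

genome_slice <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    stop_mpsa("missing_sequence", "chromosome %s not in genome", chrom)
  }
  if (start < 1 || end > nchar(genome[[chrom]])) {
    stop_mpsa("missing_sequence",
              "requested %s:%d-%d outside genome sequence (length %d)",
              chrom, start, end, nchar(genome[[chrom]]))
  }
  substr(genome[[chrom]], start, end)
}

#' Extract a test region (exon plus intronic flanks) from a genome
#'
#' Slices the exon and its flanking intron sequence out of the genome and
#' orients the region in splicing sense: for minus-strand exons the slice is
#' reverse-complemented and the flank roles swap, so the upstream intron is
#' always the one containing the 3' splice site.
#'
#' @param exon a list/row with fields `id`, `chrom`, `start`, `end`, `strand`
#'   (1-based inclusive coordinates, strand "+" or "-").
#' @param genome genome sequence source (FASTA path, `DNAStringSet`, or named
#'   character vector).
#' @param cfg a [design_config()].
#' @param up_flank,down_flank flank lengths to take; default the configured
#'   minima.
#' @return an `mpsa_test_region`.
#' @export
extract_test_region <- function(exon, genome, cfg = design_config(),
                                up_flank = cfg$min_up_flank,
                                down_flank = cfg$min_down_flank) {
  exon_len <- exon$end - exon$start + 1L
  if (exon$end < exon$start) stop_mpsa("coordinates", "exon end < start")
  if (exon_len < cfg$min_exon_len || exon_len > cfg$max_exon_len) {
    stop_mpsa("design_constraint",
              "exon %s length %d outside allowed range [%d, %d]",
              exon$id, exon_len, cfg$min_exon_len, cfg$max_exon_len)
  }
  if (up_flank < cfg$min_up_flank || down_flank < cfg$min_down_flank) {
    stop_mpsa("design_constraint", "flanks below configured minima")
  }
  genome <- as_genome(genome)
  if (identical(exon$strand, "+")) {
    up <- genome_slice(genome, exon$chrom, exon$start - up_flank, exon$start - 1L)
    ex <- genome_slice(genome, exon$chrom, exon$start, exon$end)
    dn <- genome_slice(genome, exon$chrom, exon$end + 1L, exon$end + down_flank)
    gpos <- seq.int(exon$start - up_flank, exon$end + down_flank)
  } else if (identical(exon$strand, "-")) {
    # splicing-sense upstream intron is genomically downstream of the exon
    up <- revcomp(genome_slice(genome, exon$chrom, exon$end + 1L, exon$end + up_flank))
    ex <- revcomp(genome_slice(genome, exon$chrom, exon$start, exon$end))
    dn <- revcomp(genome_slice(genome, exon$chrom, exon$start - down_flank, exon$start - 1L))
    gpos <- seq.int(exon$end + up_flank, exon$start - down_flank)
  } else {
    stop_mpsa("coordinates", "strand must be '+' or '-'")
  }
  new_test_region(up, ex, dn,
                  origin = list(id = exon$id, chrom = exon$chrom,
                                start = exon$start, end = exon$end,
                                strand = exon$strand),
                  gpos = gpos)
}

# Map a genomic interval [pos, pos+len-1] to region offsets; returns the
# 1-based start offset in the region or NA.
region_offset_of <- function(region, pos, len = 1L) {
  strand <- region$origin$strand
  anchor <- if (identical(strand, "-")) pos + len - 1L else pos
  off <- match(anchor, region$gpos)
  if (is.na(off)) return(NA_integer_)
  if (len > 1L) {
    # require the whole ref allele to be contiguous in the map
    want <- if (identical(strand, "-")) seq.int(anchor, pos) else seq.int(pos, pos + len - 1L)
    got <- region$gpos[off:(off + len - 1L)]
    if (off + len - 1L > length(region$gpos) || !identical(as.integer(got), as.integer(want))) {
      return(NA_integer_)
    }
  }
  off
}

# Split a region string edit back into parts given old part lengths and the
# edit location/size. The whole edit is attributed to the part containing its
# first base.
relengthen_parts <- function(lens, off, n_ref, n_alt) {
  bounds <- cumsum(lens)
  part <- which(off <= bounds)[1]
  lens[part] <- lens[part] + (n_alt - n_ref)
  if (lens[part] < 0) stop_mpsa("design_constraint", "edit exceeds part length")
  lens
}

#' Apply a variant to a test region
#'
#' Substitutes the variant's alternate allele into the region at the mapped
#' offset. Alleles are given in genome (plus-strand) orientation and are
#' complemented automatically for minus-strand regions. For deletions that
#' shorten a flank below its configured minimum, the flank is re-padded from
#' the genome when one is supplied.
#'
#' @param region an `mpsa_test_region` (reference).
#' @param v variant with fields `id`, `chrom`, `pos`, `ref_allele`,
#'   `alt_allele` (VCF-style, 1-based).
#' @param cfg a [design_config()].
#' @param genome optional genome source used to re-pad shortened flanks.
#' @return the edited `mpsa_test_region`.
#' @export
apply_variant <- function(region, v, cfg = design_config(), genome = NULL) {
  assert_dna(v$ref_allele, "ref allele")
  assert_dna(v$alt_allele, "alt allele")
  if (!identical(v$chrom, region$origin$chrom)) {
    stop_mpsa("position", "variant %s on %s but region is on %s",
              v$id, v$chrom, region$origin$chrom)
  }
  minus <- identical(region$origin$strand, "-")
  ref <- if (minus) revcomp(v$ref_allele) else v$ref_allele
  alt <- if (minus) revcomp(v$alt_allele) else v$alt_allele
  n_ref <- nchar(ref); n_alt <- nchar(alt)
  off <- region_offset_of(region, v$pos, nchar(v$ref_allele))
  if (is.na(off)) {
    stop_mpsa("position", "variant %s at %s:%d does not map inside the region",
              v$id, v$chrom, v$pos)
  }
  seq <- region_sequence(region)
  found <- substr(seq, off, off + n_ref - 1L)
  if (!identical(found, ref)) {
    stop_mpsa("ref_mismatch",
              "variant %s: region has %s at the mapped offset, expected %s",
              v$id, found, ref)
  }
  new_seq <- paste0(substr(seq, 1L, off - 1L), alt,
                    substr(seq, off + n_ref, nchar(seq)))
  new_gpos <- c(head(region$gpos, off - 1L),
                if (n_alt == n_ref) region$gpos[off:(off + n_ref - 1L)]
                else rep(NA_integer_, n_alt),
                if (off + n_ref <= length(region$gpos))
                  region$gpos[(off + n_ref):length(region$gpos)]
                else integer(0))
  lens <- relengthen_parts(region_part_lengths(region), off, n_ref, n_alt)
  out <- new_test_region(substr(new_seq, 1L, lens[1]),
                         substr(new_seq, lens[1] + 1L, lens[1] + lens[2]),
                         substr(new_seq, lens[1] + lens[2] + 1L, nchar(new_seq)),
                         origin = region$origin, gpos = new_gpos)
  out <- repad_flanks(out, cfg, genome)
  out
}

# Re-extend flanks from the genome if a deletion shortened one below minimum.
repad_flanks <- function(region, cfg, genome) {
  lens <- region_part_lengths(region)
  need_up <- cfg$min_up_flank - lens[["upstream"]]
  need_dn <- cfg$min_down_flank - lens[["downstream"]]
  if (need_up <= 0 && need_dn <= 0) return(region)
  if (is.null(genome)) {
    stop_mpsa("flank",
              "variant shortens a flank below its minimum and no genome was supplied for re-padding")
  }
  genome <- as_genome(genome)
  minus <- identical(region$origin$strand, "-")
  chrom <- region$origin$chrom
  if (need_up > 0) {
    g0 <- region$gpos[!is.na(region$gpos)][1]
    if (minus) {
      pad <- revcomp(genome_slice(genome, chrom, g0 + 1L, g0 + need_up))
      gpad <- seq.int(g0 + need_up, g0 + 1L)
    } else {
      pad <- genome_slice(genome, chrom, g0 - need_up, g0 - 1L)
      gpad <- seq.int(g0 - need_up, g0 - 1L)
    }
    region <- new_test_region(paste0(pad, region$upstream_intron_seq),
                              region$exon_seq, region$downstream_intron_seq,
                              region$origin, c(gpad, region$gpos))
  }
  if (need_dn > 0) {
    gp <- region$gpos[!is.na(region$gpos)]
    gN <- gp[length(gp)]
    if (minus) {
      pad <- revcomp(genome_slice(genome, chrom, gN - need_dn, gN - 1L))
      gpad <- seq.int(gN - 1L, gN - need_dn)
    } else {
      pad <- genome_slice(genome, chrom, gN + 1L, gN + need_dn)
      gpad <- seq.int(gN + 1L, gN + need_dn)
    }
    region <- new_test_region(region$upstream_intron_seq, region$exon_seq,
                              paste0(region$downstream_intron_seq, pad),
                              region$origin, c(region$gpos, gpad))
  }
  region
}

#' Splice-site control transforms
#'
#' `make_mutated_control` kills both splice sites: the 3' splice-site AG at
#' the end of the upstream intron becomes TC and the 5' splice-site GT at the
#' start of the downstream intron becomes CA. `make_consensus_control`
#' strengthens them: the last 22 nt of the upstream intron become a 20-nt
#' pyrimidine tract followed by AG, and the first 6 nt of the downstream
#' intron become the consensus 5' splice site GTAAGT. The exon itself is
#' never touched.
#'
#' @param region a reference `mpsa_test_region` with canonical AG/GT
#'   boundaries (for the mutated control).
#' @param cfg a [design_config()] (supplies the pyrimidine tract).
#' @return the transformed region.
#' @export
make_mutated_control <- function(region) {
  up <- region$upstream_intron_seq
  dn <- region$downstream_intron_seq
  nu <- nchar(up)
  if (substr(up, nu - 1L, nu) != "AG" || substr(dn, 1L, 2L) != "GT") {
    stop_mpsa("noncanonical_boundary",
              "region boundaries are not AG...GT; found %s...%s",
              substr(up, nu - 1L, nu), substr(dn, 1L, 2L))
  }
  new_test_region(paste0(substr(up, 1L, nu - 2L), "TC"),
                  region$exon_seq,
                  paste0("CA", substr(dn, 3L, nchar(dn))),
                  region$origin, region$gpos)
}

#' @rdname make_mutated_control
#' @export
make_consensus_control <- function(region, cfg = design_config()) {
  up <- region$upstream_intron_seq
  dn <- region$downstream_intron_seq
  nu <- nchar(up)
  if (nu < 22L) stop_mpsa("flank", "upstream intron shorter than 22 nt")
  if (nchar(dn) < 6L) stop_mpsa("flank", "downstream intron shorter than 6 nt")
  new_test_region(paste0(substr(up, 1L, nu - 22L), cfg$pyrimidine_tract, "AG"),
                  region$exon_seq,
                  paste0("GTAAGT", substr(dn, 7L, nchar(dn))),
                  region$origin, region$gpos)
}
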