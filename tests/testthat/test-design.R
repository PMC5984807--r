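# Library design: region extraction, variant application, splice-site
# controls, barcodes, oligo assembly, and the pool table.

test_that("test regions are sliced correctly on both strands", {
  g <- genome_with_exon(start = 201L, exon_len = 70L)
  ex <- toy_exon(201L, 70L, "+")
  r <- extract_test_region(ex, g)
  expect_equal(nchar(region_sequence(r)), 140L)
  expect_equal(r$exon_seq, substr(g[["chr1"]], 201, 270))
  expect_equal(r$upstream_intron_seq, substr(g[["chr1"]], 151, 200))
  expect_true(endsWith(r$upstream_intron_seq, "AG"))
  expect_true(startsWith(r$downstream_intron_seq, "GT"))

  # minus strand: the region is the reverse complement of the plus-strand
  # slice, with flank roles swapped
  ex_m <- toy_exon(201L, 70L, "-")
  r_m <- extract_test_region(ex_m, g)
  expect_equal(region_sequence(r_m),
               revcomp(substr(g[["chr1"]], 201 - 20, 270 + 50)))
  expect_equal(r_m$exon_seq, revcomp(r$exon_seq))
  expect_equal(nchar(r_m$upstream_intron_seq), 50L)
})

test_that("exon length limits and genome gaps are enforced", {
  g <- genome_with_exon()
  expect_error(extract_test_region(toy_exon(201L, 67L), g),
               class = "mpsa_design_constraint")
  expect_error(extract_test_region(toy_exon(201L, 98L), g),
               class = "mpsa_design_constraint")
  expect_error(extract_test_region(toy_exon(30L, 70L), g),
               class = "mpsa_missing_sequence")
})

test_that("coordinate map is invertible over the region", {
  g <- genome_with_exon()
  r <- extract_test_region(toy_exon(201L, 70L, "+"), g)
  for (pos in c(151L, 200L, 201L, 270L, 290L)) {
    off <- match(pos, r$gpos)
    expect_equal(r$gpos[off], pos)
    expect_equal(substr(region_sequence(r), off, off),
                 substr(g[["chr1"]], pos, pos))
  }
  r_m <- extract_test_region(toy_exon(201L, 70L, "-"), g)
  off <- match(250L, r_m$gpos)
  expect_equal(substr(region_sequence(r_m), off, off),
               revcomp(substr(g[["chr1"]], 250, 250)))
})

test_that("SNVs are applied in place, with complementation on minus strand", {
  g <- genome_with_exon()
  r <- extract_test_region(toy_exon(201L, 70L, "+"), g)
  ref_b <- substr(g[["chr1"]], 204, 204)
  alt_b <- setdiff(c("A", "C", "G", "T"), ref_b)[1]
  v <- list(id = "v1", chrom = "chr1", pos = 204L,
            ref_allele = ref_b, alt_allele = alt_b)
  r2 <- apply_variant(r, v)
  s1 <- region_sequence(r); s2 <- region_sequence(r2)
  diff <- which(strsplit(s1, "")[[1]] != strsplit(s2, "")[[1]])
  expect_equal(diff, 54L)  # 50 flank + offset 4 within exon
  expect_equal(substr(s2, 54, 54), alt_b)

  r_m <- extract_test_region(toy_exon(201L, 70L, "-"), g)
  r2_m <- apply_variant(r_m, v)
  off <- match(204L, r_m$gpos)
  expect_equal(substr(region_sequence(r2_m), off, off), revcomp(alt_b))
})

test_that("deletions shift the coordinate map and repad short flanks", {
  g <- genome_with_exon()
  ex <- toy_exon(201L, 70L, "+")
  # extract with 2 nt of slack so the deletion leaves the flank at minimum
  r <- extract_test_region(ex, g, up_flank = 52L)
  p <- 160L
  v <- list(id = "del1", chrom = "chr1", pos = p,
            ref_allele = substr(g[["chr1"]], p, p + 2L),
            alt_allele = substr(g[["chr1"]], p, p))
  r2 <- apply_variant(r, v)
  expect_equal(nchar(r2$upstream_intron_seq), 50L)
  expect_equal(nchar(region_sequence(r2)), nchar(region_sequence(r)) - 2L)
  # downstream offsets shifted by -2
  expect_equal(match(201L, r2$gpos), match(201L, r$gpos) - 2L)

  # at minimum flank, a deletion triggers genome re-padding
  r_min <- extract_test_region(ex, g)
  r3 <- apply_variant(r_min, v, genome = g)
  expect_equal(nchar(r3$upstream_intron_seq), 50L)
  expect_true(startsWith(region_sequence(r3), substr(g[["chr1"]], 149, 150)))
  expect_error(apply_variant(r_min, v), class = "mpsa_flank")
})

test_that("allele mismatches and out-of-region positions are rejected", {
  g <- genome_with_exon()
  r <- extract_test_region(toy_exon(201L, 70L, "+"), g)
  ref_b <- substr(g[["chr1"]], 204, 204)
  wrong <- setdiff(c("A", "C", "G", "T"), ref_b)[1]
  expect_error(apply_variant(r, list(id = "x", chrom = "chr1", pos = 204L,
                                     ref_allele = wrong, alt_allele = "A")),
               class = "mpsa_ref_mismatch")
  expect_error(apply_variant(r, list(id = "x", chrom = "chr1", pos = 500L,
                                     ref_allele = "A", alt_allele = "C")),
               class = "mpsa_position")
})

test_that("mutated splice-site control flips AG->TC and GT->CA and nothing else", {
  g <- genome_with_exon()
  r <- extract_test_region(toy_exon(201L, 70L, "+"), g)
  m <- make_mutated_control(r)
  expect_true(endsWith(m$upstream_intron_seq, "TC"))
  expect_true(startsWith(m$downstream_intron_seq, "CA"))
  expect_identical(m$exon_seq, r$exon_seq)
  d <- sum(strsplit(region_sequence(r), "")[[1]] !=
             strsplit(region_sequence(m), "")[[1]])
  expect_equal(d, 4L)  # locality: exactly the four boundary bases
  # applying twice fails: boundaries are no longer AG/GT
  expect_error(make_mutated_control(m), class = "mpsa_noncanonical_boundary")
})

test_that("consensus control installs the pyrimidine tract, AG, and GTAAGT", {
  g <- genome_with_exon()
  r <- extract_test_region(toy_exon(201L, 70L, "+"), g)
  k <- make_consensus_control(r)
  expect_match(k$upstream_intron_seq, "[CT]{20}AG$")
  expect_true(startsWith(k$downstream_intron_seq, "GTAAGT"))
  expect_identical(k$exon_seq, r$exon_seq)
  expect_equal(nchar(region_sequence(k)), nchar(region_sequence(r)))

  cfg_loose <- design_config(min_up_flank = 10L)
  short <- extract_test_region(toy_exon(201L, 70L, "+"), g, cfg_loose,
                               up_flank = 21L)
  expect_error(make_consensus_control(short), class = "mpsa_flank")
})

test_that("barcodes are deterministic, motif-free, and pairwise Hamming >= 2", {
  cfg <- design_config()
  b1 <- generate_barcodes(300, cfg, seed = 9L)
  b2 <- generate_barcodes(300, cfg, seed = 9L)
  expect_identical(b1, b2)
  expect_false(any(duplicated(b1)))
  expect_true(all(nchar(b1) == 8L))
  # brute-force motif scan, both strands
  motifs <- c(cfg$restriction_motifs, revcomp(cfg$restriction_motifs))
  for (m in motifs) expect_false(any(grepl(m, b1, fixed = TRUE)))
  # exhaustive pairwise Hamming distance on the sample
  ints <- vapply(b1, utf8ToInt, integer(8))
  for (i in seq_len(ncol(ints) - 1)) {
    d <- colSums(ints[, (i + 1):ncol(ints), drop = FALSE] != ints[, i])
    expect_true(all(d >= 2))
  }
  expect_error(generate_barcodes(4^8, cfg), class = "mpsa_infeasible")
})

test_that("oligo assembly concatenates parts, keeps primers at the ends, and flags strays", {
  g <- genome_with_exon()
  cfg <- design_config()
  r <- extract_test_region(toy_exon(201L, 70L, "+"), g)
  o <- assemble_oligo(r, "ACGTTGCA", "exA_ref", cfg, variant_class = "reference")
  expect_identical(o$sequence, paste(o$parts, collapse = ""))
  expect_true(startsWith(o$sequence, cfg$fwd_primer))
  expect_true(endsWith(o$sequence, revcomp(cfg$rev_primer)))
  # reassembly from recorded offsets reproduces each part
  for (p in names(o$parts)) {
    expect_equal(substr(o$sequence, o$part_offsets[[p]],
                        o$part_offsets[[p]] + nchar(o$parts[[p]]) - 1L),
                 unname(o$parts[[p]]))
  }
  # a PstI site inside the exon is a stray motif, reported by name
  g2 <- g
  substr(g2[["chr1"]], 220, 225) <- "CTGCAG"
  r_bad <- extract_test_region(toy_exon(201L, 70L, "+"), g2)
  err <- tryCatch(assemble_oligo(r_bad, "ACGTTGCA", "bad", cfg),
                  mpsa_stray_motif = function(e) conditionMessage(e))
  expect_match(err, "PstI")
  # synthesis length limit
  cfg_short <- design_config(max_oligo_len = 100L)
  expect_error(assemble_oligo(r, "ACGTTGCA", "x", cfg_short),
               class = "mpsa_length_overflow")
})

test_that("every pool oligo contains its barcode exactly once", {
  pool <- small_sim()$pool
  hits <- mapply(function(s, b) {
    length(gregexpr(b, s, fixed = TRUE)[[1]])
  }, pool$oligo_sequence, pool$barcode)
  expect_true(all(hits == 1L))
})

test_that("variant oligos differ from their reference by exactly the designed edit", {
  pool <- small_sim()$pool
  one <- pool[!duplicated(pool$variant_id), ]
  insert_of <- function(r) substr(r$oligo_sequence, r$insert_start,
                                  r$insert_start + r$up_len + r$exon_len +
                                    r$down_len - 1L)
  for (ex in unique(one$exon_id)) {
    grp <- one[one$exon_id == ex, ]
    ref <- grp[grp$variant_class == "reference", ]
    ref_ins <- insert_of(ref)
    for (i in which(grp$variant_class == "SNV")) {
      v <- grp[i, ]
      diff <- which(strsplit(insert_of(v), "")[[1]] !=
                      strsplit(ref_ins, "")[[1]])
      expect_equal(diff, v$var_offset)
      expect_equal(substr(insert_of(v), diff, diff), v$var_alt)
      expect_equal(substr(ref_ins, diff, diff), v$var_ref)
    }
    mut <- grp[grp$variant_class == "control_mutated", ]
    d_mut <- sum(strsplit(insert_of(mut), "")[[1]] != strsplit(ref_ins, "")[[1]])
    expect_equal(d_mut, 4L)
    cons <- grp[grp$variant_class == "control_consensus", ]
    diff_cons <- which(strsplit(insert_of(cons), "")[[1]] !=
                         strsplit(ref_ins, "")[[1]])
    # confined to the last 22 nt of the upstream intron + first 6 downstream
    expect_true(all(diff_cons >= ref$up_len - 21L &
                      diff_cons <= ref$up_len + ref$exon_len + 6L))
    expect_true(!any(diff_cons > ref$up_len & diff_cons <= ref$up_len + ref$exon_len))
  }
})

test_that("pool tables round-trip through TSV", {
  pool <- small_sim()$pool
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pool(pool, path)
  back <- read_pool(path)
  expect_equal(back, pool, ignore_attr = TRUE)
})

test_that("pool summary counts variants, exons, and rule violations", {
  pool <- small_sim()$pool   # 3 exons x (ref + mut + cons + 2 SNVs) x 3 bc
  s <- summarize_pool(pool)
  expect_equal(s$n_exons, 3L)
  expect_equal(s$n_variants_incl_controls, 15L)
  expect_equal(s$n_variants_excl_controls, 6L)
  expect_equal(s$barcodes_per_variant, c(3L, 3L))
  expect_true(s$rules_pass)
  # dropping one barcode of a variant violates the minimum
  crippled <- pool[-which(pool$variant_id == pool$variant_id[1])[1], ]
  s2 <- summarize_pool(crippled)
  expect_false(s2$rules_pass)
  expect_equal(s2$violations$too_few_barcodes, pool$variant_id[1])
})

test_that("format readers agree with established parsers", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "exons.bed")
  writeLines(c("chr1\t200\t270\texA\t0\t+", "chr1\t300\t380\texB\t0\t-"), bed)
  mine <- read_exons_bed(bed)
  oracle <- as.data.frame(rtracklayer::import(bed))
  expect_equal(mine$start, oracle$start)
  expect_equal(mine$end, oracle$end)
  expect_equal(mine$strand, as.character(oracle$strand))
  expect_equal(mine$id, oracle$name)

  gtf <- file.path(dir, "exons.gtf")
  writeLines(c(
    "chr1\tsrc\texon\t201\t270\t.\t+\t.\tgene_id \"g1\"; exon_id \"exA\";",
    "chr1\tsrc\tgene\t100\t500\t.\t+\t.\tgene_id \"g1\";",
    "chr1\tsrc\texon\t301\t380\t.\t-\t.\tgene_id \"g1\"; exon_id \"exB\";"), gtf)
  mine_g <- read_exons_gtf(gtf)
  orc <- as.data.frame(rtracklayer::import(gtf))
  orc <- orc[orc$type == "exon", ]
  expect_equal(mine_g$start, orc$start)
  expect_equal(mine_g$end, orc$end)
  expect_equal(mine_g$id, orc$exon_id)

  vcf <- file.path(dir, "vars.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t204\trs1\tA\tT\t.\t.\t.",
               "chr1\t210\t.\tCT\tC\t.\t.\t.",
               "chr1\t220\trs3\tG\tA,C\t.\t.\t."), vcf)
  mine_v <- read_variants_vcf(vcf)
  expect_equal(nrow(mine_v), 4L)  # multi-allelic row split
  orc_v <- VariantAnnotation::readVcf(vcf, genome = "toy")
  expect_equal(unique(mine_v$pos), BiocGenerics::start(orc_v))
  expect_equal(mine_v$ref_allele[1:2],
               as.character(VariantAnnotation::ref(orc_v))[1:2])
  expect_equal(mine_v$klass, c("SNV", "deletion", "SNV", "SNV"))
})

test_that("design_pool builds a valid pool from files and logs skipped entries", {
  dir <- withr::local_tempdir()
  g <- genome_with_exon(start = 201L, exon_len = 70L)
  # second, out-of-range exon must be skipped, not fatal
  exons <- data.frame(id = c("exA", "tiny"), chrom = "chr1",
                      start = c(201L, 400L), end = c(270L, 430L),
                      strand = "+", stringsAsFactors = FALSE)
  ref_b <- substr(g[["chr1"]], 204, 204)
  variants <- data.frame(id = "v1", chrom = "chr1", pos = 204L,
                         ref_allele = ref_b,
                         alt_allele = setdiff(c("A", "C", "G", "T"), ref_b)[1],
                         klass = "SNV", stringsAsFactors = FALSE)
  pool <- design_pool(exons, g, variants, seed = 3L)
  expect_s3_class(validate_pool(pool), "data.frame")
  s <- summarize_pool(pool)
  expect_equal(s$n_exons, 1L)
  expect_equal(s$n_variants_incl_controls, 4L)  # ref + mut + cons + v1
  expect_true(s$rules_pass)
  skipped <- attr(pool, "skipped")
  expect_true("tiny" %in% skipped$id)
})
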