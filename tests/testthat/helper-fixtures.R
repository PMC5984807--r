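# Shared fixtures, all built in code at test time.

# A deterministic toy genome: one chromosome long enough for an exon with
# generous flanks. Sequence is fixed (seeded) so expected slices are stable.
toy_genome <- function(len = 600L, seed = 101L) {
  g <- withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), len,
                                           replace = TRUE), collapse = ""))
  c(chr1 = g)
}

# A genome hand-built around a known exon: canonical AG/GT boundaries at the
# requested coordinates, everything else seeded random.
genome_with_exon <- function(start = 201L, exon_len = 70L, seed = 103L) {
  g <- toy_genome(600L, seed)
  s <- g[["chr1"]]
  substr(s, start - 2L, start - 1L) <- "AG"             # 3'ss before exon
  substr(s, start + exon_len, start + exon_len + 1L) <- "GT"  # 5'ss after
  c(chr1 = s)
}

toy_exon <- function(start = 201L, exon_len = 70L, strand = "+") {
  list(id = "exA", chrom = "chr1", start = start,
       end = start + exon_len - 1L, strand = strand)
}

# Small simulated study used by several files; memoised per session.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_exons = 3L, variants_per_exon = 2L,
                        molecules_per_barcode = 50L,
                        depth_meanlog = log(30))
      cache <<- simulate_pool(cfg, seed = 202L)
    }
    cache
  }
})

# Build a FASTQ pair on disk from sequence vectors (constant Q30).
fastq_pair <- function(r1, r2, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ids <- sprintf("read%04d", seq_along(r1))
  p1 <- file.path(dir, "R1.fastq")
  p2 <- file.path(dir, "R2.fastq")
  write_fastq(ids, r1, strrep("?", nchar(r1)), p1)
  write_fastq(ids, r2, strrep("?", nchar(r2)), p2)
  list(r1 = p1, r2 = p2)
}

# Corrupt a sequence at exactly n random positions (always to a different base).
corrupt <- function(seq, n, seed = 1L) {
  withr::with_seed(seed, {
    ch <- strsplit(seq, "")[[1]]
    pos <- sample(length(ch), n)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  })
}
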