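# Readers for the genomic input formats the design module consumes. Only the
# fields the design needs are parsed: exon coordinates from BED6/GTF and
# CHROM/POS/ID/REF/ALT from VCF. Coordinates are normalized to 1-based
# inclusive (BED's 0-based half-open starts are shifted at read time).

read_maybe_gz <- function(path) {
  if (!file.exists(path)) stop_mpsa("missing_file", "file not found: %s", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con)
}

#' Read exon coordinates
#'
#' `read_exons_bed` parses BED6 (0-based half-open converted to 1-based
#' inclusive); `read_exons_gtf` parses GTF and keeps rows with feature type
#' `exon`, using the `exon_id` attribute (falling back to `gene_id` plus a
#' counter) as the identifier.
#'
#' @param path file path (optionally gzipped).
#' @return data.frame with columns `id`, `chrom`, `start`, `end`, `strand`
#'   (1-based inclusive).
#' @export
read_exons_bed <- function(path) {
  lines <- read_maybe_gz(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 6)) stop_mpsa("malformed_input", "BED6 requires 6 columns")
  data.frame(
    id = vapply(f, `[[`, "", 4L),
    chrom = vapply(f, `[[`, "", 1L),
    start = as.integer(vapply(f, `[[`, "", 2L)) + 1L,
    end = as.integer(vapply(f, `[[`, "", 3L)),
    strand = vapply(f, `[[`, "", 6L),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_exons_bed
#' @export
read_exons_gtf <- function(path) {
  lines <- read_maybe_gz(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 9)) stop_mpsa("malformed_input", "GTF requires 9 columns")
  keep <- vapply(f, `[[`, "", 3L) == "exon"
  f <- f[keep]
  if (!length(f)) stop_mpsa("malformed_input", "no exon features in GTF")
  attr_field <- function(a, key) {
    m <- regmatches(a, regexpr(paste0(key, ' "[^"]*"'), a))
    if (!length(m)) return(NA_character_)
    sub(paste0(key, ' "([^"]*)"'), "\\1", m)
  }
  attrs <- vapply(f, `[[`, "", 9L)
  ids <- vapply(attrs, attr_field, "", key = "exon_id", USE.NAMES = FALSE)
  genes <- vapply(attrs, attr_field, "", key = "gene_id", USE.NAMES = FALSE)
  miss <- is.na(ids)
  ids[miss] <- paste0(genes[miss], "_exon", seq_len(sum(miss)))
  data.frame(
    id = ids,
    chrom = vapply(f, `[[`, "", 1L),
    start = as.integer(vapply(f, `[[`, "", 4L)),
    end = as.integer(vapply(f, `[[`, "", 5L)),
    strand = vapply(f, `[[`, "", 7L),
    stringsAsFactors = FALSE
  )
}

#' Read variants from a VCF
#'
#' Parses VCF v4.x keeping CHROM/POS/ID/REF/ALT only; multi-allelic rows are
#' split into one record per alternate allele. Symbolic/breakend alleles are
#' rejected.
#'
#' @param path VCF path (optionally gzipped).
#' @return data.frame with columns `id`, `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`, `klass` (SNV, insertion, deletion, or MNV).
#' @export
read_variants_vcf <- function(path) {
  lines <- read_maybe_gz(path)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!any(grepl("^#CHROM", lines))) {
    stop_mpsa("malformed_input", "VCF header line (#CHROM) not found in %s", path)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) < 5)) stop_mpsa("malformed_input", "VCF requires >= 5 columns")
  rows <- lapply(seq_along(f), function(i) {
    r <- f[[i]]
    alts <- strsplit(r[5], ",", fixed = TRUE)[[1]]
    id <- if (r[3] == "." || !nzchar(r[3])) sprintf("%s_%s", r[1], r[2]) else r[3]
    data.frame(id = if (length(alts) > 1) paste0(id, "_", seq_along(alts)) else id,
               chrom = r[1], pos = as.integer(r[2]), ref_allele = r[4],
               alt_allele = alts, stringsAsFactors = FALSE)
  })
  out <- as.data.frame(data.table::rbindlist(rows))
  if (any(!is_dna(out$ref_allele) | !is_dna(out$alt_allele))) {
    stop_mpsa("malformed_input", "non-ACGT allele in VCF (symbolic alleles unsupported)")
  }
  nr <- nchar(out$ref_allele); na <- nchar(out$alt_allele)
  out$klass <- ifelse(nr == 1 & na == 1, "SNV",
               ifelse(nr < na, "insertion",
               ifelse(nr > na, "deletion", "MNV")))
  out
}

#' Read a genome FASTA
#' @param path FASTA path.
#' @return named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) as_genome(path)
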