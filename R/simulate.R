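# Ground-truth simulator: synthetic design pools and FASTQ read sets that
# emulate the assay's data-generating structure — per-barcode depth with
# log-normal skew, barcode-variant misassignment, PCR duplicates sharing a
# UMI, substitution sequencing errors, and true per-variant PSI including
# near-zero mutated-splice-site controls and high consensus controls. All
# randomness flows from one master seed via named substreams so stages can be
# re-run independently.

#' Simulation configuration
#'
#' Defaults reflect the assayed study conditions: at least three 8-nt
#' barcodes per variant, 150-nt reads, a 10-nt UMI, a 4.59% barcode-variant
#' misassignment rate, and a log-normal per-barcode depth whose 90th/10th
#' percentile skew is 5.5 (sdlog = log(5.5) / (z90 - z10)). Reference exons
#' draw PSI from Beta(2,2) scaled to 0-100; variant effects are a mixture of
#' a near-null component and a wider effect component; mutated splice-site
#' controls draw from Beta(1,20) (near 0) and consensus controls from
#' Beta(20,1) (near 100).
#'
#' @param n_exons number of simulated exons.
#' @param variants_per_exon test variants (SNVs) per exon, besides the
#'   reference and controls; either a scalar or one count per exon.
#' @param barcodes_per_variant barcodes per variant (>= 3).
#' @param controls include mutated/consensus splice-site controls.
#' @param depth_meanlog,depth_sdlog log-normal per-barcode plasmid depth.
#' @param error_rate per-base substitution error rate.
#' @param misassignment_rate probability a plasmid read carries another
#'   designed variant of the same exon.
#' @param duplication_p geometric PCR duplication parameter; reads per
#'   molecule is `1 + Geometric(p)` (expectation `1 + (1-p)/p`).
#' @param molecules_per_barcode RNA molecules per barcode.
#' @param read_len RNA read length (nt).
#' @param plasmid_read_len plasmid read length (nt).
#' @param ref_psi_shape,mutated_psi_shape,consensus_psi_shape Beta shape
#'   pairs for reference/control true PSI.
#' @param effect_null_prob,effect_null_sd,effect_sd variant-effect mixture:
#'   with probability `effect_null_prob` the effect is N(0, effect_null_sd),
#'   otherwise N(0, effect_sd).
#' @param conditions condition labels to draw truth for.
#' @param effect_mode `shared` (the same variant effect in every condition)
#'   or `independent` (effects drawn per condition).
#' @return list of class `mpsa_sim_config`.
#' @export
sim_config <- function(n_exons = 10L, variants_per_exon = 4L,
                       barcodes_per_variant = 3L, controls = TRUE,
                       depth_meanlog = log(60), depth_sdlog = log(5.5) / 2.5631,
                       error_rate = 0.001, misassignment_rate = 0.0459,
                       duplication_p = 0.5, molecules_per_barcode = 200L,
                       read_len = 150L, plasmid_read_len = 150L,
                       ref_psi_shape = c(2, 2), mutated_psi_shape = c(1, 20),
                       consensus_psi_shape = c(20, 1),
                       effect_null_prob = 0.5, effect_null_sd = 1,
                       effect_sd = 20,
                       conditions = "cond1",
                       effect_mode = c("shared", "independent")) {
  effect_mode <- match.arg(effect_mode)
  stopifnot(n_exons >= 1, all(variants_per_exon >= 0), barcodes_per_variant >= 1,
            length(variants_per_exon) %in% c(1L, n_exons),
            error_rate >= 0, error_rate <= 1,
            misassignment_rate >= 0, misassignment_rate <= 1,
            duplication_p > 0, duplication_p <= 1)
  structure(as.list(environment()), class = "mpsa_sim_config")
}

# Random intronic/exonic sequence with the canonical boundary dinucleotides.
random_region <- function(exon_id, up_len, exon_len, down_len) {
  up <- paste0(random_dna(1, up_len - 2L), "AG")
  ex <- random_dna(1, exon_len)
  dn <- paste0("GT", random_dna(1, down_len - 2L))
  new_test_region(up, ex, dn,
                  origin = list(id = exon_id, chrom = exon_id, start = 1L,
                                end = exon_len, strand = "+"),
                  gpos = seq_len(up_len + exon_len + down_len))
}

#' Simulate a designed pool with known true PSI
#'
#' Generates random exons with canonical AG/GT boundaries, a reference, SNV
#' variants, and both splice-site controls per exon, assembles barcoded
#' oligos through the design module, and draws a true PSI per variant and
#' condition. Deterministic for a fixed seed.
#'
#' @param cfg a [sim_config()].
#' @param seed master seed.
#' @param design_cfg a [design_config()].
#' @return list of class `mpsa_sim`: `pool` (pool table), `truth` (long
#'   data.frame `variant_id`, `exon_id`, `variant_class`, `condition`,
#'   `true_psi`), `cfg`, `design_cfg`, `seed`.
#' @export
simulate_pool <- function(cfg = sim_config(), seed = 1L,
                          design_cfg = design_config()) {
  vpe <- rep_len(cfg$variants_per_exon, cfg$n_exons)
  entries <- with_seed(derive_seed(seed, "pool"), {
    out <- list()
    for (e in seq_len(cfg$n_exons)) {
      exon_id <- sprintf("ex%03d", e)
      # rejection-sample a region whose reference oligo assembles cleanly
      region <- NULL
      for (try in 1:50) {
        exon_len <- sample(design_cfg$min_exon_len:design_cfg$max_exon_len, 1)
        cand <- random_region(exon_id, design_cfg$min_up_flank, exon_len,
                              design_cfg$min_down_flank)
        # the reference and both control transforms must all assemble cleanly
        probe <- strrep("A", design_cfg$barcode_len)
        ok <- tryCatch({
          assemble_oligo(cand, probe, "probe", design_cfg)
          assemble_oligo(make_mutated_control(cand), probe, "probe", design_cfg)
          assemble_oligo(make_consensus_control(cand, design_cfg), probe,
                         "probe", design_cfg)
          TRUE
        }, mpsa_stray_motif = function(e) FALSE)
        if (ok) { region <- cand; break }
      }
      if (is.null(region)) stop_mpsa("infeasible", "could not draw a clean region")
      add <- function(vid, reg, klass, voff = NA_integer_,
                      vref = NA_character_, valt = NA_character_) {
        out[[length(out) + 1L]] <<- list(variant_id = vid, region = reg,
                                         klass = klass, exon_id = exon_id,
                                         var_offset = voff, var_ref = vref,
                                         var_alt = valt)
      }
      add(paste0(exon_id, "_ref"), region, "reference")
      if (cfg$controls) {
        add(paste0(exon_id, "_mut"), make_mutated_control(region),
            "control_mutated")
        add(paste0(exon_id, "_cons"), make_consensus_control(region, design_cfg),
            "control_consensus")
      }
      L <- sum(region_part_lengths(region))
      v <- 0L
      tries <- 0L
      while (v < vpe[e] && tries < 200L) {
        tries <- tries + 1L
        pos <- sample.int(L, 1)
        seqs <- region_sequence(region)
        ref_b <- substr(seqs, pos, pos)
        alt_b <- sample(setdiff(DNA_BASES, ref_b), 1)
        reg_v <- tryCatch(
          apply_variant(region, list(id = "v", chrom = exon_id, pos = pos,
                                     ref_allele = ref_b, alt_allele = alt_b),
                        design_cfg),
          error = function(e) NULL)
        if (is.null(reg_v)) next
        ok <- tryCatch({
          assemble_oligo(reg_v, strrep("A", design_cfg$barcode_len), "probe",
                         design_cfg)
          TRUE
        }, mpsa_stray_motif = function(e) FALSE)
        if (!ok) next
        v <- v + 1L
        add(sprintf("%s_v%02d", exon_id, v), reg_v, "SNV", pos, ref_b, alt_b)
      }
    }
    out
  })
  oligos <- assemble_pool_oligos(entries, design_cfg,
                                 derive_seed(seed, "barcodes"),
                                 cfg$barcodes_per_variant)
  pool <- pool_table(oligos)
  meta <- as.data.frame(data.table::rbindlist(lapply(entries, function(e) {
    data.frame(variant_id = e$variant_id, var_offset = e$var_offset,
               var_ref = e$var_ref, var_alt = e$var_alt,
               stringsAsFactors = FALSE)
  })))
  pool <- merge(pool, meta, by = "variant_id", sort = FALSE)
  pool <- pool[, c("oligo_id", "variant_id", "exon_id", "barcode",
                   "variant_class", "oligo_sequence", "up_len", "exon_len",
                   "down_len", "insert_start", "exon_start", "barcode_start",
                   "var_offset", "var_ref", "var_alt")]
  truth <- with_seed(derive_seed(seed, "truth"), {
    one <- unique(pool[, c("variant_id", "exon_id", "variant_class")])
    rows <- list()
    for (ex in unique(one$exon_id)) {
      sub <- one[one$exon_id == ex, , drop = FALSE]
      ref_psi <- setNames(100 * rbeta(length(cfg$conditions),
                                      cfg$ref_psi_shape[1], cfg$ref_psi_shape[2]),
                          cfg$conditions)
      shared_eff <- NULL
      for (i in seq_len(nrow(sub))) {
        klass <- sub$variant_class[i]
        eff_shared <- if (klass == "SNV") {
          if (runif(1) < cfg$effect_null_prob) rnorm(1, 0, cfg$effect_null_sd)
          else rnorm(1, 0, cfg$effect_sd)
        } else NA_real_
        for (cond in cfg$conditions) {
          psi <- switch(klass,
            reference = ref_psi[[cond]],
            control_mutated = 100 * rbeta(1, cfg$mutated_psi_shape[1],
                                          cfg$mutated_psi_shape[2]),
            control_consensus = 100 * rbeta(1, cfg$consensus_psi_shape[1],
                                            cfg$consensus_psi_shape[2]),
            { # SNV
              eff <- if (cfg$effect_mode == "shared") eff_shared else {
                if (runif(1) < cfg$effect_null_prob) rnorm(1, 0, cfg$effect_null_sd)
                else rnorm(1, 0, cfg$effect_sd)
              }
              clamp(ref_psi[[cond]] + eff, 0, 100)
            })
          rows[[length(rows) + 1L]] <- data.frame(
            variant_id = sub$variant_id[i], exon_id = ex,
            variant_class = klass, condition = cond, true_psi = psi,
            stringsAsFactors = FALSE)
        }
      }
    }
    as.data.frame(data.table::rbindlist(rows))
  })
  structure(list(pool = pool, truth = truth, cfg = cfg,
                 design_cfg = design_cfg, seed = seed),
            class = "mpsa_sim")
}

#' Simulate plasmid amplicon reads
#'
#' Per-barcode depths are log-normal (rounded, minimum 1); with probability
#' `misassignment_rate` a read's insert is swapped to another designed
#' variant of the same exon (keeping the barcode); substitution errors are
#' i.i.d. per base; mates overlap so error-free pairs always merge.
#'
#' @param sim an [simulate_pool()] result.
#' @param seed master seed (substream `plasmid`).
#' @param dir output directory for the FASTQ pair.
#' @return list: `r1`, `r2` (paths), `depths` (true per-barcode depth),
#'   `n_misassigned` (planted count), `n_reads`.
#' @export
simulate_plasmid_fastq <- function(sim, seed = sim$seed, dir = tempdir()) {
  cfg <- sim$cfg
  pool <- sim$pool
  out <- with_seed(derive_seed(seed, "plasmid"), {
    nb <- nrow(pool)
    depths <- pmax(1L, as.integer(round(rlnorm(nb, cfg$depth_meanlog,
                                               cfg$depth_sdlog))))
    bc_idx <- rep(seq_len(nb), depths)
    n <- length(bc_idx)
    mis <- runif(n) < cfg$misassignment_rate
    seqs <- pool$oligo_sequence[bc_idx]
    # swap inserts for misassigned reads: donor variant from the same exon
    for (i in which(mis)) {
      row <- pool[bc_idx[i], ]
      donors <- which(pool$exon_id == row$exon_id &
                        pool$variant_id != row$variant_id &
                        !duplicated(pool$variant_id))
      if (!length(donors)) { mis[i] <- FALSE; next }
      d <- pool[sample(donors, 1), ]
      ins <- substr(d$oligo_sequence, d$insert_start,
                    d$insert_start + d$up_len + d$exon_len + d$down_len - 1L)
      seqs[i] <- paste0(substr(row$oligo_sequence, 1L, row$insert_start - 1L),
                        ins,
                        substr(row$oligo_sequence,
                               row$insert_start + row$up_len + row$exon_len +
                                 row$down_len,
                               nchar(row$oligo_sequence)))
    }
    L <- nchar(seqs)
    rl <- pmin(cfg$plasmid_read_len, L)
    r1 <- substr(seqs, 1L, rl)
    r2 <- revcomp(substr(seqs, L - rl + 1L, L))
    r1 <- mutate_seqs(r1, cfg$error_rate)
    r2 <- mutate_seqs(r2, cfg$error_rate)
    list(r1 = r1, r2 = r2, depths = setNames(depths, pool$barcode),
         n_mis = sum(mis))
  })
  ids <- sprintf("plasmid_%06d", seq_along(out$r1))
  r1_path <- file.path(dir, "plasmid_R1.fastq")
  r2_path <- file.path(dir, "plasmid_R2.fastq")
  write_fastq(ids, out$r1, strrep("?", nchar(out$r1)), r1_path)
  write_fastq(ids, out$r2, strrep("?", nchar(out$r2)), r2_path)
  list(r1 = r1_path, r2 = r2_path, depths = out$depths,
       n_misassigned = out$n_mis, n_reads = length(out$r1))
}

#' Simulate RNA amplicon reads with molecule-level truth
#'
#' Per barcode, `molecules_per_barcode` transcripts are drawn; each is an
#' inclusion molecule with probability `true_psi / 100` for the barcode's
#' variant in `condition`. Every molecule receives a distinct 10-nt UMI and
#' `1 + Geometric(duplication_p)` PCR copies. Read 1 runs from the exon-1
#' primer across the splice junction; read 2 carries the UMI, UTR anchor,
#' reverse-complemented barcode, restriction site and exon-3 check sequence.
#' Substitution errors are applied per copy.
#'
#' @param sim an [simulate_pool()] result.
#' @param condition condition whose truth PSI drives the simulation.
#' @param seed master seed (substream `rna:<condition>`).
#' @param backbone a [reporter_backbone()].
#' @param dir output directory.
#' @return list: `r1`, `r2` (paths), `molecules` (truth data.frame `barcode`,
#'   `umi`, `outcome`), `n_reads`.
#' @export
simulate_rna_fastq <- function(sim, condition = sim$cfg$conditions[1],
                               seed = sim$seed,
                               backbone = reporter_backbone(),
                               dir = tempdir()) {
  cfg <- sim$cfg
  pool <- sim$pool
  truth <- sim$truth[sim$truth$condition == condition, ]
  if (!nrow(truth)) stop_mpsa("config", "no truth for condition %s", condition)
  psi_of <- setNames(truth$true_psi, truth$variant_id)
  out <- with_seed(derive_seed(seed, paste0("rna:", condition)), {
    nb <- nrow(pool)
    m <- cfg$molecules_per_barcode
    test_exon <- substr(pool$oligo_sequence, pool$exon_start,
                        pool$exon_start + pool$exon_len - 1L)
    site <- "ACTAGT"
    inc_tx <- paste0(backbone$exon1, test_exon, backbone$exon3, site,
                     pool$barcode, backbone$utr_tail)
    skp_tx <- paste0(backbone$exon1, backbone$exon3, site, pool$barcode,
                     backbone$utr_tail)
    rc_inc <- revcomp(inc_tx)
    rc_skp <- revcomp(skp_tx)
    bc_idx <- rep(seq_len(nb), each = m)
    psi <- psi_of[pool$variant_id[bc_idx]]
    inc <- runif(nb * m) < psi / 100
    umi <- character(nb * m)
    for (b in seq_len(nb)) {
      umi[((b - 1L) * m + 1L):(b * m)] <- int_to_dna(sample.int(1048576L, m) - 1L, 10L)
    }
    copies <- 1L + rgeom(nb * m, cfg$duplication_p)
    idx <- rep(seq_len(nb * m), copies)
    tx <- ifelse(inc[idx], inc_tx[bc_idx[idx]], skp_tx[bc_idx[idx]])
    rc <- ifelse(inc[idx], rc_inc[bc_idx[idx]], rc_skp[bc_idx[idx]])
    r1 <- substr(tx, 1L, cfg$read_len)
    r2 <- paste0(umi[idx], substr(rc, 1L, cfg$read_len - 10L))
    r1 <- mutate_seqs(r1, cfg$error_rate)
    r2 <- mutate_seqs(r2, cfg$error_rate)
    list(r1 = r1, r2 = r2,
         molecules = data.frame(barcode = pool$barcode[bc_idx],
                                umi = umi,
                                outcome = ifelse(inc, "INCLUSION", "SKIPPING"),
                                stringsAsFactors = FALSE))
  })
  ids <- sprintf("rna_%07d", seq_along(out$r1))
  r1_path <- file.path(dir, sprintf("rna_%s_R1.fastq", condition))
  r2_path <- file.path(dir, sprintf("rna_%s_R2.fastq", condition))
  write_fastq(ids, out$r1, strrep("?", nchar(out$r1)), r1_path)
  write_fastq(ids, out$r2, strrep("?", nchar(out$r2)), r2_path)
  list(r1 = r1_path, r2 = r2_path, molecules = out$molecules,
       n_reads = length(out$r1))
}

#' End-to-end recovery check
#'
#' Runs design simulation, plasmid QC, RNA quantification and the recovery
#' comparisons in one call: maximum absolute PSI error against truth, the
#' expected control ordering (mutated < reference < consensus), and, with two
#' conditions, the directionality-agreement fractions.
#'
#' @param cfg a [sim_config()].
#' @param seed master seed.
#' @param run_plasmid_qc merge/call plasmid reads and honor the barcode
#'   filter (slower); otherwise all barcodes are kept.
#' @param backbone a [reporter_backbone()].
#' @param dir scratch directory.
#' @return list of class `mpsa_e2e`: `psi` (merged estimate/truth table),
#'   `max_abs_err`, `control_means`, `control_order_ok`, `agreement`
#'   (NULL for single-condition runs), `qc` (NULL when skipped).
#' @export
end_to_end_check <- function(cfg = sim_config(), seed = 1L,
                             run_plasmid_qc = FALSE,
                             backbone = reporter_backbone(),
                             dir = tempdir()) {
  stage <- "design"
  res <- tryCatch({
    sim <- simulate_pool(cfg, seed)
    qc <- NULL
    kept <- NULL
    if (run_plasmid_qc) {
      stage <- "plasmid_qc"
      pl <- simulate_plasmid_fastq(sim, seed, dir = dir)
      qc <- qc_plasmid(pl$r1, pl$r2, sim$pool, sim$design_cfg)
      kept <- qc$kept
    }
    stage <- "quantify"
    layout <- rna_layout(backbone, sim$design_cfg)
    tabs <- list()
    for (cond in cfg$conditions) {
      rna <- simulate_rna_fastq(sim, cond, seed, backbone, dir)
      q <- quantify(rna$r1, rna$r2, sim$pool, backbone, condition = cond,
                    layout = layout, kept_barcodes = kept,
                    cfg = sim$design_cfg)
      tabs[[cond]] <- q$variant_psi
    }
    stage <- "compare"
    est <- do.call(rbind, tabs)
    cmp <- merge(est, sim$truth,
                 by.x = c("variant_id", "condition"),
                 by.y = c("variant_id", "condition"))
    cmp$abs_err <- abs(cmp$psi - cmp$true_psi)
    ctrl <- tapply(cmp$psi, cmp$variant_class, mean, na.rm = TRUE)
    order_ok <- !cfg$controls ||
      (ctrl[["control_mutated"]] < ctrl[["reference"]] &&
         ctrl[["reference"]] < ctrl[["control_consensus"]])
    agreement <- NULL
    if (length(cfg$conditions) >= 2) {
      d1 <- delta_psi(tabs[[cfg$conditions[1]]], sim$pool)
      d2 <- delta_psi(tabs[[cfg$conditions[2]]], sim$pool)
      test1 <- d1[d1$variant_class == "SNV", c("variant_id", "delta_psi")]
      test2 <- d2[d2$variant_class == "SNV", c("variant_id", "delta_psi")]
      j <- merge(test1, test2, by = "variant_id")
      agreement <- directionality_agreement(j$delta_psi.x, j$delta_psi.y)
    }
    structure(list(psi = cmp, max_abs_err = max(cmp$abs_err, na.rm = TRUE),
                   control_means = ctrl, control_order_ok = order_ok,
                   agreement = agreement, qc = qc),
              class = "mpsa_e2e")
  }, mpsa_error = function(e) {
    stop_mpsa("pipeline", "stage %s failed: %s", stage, conditionMessage(e))
  })
  res
}
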