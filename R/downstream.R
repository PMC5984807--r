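# Interpretive analyses over PSI / delta-PSI tables: splicing-regulatory
# hexamer score deltas, per-hexamer effect associations, cross-condition
# directionality agreement, premature-termination-codon (PTC) prediction and
# the NMD regression, conservation contrasts, and external score joins.

#' Read / validate a hexamer score table
#'
#' Two-column table mapping DNA hexamers to an exonic splicing
#' enhancer/silencer activity score (ESEseq scale: positive = enhancer-like,
#' negative = silencer-like). Lookups of absent hexamers return 0.
#'
#' @param x TSV path or data.frame with columns `hexamer`, `score`.
#' @return named numeric vector keyed by hexamer.
#' @export
read_hexamer_table <- function(x) {
  if (is.character(x)) x <- read_tsv_file(x)
  if (!all(c("hexamer", "score") %in% names(x))) {
    stop_mpsa("malformed_input", "hexamer table needs columns hexamer, score")
  }
  assert_dna(x$hexamer, "hexamer")
  if (any(nchar(x$hexamer) != 6)) stop_mpsa("malformed_input", "hexamers must be 6 nt")
  if (anyDuplicated(x$hexamer)) stop_mpsa("malformed_input", "duplicate hexamer keys")
  setNames(as.numeric(x$score), x$hexamer)
}

hexamer_lookup <- function(table, hex) {
  v <- unname(table[hex])
  v[is.na(v)] <- 0
  v
}

# Hexamers fully inside the exon that overlap the locus [start, end]
# (1-based, exon coordinates). Returns character(0) when none fit.
exon_hexamers_at <- function(exon_seq, start, end) {
  L <- nchar(exon_seq)
  from <- max(1L, start - 5L)
  to <- min(end, L - 5L)
  if (to < from) return(character(0))
  substring(exon_seq, from:to, (from:to) + 5L)
}

#' Change in hexamer splicing-regulatory score caused by an exonic variant
#'
#' Sums the scores of all hexamers fully contained in the exon that overlap
#' the variant locus, in the variant and in the reference exon, and returns
#' variant minus reference. Hexamers extending outside the exon are excluded;
#' hexamers absent from the score table contribute 0. Swapping reference and
#' variant negates the result.
#'
#' @param ref_exon,var_exon exon sequences (reference and variant).
#' @param ref_locus,var_locus variant locus `c(start, end)` in each exon's
#'   own 1-based coordinates (for an SNV, both are `c(pos, pos)`).
#' @param table hexamer score table from [read_hexamer_table()].
#' @return list with `delta` (numeric), `gained` and `lost` hexamer sets.
#' @export
eseseq_delta <- function(ref_exon, var_exon, ref_locus, var_locus, table) {
  ref_hex <- exon_hexamers_at(ref_exon, ref_locus[1], ref_locus[2])
  var_hex <- exon_hexamers_at(var_exon, var_locus[1], var_locus[2])
  list(delta = sum(hexamer_lookup(table, var_hex)) -
         sum(hexamer_lookup(table, ref_hex)),
       gained = setdiff(var_hex, ref_hex),
       lost = setdiff(ref_hex, var_hex))
}

#' Hexamer score deltas for all exonic variants of a pool
#'
#' Applies [eseseq_delta()] to every designed variant whose edit lies inside
#' the test exon; intronic variants, reference rows and controls are flagged
#' not-applicable.
#'
#' @param pool pool data.frame carrying `var_offset`/`var_ref`/`var_alt`.
#' @param table hexamer score table.
#' @return data.frame `variant_id`, `applicable`, `delta_ese`, plus `gained`
#'   and `lost` hexamer sets as list columns.
#' @export
pool_eseseq_deltas <- function(pool, table) {
  one <- pool[!duplicated(pool$variant_id), , drop = FALSE]
  out <- lapply(seq_len(nrow(one)), function(i) {
    r <- one[i, ]
    if (is.na(r$var_offset) || !r$variant_class %in% c("SNV", "MNV", "insertion", "deletion")) {
      return(list(variant_id = r$variant_id, applicable = FALSE,
                  delta_ese = NA_real_, gained = list(character(0)),
                  lost = list(character(0))))
    }
    exon_off <- r$var_offset - r$up_len   # 1-based within exon
    n_ref <- nchar(r$var_ref); n_alt <- nchar(r$var_alt)
    if (exon_off < 1L || exon_off + n_alt - 1L > r$exon_len) {
      return(list(variant_id = r$variant_id, applicable = FALSE,
                  delta_ese = NA_real_, gained = list(character(0)),
                  lost = list(character(0))))
    }
    var_exon <- substr(r$oligo_sequence, r$exon_start,
                       r$exon_start + r$exon_len - 1L)
    ref_exon <- paste0(substr(var_exon, 1L, exon_off - 1L), r$var_ref,
                       substr(var_exon, exon_off + n_alt, r$exon_len))
    d <- eseseq_delta(ref_exon, var_exon,
                      c(exon_off, exon_off + n_ref - 1L),
                      c(exon_off, exon_off + n_alt - 1L), table)
    list(variant_id = r$variant_id, applicable = TRUE, delta_ese = d$delta,
         gained = list(d$gained), lost = list(d$lost))
  })
  as.data.frame(data.table::rbindlist(out))
}

#' Per-hexamer association with splicing change
#'
#' For each hexamer, the mean signed delta PSI over the events in which it
#' was gained (contributing `+delta_psi`) or lost (contributing
#' `-delta_psi`), the event count, and the Spearman correlation of the
#' per-hexamer means against a score table.
#'
#' @param events data.frame with list columns `gained`, `lost` and a numeric
#'   `delta_psi` per variant.
#' @param table optional hexamer score table for the correlation.
#' @return list with `per_hexamer` (data.frame `hexamer`, `mean_signed_dpsi`,
#'   `n_events`) and `spearman_vs_table` (NA when no table given).
#' @export
hexamer_association <- function(events, table = NULL) {
  recs <- list()
  for (i in seq_len(nrow(events))) {
    d <- events$delta_psi[i]
    if (!is.finite(d)) next
    g <- events$gained[[i]]; l <- events$lost[[i]]
    if (length(g)) recs[[length(recs) + 1L]] <- data.frame(hexamer = g, val = d)
    if (length(l)) recs[[length(recs) + 1L]] <- data.frame(hexamer = l, val = -d)
  }
  if (!length(recs)) stop_mpsa("insufficient_data", "no hexamer gain/loss events")
  dt <- data.table::rbindlist(recs)
  per <- dt[, .(mean_signed_dpsi = mean(val), n_events = .N), by = hexamer]
  rho <- NA_real_
  if (!is.null(table)) {
    sc <- table[per$hexamer]
    keep <- !is.na(sc)
    if (sum(keep) >= 3) {
      rho <- cor(per$mean_signed_dpsi[keep], sc[keep], method = "spearman")
    }
  }
  list(per_hexamer = as.data.frame(per), spearman_vs_table = rho)
}

#' Directionality agreement of variant effects between two conditions
#'
#' For each threshold tau, restricts to variants with `|delta_psi| > tau` in
#' the conditioning condition and a nonzero delta PSI in both, and reports
#' the fraction whose effect signs agree.
#'
#' @param delta_a,delta_b paired per-variant delta PSI in the two conditions.
#' @param tau thresholds on `|delta|` in the conditioning condition
#'   (strict `>`).
#' @param condition_on which vector gates eligibility (`"b"` by default,
#'   mirroring conditioning on the second cell line).
#' @return data.frame `tau`, `n_eligible`, `n_agree`, `fraction` (NA when no
#'   variant is eligible).
#' @export
directionality_agreement <- function(delta_a, delta_b, tau = c(0, 5, 10),
                                     condition_on = c("b", "a")) {
  condition_on <- match.arg(condition_on)
  if (length(delta_a) != length(delta_b)) {
    stop_mpsa("malformed_input", "delta vectors differ in length")
  }
  gate <- if (condition_on == "b") delta_b else delta_a
  ok <- is.finite(delta_a) & is.finite(delta_b)
  rows <- lapply(tau, function(t) {
    elig <- ok & abs(gate) > t & delta_a != 0 & delta_b != 0
    n <- sum(elig)
    agr <- sum(sign(delta_a[elig]) == sign(delta_b[elig]))
    data.frame(tau = t, n_eligible = n, n_agree = agr,
               fraction = if (n > 0) agr / n else NA_real_)
  })
  do.call(rbind, rows)
}

#' Predict a premature termination codon (PTC)
#'
#' Translates from the reporter ORF start, finds the first in-frame stop
#' codon, and flags a PTC when the stop ends 50 or more nucleotides upstream
#' of the last exon-exon junction of the transcript (boundary inclusive). A
#' transcript with no in-frame stop is flagged and is not a PTC.
#'
#' @param mrna transcript sequence.
#' @param orf_start 1-based offset of the ATG.
#' @param junctions strictly increasing exon-junction offsets (position of
#'   the last base of the upstream exon).
#' @param ptc_distance minimum stop-to-last-junction distance (nt).
#' @return list `is_ptc`, `stop_end` (NA when no stop), `last_junction`,
#'   `no_stop`.
#' @export
predict_ptc <- function(mrna, orf_start, junctions, ptc_distance = 50L) {
  if (substr(mrna, orf_start, orf_start + 2L) != "ATG") {
    stop_mpsa("invalid_orf", "orf_start does not point at an ATG")
  }
  if (is.unsorted(junctions, strictly = TRUE)) {
    stop_mpsa("malformed_input", "junction offsets must be strictly increasing")
  }
  L <- nchar(mrna)
  starts <- seq.int(orf_start, L - 2L, by = 3L)
  codons <- substring(mrna, starts, starts + 2L)
  stop_i <- which(codons %in% c("TAA", "TAG", "TGA"))
  last_j <- max(junctions)
  if (!length(stop_i)) {
    return(list(is_ptc = FALSE, stop_end = NA_integer_,
                last_junction = last_j, no_stop = TRUE))
  }
  stop_end <- starts[stop_i[1]] + 2L
  list(is_ptc = (last_j - stop_end) >= ptc_distance,
       stop_end = stop_end, last_junction = last_j, no_stop = FALSE)
}

#' PTC calls for every variant of a pool
#'
#' Builds each variant's inclusion isoform on the reporter backbone and
#' applies the 50-nt PTC rule.
#'
#' @param pool pool data.frame.
#' @param backbone a [reporter_backbone()].
#' @param ptc_distance see [predict_ptc()].
#' @return data.frame `variant_id`, `is_ptc`, `stop_end`, `last_junction`,
#'   `no_stop`.
#' @export
predict_pool_ptc <- function(pool, backbone = reporter_backbone(),
                             ptc_distance = 50L) {
  one <- pool[!duplicated(pool$variant_id), , drop = FALSE]
  rows <- lapply(seq_len(nrow(one)), function(i) {
    ref <- build_reference(one[i, ], backbone)
    p <- predict_ptc(ref$inclusion_seq, backbone$orf_start,
                     ref$junctions_inclusion, ptc_distance)
    data.frame(variant_id = one$variant_id[i], is_ptc = p$is_ptc,
               stop_end = p$stop_end, last_junction = p$last_junction,
               no_stop = p$no_stop)
  })
  as.data.frame(data.table::rbindlist(rows))
}

#' Fit the NMD regression model
#'
#' Ordinary least squares predicting the control-context PSI from the
#' NMD-attenuated (UPF1 knockdown) PSI and the PTC flag, on a seeded
#' stratified 2/3 train split; the held-out third gives `mse_test`, and the
#' nested model without the PTC term (same split) gives `mse_test_noptc`. A
#' PTC-sensitive assay should show `mse_test < mse_test_noptc`.
#'
#' @param psi_scrambled response: PSI under the control (scrambled shRNA)
#'   condition.
#' @param psi_upf1kd predictor: PSI under NMD knockdown.
#' @param ptc logical PTC flags.
#' @param seed split seed.
#' @return list of class `mpsa_nmd_fit`: `coefficients` (intercept, psi, ptc;
#'   `ptc` is NA when the flags are constant), `mse_test`, `mse_test_noptc`,
#'   `train_idx`, `test_idx`, `seed`, `n`.
#' @export
fit_nmd_model <- function(psi_scrambled, psi_upf1kd, ptc, seed = 1L) {
  keep <- complete.cases(psi_scrambled, psi_upf1kd, ptc)
  y <- psi_scrambled[keep]; x <- psi_upf1kd[keep]; p <- as.logical(ptc[keep])
  n <- length(y)
  if (n < 30) stop_mpsa("insufficient_data", "need >= 30 complete records")
  test_idx <- with_seed(seed, {
    idx <- integer(0)
    for (s in unique(p)) {
      grp <- which(p == s)
      idx <- c(idx, sample(grp, max(1L, round(length(grp) / 3))))
    }
    sort(idx)
  })
  train_idx <- setdiff(seq_len(n), test_idx)
  df <- data.frame(y = y, x = x, p = as.numeric(p))
  constant_ptc <- length(unique(p)) == 1L
  full <- if (constant_ptc) lm(y ~ x, data = df[train_idx, ])
          else lm(y ~ x + p, data = df[train_idx, ])
  if (any(is.na(coef(full)))) stop_mpsa("rank_deficient", "design matrix is rank deficient")
  nested <- lm(y ~ x, data = df[train_idx, ])
  mse <- function(fit) mean((df$y[test_idx] - predict(fit, df[test_idx, ]))^2)
  cf <- coef(full)
  structure(list(
    coefficients = c(intercept = unname(cf[1]), psi = unname(cf["x"]),
                     ptc = if (constant_ptc) NA_real_ else unname(cf["p"])),
    mse_test = mse(full),
    mse_test_noptc = mse(nested),
    train_idx = train_idx, test_idx = test_idx, seed = seed, n = n
  ), class = "mpsa_nmd_fit")
}

#' Predicted endogenous NMD effect on flagged variants
#'
#' Applies the fitted NMD model with the PTC indicator forced on to variants
#' whose annotation (stop gained / frameshift) marks them as endogenous NMD
#' targets, giving the PSI they would show with NMD active; the adjusted
#' delta PSI is recomputed against the unadjusted reference PSI. Non-flagged
#' variants are unchanged. Adjusted PSI is clamped to [0, 100] and clamping
#' is counted.
#'
#' @param tbl data.frame with `variant_id`, `psi` (measured
#'   knockdown-context PSI), `ref_psi`.
#' @param fit an [fit_nmd_model()] result.
#' @param flagged logical vector (or variant_id subset) marking NMD-target
#'   variants.
#' @return `tbl` with added `psi_adjusted`, `delta_psi_adjusted`, `clamped`;
#'   attribute `n_clamped`.
#' @export
predict_endogenous_nmd_effect <- function(tbl, fit, flagged) {
  if (!inherits(fit, "mpsa_nmd_fit")) stop_mpsa("config", "fit must be an mpsa_nmd_fit")
  if (is.character(flagged)) flagged <- tbl$variant_id %in% flagged
  cf <- fit$coefficients
  if (is.na(cf["ptc"])) stop_mpsa("config", "fit has no PTC coefficient")
  pred <- cf["intercept"] + cf["psi"] * tbl$psi + cf["ptc"]
  adj <- ifelse(flagged, pred, tbl$psi)
  clamped <- adj < 0 | adj > 100
  adj <- clamp(adj, 0, 100)
  tbl$psi_adjusted <- adj
  tbl$delta_psi_adjusted <- adj - tbl$ref_psi
  tbl$clamped <- clamped
  attr(tbl, "n_clamped") <- sum(clamped)
  tbl
}

#' Conservation contrast between high- and low-impact variants
#'
#' Two-sided Mann-Whitney U test comparing per-variant conservation scores
#' between variants with `|delta_psi| >= threshold` (high impact, boundary
#' inclusive) and the rest, optionally within an annotation subgroup.
#'
#' @param scores per-variant conservation scores.
#' @param abs_delta_psi per-variant `|delta_psi|`.
#' @param threshold grouping threshold (default 5).
#' @param annotation optional per-variant annotation class vector.
#' @param subgroup optional annotation value(s) to restrict to.
#' @return list of class `mpsa_conservation_contrast`: `U`, `p_value`,
#'   `n_high`, `n_low`, `median_high`, `median_low`, `threshold`.
#' @export
conservation_contrast <- function(scores, abs_delta_psi, threshold = 5,
                                  annotation = NULL, subgroup = NULL) {
  keep <- is.finite(scores) & is.finite(abs_delta_psi)
  if (!is.null(subgroup)) {
    if (is.null(annotation)) stop_mpsa("config", "subgroup filter needs annotations")
    keep <- keep & annotation %in% subgroup
  }
  hi <- keep & abs_delta_psi >= threshold
  lo <- keep & abs_delta_psi < threshold
  if (!sum(hi) || !sum(lo)) stop_mpsa("insufficient_data", "a contrast group is empty")
  w <- wilcox.test(scores[hi], scores[lo], alternative = "two.sided", exact = FALSE)
  structure(list(U = unname(w$statistic), p_value = w$p.value,
                 n_high = sum(hi), n_low = sum(lo),
                 median_high = median(scores[hi]), median_low = median(scores[lo]),
                 threshold = threshold),
            class = "mpsa_conservation_contrast")
}

#' Join an external per-variant score table and correlate with delta PSI
#'
#' Inner join on `variant_id`, then Spearman correlation between the external
#' score and delta PSI. Duplicate ids in the score table are an error;
#' unmatched ids are returned for logging.
#'
#' @param delta_tbl data.frame with `variant_id`, `delta_psi`.
#' @param score_tbl data.frame with `variant_id`, `score`.
#' @return list with `joined` data.frame, `spearman_rho`, `p_value`,
#'   `unmatched` ids.
#' @export
external_score_join <- function(delta_tbl, score_tbl) {
  if (anyDuplicated(score_tbl$variant_id)) {
    stop_mpsa("malformed_input", "duplicate variant id in score table: %s",
              score_tbl$variant_id[duplicated(score_tbl$variant_id)][1])
  }
  joined <- merge(delta_tbl, score_tbl, by = "variant_id")
  joined <- joined[is.finite(joined$delta_psi) & is.finite(joined$score), ]
  if (!nrow(joined)) stop_mpsa("insufficient_data", "no shared variant ids")
  ct <- suppressWarnings(cor.test(joined$score, joined$delta_psi,
                                  method = "spearman"))
  list(joined = joined,
       spearman_rho = unname(ct$estimate),
       p_value = ct$p.value,
       unmatched = setdiff(union(delta_tbl$variant_id, score_tbl$variant_id),
                           joined$variant_id))
}
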