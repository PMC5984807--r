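# Hexamer score deltas, directionality agreement, PTC prediction, the NMD
# regression, conservation contrasts, and external score joins.

toy_hex_table <- function() {
  read_hexamer_table(data.frame(
    hexamer = c("AAAAAA", "AAATAA", "AATAAA"),
    score = c(1.0, -0.5, -0.3)))
}

test_that("hexamer delta matches the hand-enumerated window sums", {
  tbl <- toy_hex_table()
  # ref exon AAAAAAA, SNV at position 4 A->T:
  #   ref windows {AAAAAA, AAAAAA} = 2.0
  #   var windows {AAATAA, AATAAA} = -0.8  ->  delta = -2.8
  d <- eseseq_delta("AAAAAAA", "AAATAAA", c(4, 4), c(4, 4), tbl)
  expect_equal(d$delta, -2.8)
  expect_equal(sort(d$gained), c("AAATAA", "AATAAA"))
  expect_equal(d$lost, "AAAAAA")

  # identical sequences -> 0
  expect_equal(eseseq_delta("AAAAAAA", "AAAAAAA", c(4, 4), c(4, 4), tbl)$delta, 0)

  # variant at exon position 1: only hexamers fully inside the exon count
  d1 <- eseseq_delta("AAAAAAA", "TAAAAAA", c(1, 1), c(1, 1), tbl)
  # single window starting at position 1; TAAAAA is absent -> contributes 0
  expect_equal(d1$delta, 0 - 1.0)

  # hexamers absent from the table contribute 0 overall
  d2 <- eseseq_delta("CCCCCCC", "CCCGCCC", c(4, 4), c(4, 4), tbl)
  expect_equal(d2$delta, 0)
})

test_that("hexamer delta is antisymmetric under ref/var swap", {
  tbl <- toy_hex_table()
  withr::with_seed(19L, {
    for (i in 1:25) {
      exon <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                    collapse = "")
      pos <- sample(30, 1)
      var <- exon
      substr(var, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                              substr(exon, pos, pos)), 1)
      fwd <- eseseq_delta(exon, var, c(pos, pos), c(pos, pos), tbl)
      rev <- eseseq_delta(var, exon, c(pos, pos), c(pos, pos), tbl)
      expect_equal(fwd$delta, -rev$delta)
      expect_equal(sort(fwd$gained), sort(rev$lost))
    }
  })
})

test_that("pool-level hexamer deltas skip intronic variants", {
  pool <- small_sim()$pool
  tbl <- toy_hex_table()
  ev <- pool_eseseq_deltas(pool, tbl)
  one <- pool[!duplicated(pool$variant_id), ]
  exonic <- one$variant_class == "SNV" &
    one$var_offset > one$up_len & one$var_offset <= one$up_len + one$exon_len
  expect_equal(ev$applicable[match(one$variant_id, ev$variant_id)], unname(exonic))
  expect_true(all(is.na(ev$delta_ese[!ev$applicable])))
  expect_true(all(is.finite(ev$delta_ese[ev$applicable])))
})

test_that("per-hexamer association uses the gain/loss sign convention", {
  ev <- data.frame(variant_id = c("v1", "v2", "v3"),
                   delta_psi = c(10, 10, 4))
  ev$gained <- list("AAAAAA", character(0), character(0))
  ev$lost <- list(character(0), "AAAAAA", "AAAAAA")
  # v1 gains h (+10), v2 loses h (-10), v3 loses h (-4)
  out <- hexamer_association(ev)
  row <- out$per_hexamer[out$per_hexamer$hexamer == "AAAAAA", ]
  expect_equal(row$n_events, 3L)
  expect_equal(row$mean_signed_dpsi, (10 - 10 - 4) / 3)

  # single gain and single loss cases from the definitions
  ev1 <- data.frame(variant_id = "v", delta_psi = 10)
  ev1$gained <- list("CCCCCC"); ev1$lost <- list(character(0))
  expect_equal(hexamer_association(ev1)$per_hexamer$mean_signed_dpsi, 10)
  ev2 <- data.frame(variant_id = "v", delta_psi = 10)
  ev2$gained <- list(character(0)); ev2$lost <- list("CCCCCC")
  expect_equal(hexamer_association(ev2)$per_hexamer$mean_signed_dpsi, -10)
})

test_that("directionality agreement thresholds, zeros, and scaling behave", {
  a <- c(5, -2, 4)
  b <- c(3, -1, -4)
  out <- directionality_agreement(a, b, tau = 0)
  expect_equal(out$fraction, 2 / 3)

  # conditioning on the first coordinate with tau = 5
  a2 <- c(6, -7, 1); b2 <- c(1, -2, 1)
  out2 <- directionality_agreement(a2, b2, tau = 5, condition_on = "a")
  expect_equal(out2$n_eligible, 2L)
  expect_equal(out2$fraction, 1)

  # exact zeros are never eligible
  out3 <- directionality_agreement(c(0, 5), c(3, 0), tau = 0)
  expect_equal(out3$n_eligible, 0L)
  expect_true(is.na(out3$fraction))

  # scale invariance under a positive factor on both columns
  withr::with_seed(7L, {
    x <- rnorm(200, 0, 8); y <- x + rnorm(200, 0, 6)
    base <- directionality_agreement(x, y, tau = c(0, 5, 10))
    scaled <- directionality_agreement(3.7 * x, 3.7 * y, tau = c(0, 3.7 * 5, 3.7 * 10))
    expect_equal(base$fraction, scaled$fraction)
    expect_equal(base$n_eligible, scaled$n_eligible)
    # the fraction table is monotone-friendly: eligibility shrinks with tau
    expect_true(all(diff(base$n_eligible) <= 0))
  })
})

test_that("PTC prediction implements the 50-nt junction rule, boundary inclusive", {
  # transcript: ATG, then codons, a TAA stop, padding, junction at the end
  make_tx <- function(gap_after_stop) {
    stopifnot(gap_after_stop %% 1 == 0)
    paste0("ATG", strrep("GGC", 5), "TAA", strrep("C", gap_after_stop))
  }
  tx <- make_tx(60)                      # stop ends 60 nt before last junction
  p <- predict_ptc(tx, 1L, junctions = c(10L, nchar(tx)))
  expect_true(p$is_ptc)
  expect_equal(p$stop_end, 21L)

  # stop inside the final exon (junction upstream of the stop)
  p2 <- predict_ptc(tx, 1L, junctions = c(10L))
  expect_false(p2$is_ptc)

  # boundary: stop ending exactly 50 nt before the last junction is a PTC
  tx50 <- make_tx(50)
  expect_true(predict_ptc(tx50, 1L, junctions = c(10L, nchar(tx50)))$is_ptc)
  tx49 <- make_tx(49)
  expect_false(predict_ptc(tx49, 1L, junctions = c(10L, nchar(tx49)))$is_ptc)

  # no in-frame stop: flagged, not a PTC
  nostop <- paste0("ATG", strrep("GGC", 30))
  p3 <- predict_ptc(nostop, 1L, junctions = c(10L, 60L))
  expect_false(p3$is_ptc)
  expect_true(p3$no_stop)

  expect_error(predict_ptc("CCCATGTAA", 1L, junctions = 5L),
               class = "mpsa_invalid_orf")
})

test_that("PTC prediction agrees with a brute-force codon scan", {
  oracle <- function(tx, orf_start, junctions, dist = 50L) {
    stops <- c("TAA", "TAG", "TGA")
    i <- orf_start
    while (i + 2L <= nchar(tx)) {
      if (substr(tx, i, i + 2L) %in% stops) {
        return((max(junctions) - (i + 2L)) >= dist)
      }
      i <- i + 3L
    }
    FALSE
  }
  withr::with_seed(23L, {
    for (rep in 1:300) {
      body_len <- 3L * sample(10:60, 1)
      tx <- paste0("ATG", paste(sample(c("A", "C", "G", "T"), body_len,
                                       replace = TRUE), collapse = ""))
      njunc <- sample(1:3, 1)
      junctions <- sort(sample(4:nchar(tx), njunc))
      mine <- predict_ptc(tx, 1L, junctions)$is_ptc
      expect_identical(mine, oracle(tx, 1L, junctions))
    }
  })
})

test_that("pool PTC calls reflect stops in the test exon", {
  pool <- small_sim()$pool
  calls <- predict_pool_ptc(pool)
  expect_equal(nrow(calls), length(unique(pool$variant_id)))
  expect_type(calls$is_ptc, "logical")
  # cross-check one variant against predict_ptc on the assembled isoform
  bb <- reporter_backbone()
  row <- pool[!duplicated(pool$variant_id), ][1, ]
  ref <- build_reference(row, bb)
  direct <- predict_ptc(ref$inclusion_seq, bb$orf_start,
                        ref$junctions_inclusion)
  expect_equal(calls$is_ptc[calls$variant_id == row$variant_id], direct$is_ptc)
})

test_that("the NMD regression recovers a noiseless linear model exactly", {
  withr::with_seed(3L, {
    x <- runif(90, 0, 100)
    p <- rep(c(TRUE, FALSE), length.out = 90)
    y <- 5 + 0.9 * x - 20 * p
  })
  fit <- fit_nmd_model(y, x, p, seed = 2L)
  expect_equal(unname(fit$coefficients["intercept"]), 5, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["psi"]), 0.9, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["ptc"]), -20, tolerance = 1e-8)
  expect_lt(fit$mse_test, 1e-16)
  expect_gt(fit$mse_test_noptc, 1)
  # the held-out set is about a third, stratified
  expect_equal(length(fit$test_idx), 30L)

  # all-false PTC flags: model degenerates to the simple regression
  fit0 <- fit_nmd_model(y[!p], x[!p], p[!p], seed = 2L)
  expect_true(is.na(fit0$coefficients["ptc"]))
  expect_equal(fit0$mse_test, fit0$mse_test_noptc)
})

test_that("with a true PTC effect the PTC model beats the nested model", {
  wins <- 0L
  betas <- numeric(20)
  for (s in 1:20) {
    withr::with_seed(1000L + s, {
      n <- 600L
      x <- runif(n, 0, 100)
      p <- runif(n) < 0.3
      y <- pmin(pmax(5 + 0.9 * x - 20 * p + rnorm(n, 0, 5), 0), 100)
    })
    fit <- fit_nmd_model(y, x, p, seed = s)
    betas[s] <- fit$coefficients["ptc"]
    if (fit$mse_test < fit$mse_test_noptc) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
  # beta_ptc close to the planted effect on average (clamping attenuates a bit)
  expect_lt(abs(mean(betas) - (-20)), 3)
})

test_that("endogenous NMD prediction shifts only flagged variants and clamps", {
  y <- c(50, 50); x <- c(50, 90)
  withr::with_seed(8L, {
    xx <- runif(60, 0, 100); pp <- rep(c(TRUE, FALSE), 30)
    yy <- 4 + 0.9 * xx - 25 * pp
  })
  fit <- fit_nmd_model(yy, xx, pp, seed = 1L)
  tbl <- data.frame(variant_id = c("v1", "v2", "v3"),
                    psi = c(50, 20, 96), ref_psi = c(40, 40, 40))
  out <- predict_endogenous_nmd_effect(tbl, fit, c("v1", "v2"))
  cf <- fit$coefficients
  expect_equal(out$psi_adjusted[1],
               unname(pmin(pmax(cf["intercept"] + cf["psi"] * 50 + cf["ptc"], 0), 100)))
  expect_equal(out$psi_adjusted[3], 96)       # non-flagged: unchanged
  expect_equal(out$delta_psi_adjusted, out$psi_adjusted - 40)
  # a low-PSI flagged variant clamps at 0
  expect_equal(out$psi_adjusted[2], 0)
  expect_true(out$clamped[2])
  expect_equal(attr(out, "n_clamped"), 1L)
})

test_that("conservation contrast separates shifted groups and not null ones", {
  withr::with_seed(12L, {
    # null: identical distributions -> p should not be small
    scores <- rnorm(200)
    dpsi <- abs(rnorm(200, 0, 10))
    cc0 <- conservation_contrast(scores, dpsi, threshold = 5)
    expect_gt(cc0$p_value, 0.05)
    # shifted: high-impact group +1.0 -> p < 0.01
    dpsi2 <- c(rep(10, 100), rep(1, 100))
    scores2 <- c(rnorm(100, 1), rnorm(100, 0))
    cc1 <- conservation_contrast(scores2, dpsi2, threshold = 5)
    expect_lt(cc1$p_value, 0.01)
    expect_equal(cc1$n_high, 100L)
  })
  # |delta| exactly at the threshold belongs to the high-impact group
  cc2 <- conservation_contrast(c(1, 2, 3, 4), c(5, 5, 1, 1), threshold = 5)
  expect_equal(cc2$n_high, 2L)
  # subgroup filtering
  ann <- c("synonymous", "synonymous", "intron", "intron")
  cc3 <- conservation_contrast(c(1, 2, 3, 4), c(6, 1, 6, 1), threshold = 5,
                               annotation = ann, subgroup = "synonymous")
  expect_equal(cc3$n_high + cc3$n_low, 2L)
  expect_error(conservation_contrast(c(1, 2), c(1, 2), threshold = 5),
               class = "mpsa_insufficient_data")
})

test_that("external score joins validate ids and report Spearman agreement", {
  d <- data.frame(variant_id = paste0("v", 1:40),
                  delta_psi = seq(-20, 19))
  perfect <- data.frame(variant_id = d$variant_id, score = d$delta_psi)
  out <- external_score_join(d, perfect)
  expect_equal(out$spearman_rho, 1)
  expect_equal(nrow(out$joined), 40L)

  # permuted scores: no association expected
  withr::with_seed(6L, {
    shuffled <- data.frame(variant_id = d$variant_id,
                           score = sample(d$delta_psi))
    out2 <- external_score_join(d, shuffled)
    expect_lt(abs(out2$spearman_rho), 0.4)
    expect_gt(out2$p_value, 0.01)
  })

  dup <- rbind(perfect, perfect[1, ])
  err <- tryCatch(external_score_join(d, dup),
                  mpsa_malformed_input = function(e) conditionMessage(e))
  expect_match(err, "v1")
  # unmatched ids are reported
  partial <- perfect[1:10, ]
  out3 <- external_score_join(d, partial)
  expect_equal(sort(out3$unmatched), sort(paste0("v", 11:40)))
})
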