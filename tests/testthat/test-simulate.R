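small_cfg <- function(...) {
  sim_config(n_chromosomes = 1, chrom_length = 2e7, ...)  # 400 bins
}

test_that("landscape generation is deterministic and respects changed_fraction", {
  cfg <- small_cfg(seed = 9)
  t1 <- simulate_rt_landscape(cfg)
  t2 <- simulate_rt_landscape(cfg)
  expect_identical(t1$rt$value, t2$rt$value)
  expect_identical(t1$origins, t2$origins)

  t0 <- simulate_rt_landscape(small_cfg(seed = 9, changed_fraction = 0))
  expect_true(all(t0$delta_rt$value == 0))

  # at 2000 bins the changed fraction lands within +/- 5 points of target
  big <- simulate_rt_landscape(sim_config(seed = 3))
  frac <- mean(abs(big$delta_rt$value) > big$config$delta_magnitude / 2)
  expect_lt(abs(frac - 0.3), 0.05)

  expect_true(all(t1$rt$value >= -3.5 & t1$rt$value <= 3.5))
  expect_true(all(t1$origins$efficiency >= 0 & t1$origins$efficiency <= 1))
})

test_that("bin_size larger than the chromosome is rejected", {
  expect_error(sim_config(chrom_length = 1e4, bin_size = 5e4), "bin_size")
})

test_that("repli-seq sampling inverts to the latent RT at high depth", {
  cfg <- small_cfg(seed = 2, depth = 1e5, noise_sd = 0)
  truth <- simulate_rt_landscape(cfg)
  cnt <- simulate_repliseq_counts(truth, replicates = 1)
  est <- log2(cnt$early / cnt$late)
  # law of large numbers: at depth 1e5 the log-ratio matches latent RT
  expect_lt(max(abs(est - truth$rt$value)), 0.05)

  # distinct replicate streams under the same master seed
  cnt2 <- simulate_repliseq_counts(truth, replicates = 1:2)
  r1 <- cnt2$early[cnt2$replicate == 1]
  r2 <- cnt2$early[cnt2$replicate == 2]
  expect_false(identical(r1, r2))
})

test_that("repli-seq fragments conserve the binned counts", {
  cfg <- small_cfg(seed = 5, depth = 5)
  truth <- simulate_rt_landscape(cfg)
  frg <- simulate_repliseq(truth, replicates = 1)
  cnt <- simulate_repliseq_counts(truth, replicates = 1)
  early <- frg[frg$fraction == "early", ]
  rebinned <- bin_fragments(early, truth$genome, cfg$bin_size)
  expect_equal(rebinned$value, as.numeric(cnt$early))
})

test_that("null features carry no RT information, coupled feature tracks delta-RT", {
  cfg <- small_cfg(seed = 6)
  truth <- simulate_rt_landscape(cfg)
  fa <- simulate_features(truth, "naive", "control")
  bin_of <- function(pk) match(
    paste(pk$chrom, (pk$start %/% cfg$bin_size) * cfg$bin_size),
    paste(truth$rt$chrom, truth$rt$start)
  )
  # a zero-weight feature: regression slope of signal on RT ~ 0
  null_pk <- fa$peaks[fa$peaks$feature == "feat10" & fa$peaks$replicate == 1, ]
  slope <- coef(lm(null_pk$signal ~ truth$rt$value[bin_of(null_pk)]))[2]
  expect_lt(abs(slope), 0.05)
  # a causal feature shows its weight
  pos_pk <- fa$peaks[fa$peaks$feature == "feat01" & fa$peaks$replicate == 1, ]
  slope1 <- coef(lm(pos_pk$signal ~ truth$rt$value[bin_of(pos_pk)]))[2]
  expect_lt(abs(slope1 - 1), 0.1)

  # coupled feature: sign of EpiLC signal change matches sign of delta-RT
  fb <- simulate_features(truth, "epilc", "control")
  pk_n <- fa$peaks[fa$peaks$feature == "feat01" & fa$peaks$replicate == 1, ]
  pk_e <- fb$peaks[fb$peaks$feature == "feat01" & fb$peaks$replicate == 1, ]
  expect_identical(pk_n$start, pk_e$start)  # shared locations
  d <- truth$delta_rt$value[bin_of(pk_n)]
  chg <- pk_e$signal - pk_n$signal
  up <- d > 0.9
  dn <- d < -0.9
  expect_gt(mean(sign(chg[up]) == 1), 0.8)
  expect_gt(mean(sign(chg[dn]) == -1), 0.8)

  # suppression = 1 makes the mutant distributionally identical to control
  cfg1 <- small_cfg(seed = 6, suppression = 1)
  truth1 <- simulate_rt_landscape(cfg1)
  fm <- simulate_features(truth1, "epilc", "mutant")
  fc <- simulate_features(truth1, "epilc", "control")
  expect_equal(mean(fm$peaks$signal), mean(fc$peaks$signal), tolerance = 0.05)
})

test_that("okazaki simulation follows the origin polarity model", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 1e7,
                    n_okazaki_fragments = 1e5, seed = 8)
  truth <- simulate_rt_landscape(cfg)
  expect_error(simulate_okseq(truth, origins = truth$origins[0, ]), "origin")

  # single origin, efficiency 1: Crick fraction 0 left, 1 right
  ori <- tibble::tibble(chrom = "chr1", start = 5e6, end = 5e6 + 1,
                        efficiency = 1)
  frg <- simulate_okseq(truth, origins = ori)
  expect_equal(nrow(frg), 1e5)  # strand counts conserve totals
  mid <- (frg$start + frg$end) %/% 2
  far_left <- frg$strand[mid < 4e6]
  far_right <- frg$strand[mid > 6e6]
  expect_true(all(far_left == "-"))
  expect_true(all(far_right == "+"))

  # efficiency 0.5: RFD steps from about -0.5 to about +0.5
  ori5 <- tibble::tibble(chrom = "chr1", start = 5e6, end = 5e6 + 1,
                         efficiency = 0.5)
  frg5 <- simulate_okseq(truth, origins = ori5)
  mid5 <- (frg5$start + frg5$end) %/% 2
  rfd_left <- mean(frg5$strand[mid5 < 4.9e6] == "+") * 2 - 1
  rfd_right <- mean(frg5$strand[mid5 > 5.1e6] == "+") * 2 - 1
  expect_lt(abs(rfd_left - (-0.5)), 0.05)
  expect_lt(abs(rfd_right - 0.5), 0.05)
})

test_that("expression tables are reproducible, positive, and decoupled at knob 0", {
  cfg <- small_cfg(seed = 11, n_tss = 500)
  truth <- simulate_rt_landscape(cfg)
  e1 <- simulate_expression(truth)
  e2 <- simulate_expression(truth)
  expect_identical(e1$expression, e2$expression)
  expect_true(all(e1$expression$expression > 0))

  eff <- purrr::map_dbl(seq_len(nrow(e1$tss)), function(i) {
    oc <- truth$origins[truth$origins$chrom == e1$tss$chrom[i], ]
    oc$efficiency[which.min(abs(oc$start - e1$tss$start[i]))]
  })
  expr <- e1$expression$expression[match(e1$tss$name, e1$expression$name)]
  rho <- cor(expr, eff, method = "spearman")
  expect_lt(abs(rho), 0.12)

  # knob engaged: strong rank correlation emerges
  cfg_c <- small_cfg(seed = 11, n_tss = 500, expression_origin_cor = 0.9)
  truth_c <- simulate_rt_landscape(cfg_c)
  ec <- simulate_expression(truth_c)
  eff_c <- purrr::map_dbl(seq_len(nrow(ec$tss)), function(i) {
    oc <- truth_c$origins[truth_c$origins$chrom == ec$tss$chrom[i], ]
    oc$efficiency[which.min(abs(oc$start - ec$tss$start[i]))]
  })
  expr_c <- ec$expression$expression[match(ec$tss$name, ec$expression$name)]
  expect_gt(cor(expr_c, eff_c, method = "spearman"), 0.6)
})
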