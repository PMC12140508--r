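test_that("stranded binning maps + to Crick and conserves totals", {
  g <- genome("chr1", 1e4)
  frg <- tibble::tibble(chrom = "chr1", start = c(100, 200, 2100),
                        end = c(250, 350, 2250),
                        strand = c("+", "-", "+"))
  st <- bin_stranded(frg, g, 1000)
  expect_equal(st$crick[1], 1)
  expect_equal(st$watson[1], 1)
  expect_equal(st$crick[3], 1)
  expect_equal(sum(st$crick) + sum(st$watson), 3)

  expect_error(bin_stranded(dplyr::mutate(frg, strand = "."), g, 1000),
               "strand")

  g2 <- tiny_genome(1, 1e5)
  frg_r <- random_intervals(500, g2, max_width = 200, seed = 41,
                            score = FALSE, strand = TRUE)
  st_r <- bin_stranded(frg_r, g2, 1000)
  oc <- oracle_bin_counts(frg_r[frg_r$strand == "+", ], g2, 1000)
  expect_equal(st_r$crick, oc$value)
})

test_that("RFD arithmetic, identity and masking hold bin-wise", {
  g <- genome("chr1", 3000)
  st <- tibble::tibble(chrom = "chr1", start = c(0, 1000, 2000),
                       end = c(1000, 2000, 3000),
                       watson = c(10, 5, 0), crick = c(30, 5, 10))
  r <- rfd(st, min_reads = 5)
  expect_equal(r$rfd[1], 0.5)
  expect_equal(r$crick_fraction[1], 0.75)
  expect_equal(r$rfd[2], 0)
  expect_equal(r$crick_fraction[2], 0.5)
  expect_equal(r$rfd[3], 1)
  expect_equal(r$rfd, 2 * r$crick_fraction - 1)

  low <- rfd(dplyr::mutate(st, watson = c(1, 0, 2), crick = c(2, 1, 1)),
             min_reads = 5)
  expect_true(all(is.na(low$rfd)))
})

test_that("stratification yields near-equal strata with genomic tie-breaks", {
  g <- tiny_genome(1, 1e5)
  pts <- random_intervals(8, g, max_width = 10, seed = 42, score = FALSE)
  s <- stratify(pts, c(5, 2, 7, 1, 8, 3, 6, 4), 4)
  expect_equal(sort(as.numeric(table(s$stratum))), c(2, 2, 2, 2))
  expect_equal(s$stratum[s$statistic == 1], 1L)
  expect_equal(s$stratum[s$statistic == 8], 4L)

  # all-equal statistic: deterministic genomic-order labels
  s0 <- stratify(pts, rep(1, 8), 4)
  expect_equal(s0$stratum, rep(1:4, each = 2))

  # stratum means are monotone in stratum index
  pts2 <- random_intervals(103, g, max_width = 10, seed = 43, score = FALSE)
  stat <- rnorm(103)
  s2 <- stratify(pts2, stat, 4)
  mns <- tapply(s2$statistic, s2$stratum, mean)
  expect_true(all(diff(mns) > 0))
  expect_lte(diff(range(table(s2$stratum))), 1)
})

test_that("fold-change gates keep the intended peaks", {
  g <- tiny_genome(1, 1e5)
  pts <- random_intervals(5, g, max_width = 10, seed = 44, score = FALSE)
  lfc <- c(-2, -0.5, 0, 1.5, 3)
  expect_equal(nrow(filter_fold_change(pts, lfc)), 3)
  expect_equal(nrow(filter_fold_change(pts, lfc, direction = "gain")), 2)
  expect_equal(nrow(filter_fold_change(pts, lfc, direction = "loss")), 1)
})

test_that("strand-bias metagene matches brute-force per-site averaging", {
  g <- genome("chr1", 1e5)
  set.seed(45)
  st <- tibble::tibble(chrom = "chr1", start = seq(0, 99000, 1000),
                       end = seq(1000, 100000, 1000),
                       watson = rpois(100, 20), crick = rpois(100, 20))
  r <- rfd(st)
  sites <- tibble::tibble(chrom = "chr1",
                          start = c(20500, 40500, 60500, 70500, 80500),
                          end = c(20501, 40501, 60501, 70501, 80501),
                          stratum = c(1L, 1L, 2L, 2L, 2L))
  prof <- strand_bias_metagene(r, sites, flank = 5000)
  # brute force for stratum 1, first offset bin (-5 kb)
  cf <- r$crick_fraction
  s1 <- sites[sites$stratum == 1, ]
  for (j in 1:10) {
    off <- -5000 + (j - 1) * 1000
    vals <- purrr::map_dbl(seq_len(nrow(s1)), function(i) {
      center <- (s1$start[i] + s1$end[i]) %/% 2
      cf[((center + off) %/% 1000) + 1]
    })
    expect_equal(prof$crick_fraction[prof$stratum == 1][j], mean(vals))
  }

  # uniform track gives a flat profile at 0.5
  st5 <- dplyr::mutate(st, watson = 20, crick = 20)
  prof5 <- strand_bias_metagene(rfd(st5), sites, flank = 5000)
  expect_true(all(prof5$crick_fraction == 0.5))

  # minus-strand sites flip their profile
  sites_m <- dplyr::mutate(sites[1, ], strand = "-", stratum = 1L)
  sites_p <- dplyr::mutate(sites[1, ], strand = "+", stratum = 1L)
  pm <- strand_bias_metagene(r, sites_m, flank = 5000)
  pp <- strand_bias_metagene(r, sites_p, flank = 5000)
  expect_equal(pm$crick_fraction, rev(pp$crick_fraction))
})

test_that("Kruskal-Wallis H matches the hand rank formula", {
  v <- c(1, 2, 3, 10, 11, 12)
  grp <- rep(c("a", "b"), each = 3)
  out <- strand_bias_h(v, grp)
  # rank-sum formula: H = 12/(N(N+1)) * sum n_i Rbar_i^2 - 3(N+1)
  rk <- rank(v)
  h_hand <- 12 / (6 * 7) * (3 * mean(rk[1:3])^2 + 3 * mean(rk[4:6])^2) - 3 * 7
  expect_equal(out$H, h_hand)
  expect_equal(out$H, 3.857, tolerance = 1e-3)

  same <- strand_bias_h(rep(c(1, 2, 3), 2), grp)
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
})

test_that("transition score is zero on flat tracks and tracks origin efficiency", {
  g <- genome("chr1", 1e5)
  st <- tibble::tibble(chrom = "chr1", start = seq(0, 99000, 1000),
                       end = seq(1000, 100000, 1000),
                       watson = 20, crick = 20)
  site <- tibble::tibble(chrom = "chr1", start = 50000, end = 50001)
  expect_equal(origin_transition_score(rfd(st), site, flank = 10000), 0)

  cfg <- sim_config(n_chromosomes = 1, chrom_length = 2e6,
                    n_okazaki_fragments = 1e5, seed = 46)
  truth <- simulate_rt_landscape(cfg)
  scores <- purrr::map_dbl(c(0.2, 0.5, 0.9), function(eff) {
    ori <- tibble::tibble(chrom = "chr1", start = 1e6, end = 1e6 + 1,
                          efficiency = eff)
    frg <- simulate_okseq(truth, origins = ori)
    r <- rfd(bin_stranded(frg, truth$genome, 1000))
    origin_transition_score(r, tibble::tibble(chrom = "chr1", start = 1e6,
                                              end = 1e6 + 1), flank = 25000)
  })
  expect_true(all(diff(scores) > 0))
  expect_true(all(scores >= -1 & scores <= 1))
})
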