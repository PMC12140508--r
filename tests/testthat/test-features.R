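test_that("background density is a CPM-per-bp rate, invariant to library size", {
  expect_equal(background_density(1e4, 1e6, 5e6), 0.002)
  expect_equal(background_density(0, 1e6, 5e6), 0)
  expect_equal(background_density(2e4, 2e6, 5e6),
               background_density(1e4, 1e6, 5e6))
  expect_error(background_density(10, 100, 0), "whole genome")
})

test_that("consensus peak correction subtracts length-scaled background with a floor", {
  pk <- tibble::tibble(
    replicate = c(1, 2),
    chrom = "chr1",
    start = c(1000, 1100),
    end = c(2000, 2100),
    signal = c(9, 11)
  )
  out <- corrected_peak_signal(pk, background = 0.002)
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 10 - 0.002 * 1000)  # 8

  # background 0 leaves the mean signal unchanged
  expect_equal(corrected_peak_signal(pk, 0)$score, 10)

  # signal below background floors at 0
  expect_equal(corrected_peak_signal(pk, 1)$score, 0)

  # peak absent from one replicate is dropped from the consensus
  pk2 <- dplyr::bind_rows(
    pk,
    tibble::tibble(replicate = 1, chrom = "chr1", start = 9000,
                   end = 9500, signal = 5)
  )
  expect_equal(nrow(corrected_peak_signal(pk2, 0)), 1)

  expect_warning(out0 <- corrected_peak_signal(pk[0, ], 0), "empty")
  expect_equal(nrow(out0), 0)
})

test_that("per-segment sums follow the strict >50% rule and match brute force", {
  segs <- tibble::tibble(segment_id = c("s1", "s2"), chrom = "chr1",
                         start = c(0, 1000), end = c(1000, 2000))
  inside <- tibble::tibble(chrom = "chr1", start = 100, end = 300, score = 5)
  expect_equal(sum_by_segment(inside, segs)$signal, c(5, 0))

  # exactly 50/50 split contributes to neither segment
  split <- tibble::tibble(chrom = "chr1", start = 950, end = 1050, score = 7)
  expect_equal(sum_by_segment(split, segs)$signal, c(0, 0))

  overlapping <- tibble::tibble(segment_id = c("a", "b"), chrom = "chr1",
                                start = c(0, 500), end = c(1000, 1500))
  expect_error(sum_by_segment(inside, overlapping), "overlap")

  g <- tiny_genome(2, 1e5)
  set.seed(15)
  segs_r <- purrr::map_dfr(g$chrom, function(ch) {
    cuts <- sort(sample(seq(1e4, 9e4, by = 1e4), 4))
    tibble::tibble(chrom = ch, start = c(0, cuts), end = c(cuts, 1e5))
  })
  segs_r$segment_id <- sprintf("s%02d", seq_len(nrow(segs_r)))
  pk <- random_intervals(300, g, max_width = 8000, seed = 16)
  expect_equal(sum_by_segment(pk, segs_r)$signal,
               oracle_segment_sums(pk, segs_r))
})

test_that("delta and transform operate elementwise as specified", {
  m1 <- tibble::tibble(segment_id = c("a", "b"), f1 = c(2, 4), f2 = c(1, 0))
  m0 <- tibble::tibble(segment_id = c("a", "b"), f1 = c(1, 1), f2 = c(0, 0))
  d <- delta_matrix(m1, m0)
  expect_equal(d$f1, c(1, 3))
  expect_equal(d$f2, c(1, 0))
  z <- delta_matrix(m1, m1)
  expect_true(all(z$f1 == 0 & z$f2 == 0))

  tm <- transform_matrix(tibble::tibble(segment_id = "a", f = 0), 1e6)
  expect_equal(tm$f, log(0.01))
  tm2 <- transform_matrix(tibble::tibble(segment_id = "a", f = exp(1) - 0.01), 1e6)
  expect_equal(tm2$f, 1)
  # doubling the window halves the transformed value
  tm3 <- transform_matrix(tibble::tibble(segment_id = "a", f = exp(1) - 0.01), 2e6)
  expect_equal(tm3$f, 0.5)
  # signed log handles negative deltas symmetrically
  sg <- transform_matrix(tibble::tibble(segment_id = "a", f = -0.99), 1e6,
                         signed = TRUE)
  expect_equal(sg$f, -log(1))
})

test_that("bin medians, nearest TSS, and IZ labels match brute force", {
  g <- genome("chr1", 2e5)
  pk <- tibble::tibble(chrom = "chr1",
                       start = c(100, 200, 300, 60000),
                       end = c(150, 250, 350, 60100),
                       value = c(1, 2, 9, 4))
  bm <- bin_median_aggregate(pk, g, 5e4)
  expect_equal(bm$value[1], 2)   # median of 1, 2, 9
  expect_equal(bm$value[2], 4)   # single peak
  expect_true(all(is.na(bm$value[3:4])))

  tss <- tibble::tibble(chrom = "chr1", start = c(1000, 3000), end = c(1001, 3001),
                        name = c("gA", "gB"))
  expr <- tibble::tibble(name = c("gA", "gB"), expression = c(10, 20))
  pk2 <- tibble::tibble(chrom = "chr1", start = c(900, 1995, 2900),
                        end = c(1000, 2005, 3000))
  nv <- nearest_tss_value(pk2, tss, expr)
  # middle peak is equidistant: tie goes to the lower coordinate
  expect_equal(nv$tss_name, c("gA", "gA", "gB"))
  expect_equal(nv$expression, c(10, 10, 20))

  # random case equals brute-force nearest search
  g2 <- tiny_genome(1, 1e6)
  tss_r <- random_intervals(40, g2, max_width = 2, seed = 18, score = FALSE)
  tss_r$name <- sprintf("g%02d", seq_len(nrow(tss_r)))
  expr_r <- tibble::tibble(name = tss_r$name, expression = runif(40))
  pk_r <- random_intervals(100, g2, max_width = 500, seed = 19, score = FALSE)
  nv_r <- nearest_tss_value(pk_r, tss_r, expr_r)
  brute <- purrr::map_chr(seq_len(nrow(pk_r)), function(k) {
    mid <- (pk_r$start[k] + pk_r$end[k]) %/% 2
    tss_r$name[which.min(abs(tss_r$start - mid))]
  })
  expect_identical(nv_r$tss_name, brute)

  iz <- tibble::tibble(chrom = "chr1", start = 49999, end = 150001)
  lab <- iz_bin_labels(iz, g, 5e4)
  expect_equal(lab$iz, c(TRUE, TRUE, TRUE, TRUE))
  iz2 <- tibble::tibble(chrom = "chr1", start = 50000, end = 150000)
  expect_equal(iz_bin_labels(iz2, g, 5e4)$iz, c(FALSE, TRUE, TRUE, FALSE))
  expect_true(all(!iz_bin_labels(iz[0, ], g, 5e4)$iz))
})

test_that("matrix construction conserves signal and is order-invariant", {
  g <- tiny_genome(1, 1e6)
  segs <- tibble::tibble(chrom = "chr1", start = seq(0, 9e5, 1e5),
                         end = seq(1e5, 1e6, 1e5))
  segs$segment_id <- sprintf("s%02d", 1:10)
  pk <- random_intervals(200, g, max_width = 2000, seed = 20)
  pk$score <- abs(pk$score)
  sums <- sum_by_segment(pk, segs)
  # accounting identity: assigned totals equal the sum over assignable peaks
  assigned <- sum(oracle_segment_sums(pk, segs))
  expect_equal(sum(sums$signal), assigned)
  # permutation invariance to peak order
  set.seed(1)
  shuf <- pk[sample(nrow(pk)), ]
  expect_equal(sum_by_segment(shuf, segs)$signal, sums$signal)
})
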