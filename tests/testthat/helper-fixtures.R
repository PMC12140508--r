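# Shared fixtures and brute-force oracles, built in code at test time.

tiny_genome <- function(n_chrom = 2, len = 1e6) {
  genome(paste0("chr", seq_len(n_chrom)), rep(len, n_chrom))
}

random_intervals <- function(n, genome, max_width = 5000, seed = 1,
                             score = TRUE, strand = FALSE) {
  set.seed(seed)
  chrom <- sample(genome$chrom, n, replace = TRUE)
  len <- genome$length[match(chrom, genome$chrom)]
  start <- floor(runif(n) * (len - max_width))
  width <- 1 + floor(runif(n) * (max_width - 1))
  out <- tibble::tibble(chrom = chrom, start = start, end = start + width)
  if (score) out$score <- round(rnorm(n), 6)
  if (strand) out$strand <- sample(c("+", "-"), n, replace = TRUE)
  out[order(factor(out$chrom, levels = genome$chrom), out$start, out$end), ]
}

# brute-force midpoint binning oracle
oracle_bin_counts <- function(fragments, genome, bin_size) {
  bins <- bin_track(genome, bin_size, value = 0)
  for (k in seq_len(nrow(fragments))) {
    mid <- (fragments$start[k] + fragments$end[k]) %/% 2
    i <- which(bins$chrom == fragments$chrom[k] &
                 bins$start <= mid & mid < bins$end)
    bins$value[i] <- bins$value[i] + 1
  }
  bins
}

# brute-force >50%-overlap segment summation oracle
oracle_segment_sums <- function(peaks, segments, min_overlap = 0.5) {
  sums <- setNames(rep(0, nrow(segments)), segments$segment_id)
  for (k in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(segments))) {
      if (peaks$chrom[k] != segments$chrom[j]) next
      ov <- min(peaks$end[k], segments$end[j]) -
        max(peaks$start[k], segments$start[j])
      if (ov > min_overlap * (peaks$end[k] - peaks$start[k])) {
        sums[j] <- sums[j] + peaks$score[k]
      }
    }
  }
  unname(sums)
}

# brute-force BH step-up oracle
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# brute-force reference-point matrix oracle (unweighted mean of
# overlapping track bins per offset window)
oracle_reference_matrix <- function(track, points, bin_size, upstream,
                                    downstream) {
  offs <- seq(-upstream, downstream - bin_size, by = bin_size)
  m <- matrix(NA_real_, nrow(points), length(offs))
  for (i in seq_len(nrow(points))) {
    center <- (points$start[i] + points$end[i]) %/% 2
    for (j in seq_along(offs)) {
      ws <- center + offs[j]; we <- ws + bin_size
      sel <- track$chrom == points$chrom[i] &
        track$start < we & track$end > ws
      v <- track$value[sel]
      if (any(!is.na(v))) m[i, j] <- mean(v, na.rm = TRUE)
    }
    if ("strand" %in% names(points) && points[["strand"]][i] == "-") {
      m[i, ] <- rev(m[i, ])
    }
  }
  m
}

# closed-form ridge oracle on standardized, centered data:
# beta = (X'X/n + lambda I)^-1 X'y/n
oracle_ridge <- function(x, y, lambda) {
  xs <- scale(x)
  xc <- scale(xs, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  n <- nrow(xc)
  solve(crossprod(xc) / n + lambda * diag(ncol(xc)), crossprod(xc, yc) / n)[, 1]
}

# smoothed replicate RT tracks from simulated counts, the standard pipeline
smoothed_replicates <- function(truth, state, genotype = "control",
                                replicates = seq_len(truth$config$n_replicates)) {
  counts <- simulate_repliseq_counts(truth, state, genotype, replicates)
  purrr::map_dfr(unique(counts$replicate), function(r) {
    cc <- counts[counts$replicate == r, ]
    e <- truth$rt; e$value <- cc$early
    l <- truth$rt; l$value <- cc$late
    sm <- loess_smooth(compute_rt(e, l))
    sm$replicate <- r
    sm
  })
}
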