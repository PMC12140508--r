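#' Compute raw replication timing from early/late counts
#'
#' Per-bin RT is `log2((early + c) / (late + c))` with pseudo-count `c`;
#' bins with total coverage `early + late < min_coverage` are masked as
#' missing so that pseudo-count-dominated bins never enter smoothing or
#' statistics.
#'
#' @param early,late Bin-track tibbles of read counts on the same binning.
#' @param pseudocount Pseudo-count added to both fractions (default 1).
#' @param min_coverage Minimum `early + late` for a bin to be kept
#'   (default 20).
#' @return A bin-track tibble of raw RT (log2 units).
#' @examples
#' g <- genome("chr1", 1e5)
#' e <- bin_track(g, 5e4, value = 64)
#' l <- bin_track(g, 5e4, value = 16)
#' compute_rt(e, l, pseudocount = 0)$value  # 2, 2
#' @export
compute_rt <- function(early, late, pseudocount = 1, min_coverage = 20) {
  assert_same_bins(early, late)
  out <- early
  tot <- early$value + late$value
  out$value <- log2((early$value + pseudocount) / (late$value + pseudocount))
  out$value[is.na(tot) | tot < min_coverage] <- NA_real_
  out
}

#' Loess-smooth an RT track chromosome by chromosome
#'
#' Local quadratic regression with tricube weights over bin index, the span
#' fraction being `span_bp / chromosome_length` (clipped so that at least
#' `min_points` non-missing bins enter each local fit). Missing bins are
#' excluded from fitting and stay missing. Chromosomes with fewer than 10
#' non-missing bins are passed through unsmoothed with a warning.
#'
#' @param track Bin-track tibble of raw RT.
#' @param span_bp Smoothing span in bp (default 300 kb).
#' @param min_points Minimum points per local fit (default 5).
#' @return A bin-track tibble of smoothed RT.
#' @export
loess_smooth <- function(track, span_bp = 3e5, min_points = 5) {
  out <- track
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    ok <- idx[!is.na(track$value[idx])]
    # truncated terminal bins shorter than half a bin are excluded from the fit
    bs <- track_bin_size(track)
    ok <- ok[(track$end[ok] - track$start[ok]) >= bs / 2]
    if (length(ok) < 10) {
      warn(paste0("chromosome ", ch, " has < 10 usable bins; left unsmoothed"))
      next
    }
    chrom_len <- max(track$end[idx])
    span <- max(span_bp / chrom_len, min_points / length(ok))
    fit <- loess(track$value[ok] ~ ok, span = span, degree = 2,
                 family = "gaussian",
                 control = loess.control(surface = "direct"))
    out$value[ok] <- as.numeric(predict(fit, ok))
  }
  out
}

rt_replicate_matrix <- function(tracks) {
  if (!all(c("replicate", "value") %in% names(tracks))) {
    abort("expected a long tibble with `replicate` and `value` columns")
  }
  wide <- tidyr::pivot_wider(tracks[, c("chrom", "start", "end", "replicate", "value")],
                             names_from = "replicate", values_from = "value")
  list(bins = wide[, c("chrom", "start", "end")],
       m = as.matrix(wide[, -(1:3)]))
}

#' Mean RT difference between two replicate sets
#'
#' Per-bin `mean(b) - mean(a)`. With `a` the naive and `b` the
#' differentiated (EpiLC) state, positive values mean earlier replication
#' after differentiation.
#'
#' @param a,b Long bin-track tibbles (`chrom`, `start`, `end`, `replicate`,
#'   `value`) of smoothed RT.
#' @return A bin-track tibble of delta-RT.
#' @export
delta_rt <- function(a, b) {
  wa <- rt_replicate_matrix(a)
  wb <- rt_replicate_matrix(b)
  if (ncol(wa$m) == 0 || ncol(wb$m) == 0) abort("empty replicate set")
  assert_same_bins(wa$bins, wb$bins)
  out <- wa$bins
  out$value <- rowMeans(wb$m) - rowMeans(wa$m)
  out
}

#' Per-bin differential RT test (Student's t + Benjamini-Hochberg)
#'
#' Unpaired two-sided Student's t with pooled variance per bin, comparing the
#' replicates of `b` against `a`; BH step-up across all testable bins.
#' A bin is labeled `earlier` if its delta is positive and its FDR is below
#' the threshold, `later` if negative and below, `unchanged` otherwise.
#' Degenerate bins with zero variance in both groups and equal means get
#' p = 1.
#'
#' @inheritParams delta_rt
#' @param fdr_threshold FDR cutoff for direction labels (default 0.05).
#' @return A tibble: `chrom`, `start`, `end`, `delta`, `t`, `df`, `p`,
#'   `fdr`, `direction`.
#' @export
test_rt_change <- function(a, b, fdr_threshold = 0.05) {
  wa <- rt_replicate_matrix(a)
  wb <- rt_replicate_matrix(b)
  assert_same_bins(wa$bins, wb$bins)
  na <- ncol(wa$m); nb <- ncol(wb$m)
  if (na < 2 || nb < 2) abort("need >= 2 replicates per side")
  ok <- rowSums(is.na(wa$m)) == 0 & rowSums(is.na(wb$m)) == 0
  ma <- rowMeans(wa$m); mb <- rowMeans(wb$m)
  va <- apply(wa$m, 1, var); vb <- apply(wb$m, 1, var)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- (mb - ma) / se
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se == 0
  tstat[degenerate] <- 0
  p[degenerate & (mb == ma)] <- 1
  p[degenerate & (mb != ma)] <- 0
  out <- wa$bins
  out$delta <- mb - ma
  out$t <- tstat
  out$df <- df
  out$p <- ifelse(ok, p, NA_real_)
  out$fdr <- NA_real_
  out$fdr[ok] <- p.adjust(out$p[ok], method = "BH")
  out$direction <- dplyr::case_when(
    !ok | is.na(out$fdr) ~ NA_character_,
    out$fdr < fdr_threshold & out$delta > 0 ~ "earlier",
    out$fdr < fdr_threshold & out$delta < 0 ~ "later",
    TRUE ~ "unchanged"
  )
  out
}

#' Spearman correlation between two bin tracks
#'
#' Computed over jointly non-missing bins; ties are mid-ranked (the default
#' of the underlying rank correlation).
#'
#' @param x,y Bin-track tibbles on the same binning.
#' @param method Correlation method (only `"spearman"`).
#' @return A single correlation coefficient.
#' @export
correlate_tracks <- function(x, y, method = "spearman") {
  assert_same_bins(x, y)
  ok <- !is.na(x$value) & !is.na(y$value)
  cor(x$value[ok], y$value[ok], method = method)
}

#' Variance fractions of principal components across RT samples
#'
#' Centers each bin (row) across samples and returns the normalized squared
#' singular values of the bins-by-samples matrix — the fraction of RT
#' variance attributable to each component. An all-identical sample set
#' yields an all-zero centered matrix; the fractions are then defined as
#' zeros with a warning.
#'
#' @param tracks Long tibble (`chrom`, `start`, `end`, `sample`, `value`).
#' @return A tibble `component`, `variance_fraction`.
#' @export
pca_variance <- function(tracks) {
  wide <- tidyr::pivot_wider(tracks[, c("chrom", "start", "end", "sample", "value")],
                             names_from = "sample", values_from = "value")
  m <- as.matrix(wide[, -(1:3)])
  m <- m[rowSums(is.na(m)) == 0, , drop = FALSE]
  m <- m - rowMeans(m)
  d <- svd(m, nu = 0, nv = 0)$d
  tot <- sum(d^2)
  frac <- if (tot == 0) {
    warn("all samples identical after centering; variance fractions undefined, returning zeros")
    rep(0, length(d))
  } else {
    d^2 / tot
  }
  tibble::tibble(component = seq_along(frac), variance_fraction = frac)
}
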