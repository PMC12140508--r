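#' Genome-wide background read density of a chromatin feature
#'
#' CPM-normalizes the reads falling outside all peaks of the feature and
#' divides by the total non-peak bp, giving a background density in CPM per
#' bp that can be scaled by peak length for subtraction.
#'
#' @param outside_reads Reads mapping outside all peaks of the feature.
#' @param total_reads Total mapped reads of the library.
#' @param nonpeak_bp Genome bp not covered by peaks (> 0).
#' @return Background density, CPM per bp.
#' @examples
#' background_density(1e4, 1e6, 5e6)  # 0.002
#' @export
background_density <- function(outside_reads, total_reads, nonpeak_bp) {
  if (any(nonpeak_bp <= 0)) abort("peaks cover the whole genome")
  (outside_reads * 1e6 / total_reads) / nonpeak_bp
}

#' Genome bp not covered by a peak set
#'
#' Merges overlapping peaks and subtracts their footprint from the genome
#' size; the denominator of [background_density()].
#'
#' @param peaks Interval tibble.
#' @param genome Genome tibble.
#' @return Non-peak bp (scalar).
#' @export
nonpeak_bp <- function(peaks, genome) {
  covered <- sum(purrr::map_dbl(genome$chrom, function(ch) {
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (nrow(p) == 0) return(0)
    p <- p[order(p$start), ]
    # merge overlapping intervals
    tot <- 0; cur_s <- p$start[1]; cur_e <- p$end[1]
    for (k in seq_len(nrow(p))[-1]) {
      if (p$start[k] <= cur_e) cur_e <- max(cur_e, p$end[k])
      else { tot <- tot + cur_e - cur_s; cur_s <- p$start[k]; cur_e <- p$end[k] }
    }
    tot + cur_e - cur_s
  }))
  sum(genome$length) - covered
}

overlaps_any <- function(x, y) {
  # logical per row of x: >= 1 bp overlap with any interval of y
  out <- logical(nrow(x))
  for (ch in unique(x$chrom)) {
    xi <- which(x$chrom == ch)
    yc <- y[y$chrom == ch, , drop = FALSE]
    if (nrow(yc) == 0) next
    yc <- yc[order(yc$start), ]
    # an x interval overlaps iff some y has start < x_end and end > x_start
    starts <- yc$start; ends <- cummax(yc$end)
    k <- findInterval(x$end[xi] - 1e-9, starts)
    out[xi] <- k >= 1 & ends[pmax(k, 1)] > x$start[xi]
  }
  out
}

#' Background-corrected consensus peak signal
#'
#' Consensus peaks are those of the first replicate that overlap (>= 1 bp) a
#' peak in every other replicate; their signal is the mean replicate signal
#' (CPM) minus the background density scaled by peak length, floored at 0.
#'
#' @param peaks Tibble of one feature's peaks across replicates:
#'   `replicate`, `chrom`, `start`, `end`, `signal`.
#' @param background CPM-per-bp background density from
#'   [background_density()].
#' @return An interval tibble of consensus peaks with corrected `score`.
#' @export
corrected_peak_signal <- function(peaks, background) {
  if (nrow(peaks) == 0) {
    warn("empty peak set")
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), score = numeric()))
  }
  reps <- sort(unique(peaks$replicate))
  ref <- peaks[peaks$replicate == reps[1], , drop = FALSE]
  keep <- rep(TRUE, nrow(ref))
  for (r in reps[-1]) {
    keep <- keep & overlaps_any(ref, peaks[peaks$replicate == r, , drop = FALSE])
  }
  cons <- ref[keep, c("chrom", "start", "end"), drop = FALSE]
  if (nrow(cons) == 0) {
    warn("no consensus peaks shared across replicates")
    cons$score <- numeric(0)
    return(cons)
  }
  # mean replicate signal over peaks overlapping each consensus location;
  # replicate peak sets are non-overlapping, so the best-overlapping peak is
  # the one straddling the consensus midpoint or its right neighbor
  sig <- matrix(NA_real_, nrow(cons), length(reps))
  mid <- (cons$start + cons$end) %/% 2
  for (ri in seq_along(reps)) {
    pr <- peaks[peaks$replicate == reps[ri], , drop = FALSE]
    for (ch in unique(cons$chrom)) {
      ci <- which(cons$chrom == ch)
      prc <- pr[pr$chrom == ch, , drop = FALSE]
      if (nrow(prc) == 0) next
      prc <- prc[order(prc$start), , drop = FALSE]
      for (cand in 0:1) {
        j <- findInterval(mid[ci], prc$start) + cand
        valid <- j >= 1 & j <= nrow(prc)
        ov <- rep(-1, length(j))
        ov[valid] <- pmin(cons$end[ci[valid]], prc$end[j[valid]]) -
          pmax(cons$start[ci[valid]], prc$start[j[valid]])
        hit <- valid & ov > 0 & is.na(sig[ci, ri])
        sig[ci[hit], ri] <- prc$signal[j[hit]]
      }
    }
  }
  cons$score <- pmax(rowMeans(sig, na.rm = TRUE) -
                       background * (cons$end - cons$start), 0)
  cons
}

#' Sum corrected peak signal per segment
#'
#' A peak contributes its full score to the unique segment covering strictly
#' more than `min_overlap` of the peak's length; peaks without such a
#' segment contribute nowhere. Segments must not overlap.
#'
#' @param peaks Interval tibble with `score`.
#' @param segments Segment tibble (`segment_id`, `chrom`, `start`, `end`).
#' @param min_overlap Required covered fraction of the peak (default 0.5,
#'   strict inequality).
#' @return A tibble `segment_id`, `signal` with one row per segment (0 where
#'   no peak was assigned).
#' @export
sum_by_segment <- function(peaks, segments, min_overlap = 0.5) {
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
      abort("segments overlap; segmentation invariant violated")
    }
  }
  # a segment covering more than half of a peak necessarily contains the
  # peak midpoint, so only the midpoint-containing segment need be checked
  sums <- setNames(rep(0, nrow(segments)), segments$segment_id)
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    sc <- segments[segments$chrom == ch, , drop = FALSE]
    if (nrow(sc) == 0) next
    sc <- sc[order(sc$start), ]
    mid <- (peaks$start[pi] + peaks$end[pi]) / 2
    j <- findInterval(mid, sc$start)
    valid <- j >= 1 & mid < sc$end[pmax(j, 1)]
    ov <- rep(-1, length(j))
    ov[valid] <- pmin(peaks$end[pi[valid]], sc$end[j[valid]]) -
      pmax(peaks$start[pi[valid]], sc$start[j[valid]])
    hit <- valid & ov > min_overlap * (peaks$end[pi] - peaks$start[pi])
    if (any(hit)) {
      add <- tapply(peaks$score[pi[hit]], sc$segment_id[j[hit]], sum)
      sums[names(add)] <- sums[names(add)] + as.numeric(add)
    }
  }
  tibble::tibble(segment_id = segments$segment_id,
                 signal = as.numeric(sums[segments$segment_id]))
}

#' Build a segment-by-feature signal matrix
#'
#' Runs background correction and per-segment summation for every feature of
#' an assay set and assembles the wide segment x feature matrix. Absent
#' signal is 0, never missing.
#'
#' @param assays A list as returned by [simulate_features()] (or with the
#'   same shape): `peaks` long tibble over features/replicates and
#'   `library` totals.
#' @param segments Segment tibble.
#' @param genome Genome tibble (for non-peak bp).
#' @return A tibble with `segment_id` and one numeric column per feature.
#' @export
build_feature_matrix <- function(assays, segments, genome) {
  feats <- unique(assays$peaks$feature)
  cols <- purrr::map(feats, function(f) {
    pk <- assays$peaks[assays$peaks$feature == f, , drop = FALSE]
    lib <- assays$library[assays$library$feature == f, , drop = FALSE]
    bg <- background_density(sum(lib$outside_reads), sum(lib$total_reads),
                             nonpeak_bp(pk, genome))
    cons <- corrected_peak_signal(pk, bg)
    sum_by_segment(cons, segments)$signal
  })
  out <- tibble::tibble(segment_id = segments$segment_id)
  out[feats] <- cols
  out
}

#' Elementwise difference of two segment-by-feature matrices
#'
#' EpiLC minus naive on identical segment sets.
#'
#' @param epilc,naive Wide matrices from [build_feature_matrix()].
#' @return A matrix tibble of deltas.
#' @export
delta_matrix <- function(epilc, naive) {
  if (!identical(epilc$segment_id, naive$segment_id) ||
      !identical(names(epilc), names(naive))) {
    abort("matrices must share segment ids and feature columns")
  }
  out <- epilc
  num <- names(out) != "segment_id"
  out[num] <- epilc[num] - naive[num]
  out
}

#' Log-transform and window-normalize a feature matrix
#'
#' State matrices (non-negative): `log(value + 0.01)`, then divided by the
#' segment length in Mb. Delta matrices contain negatives, for which the
#' plain log is undefined; with `signed = TRUE` the signed log
#' `sign(v) * log(|v| + 0.01)` is used instead.
#'
#' @param m Wide matrix tibble.
#' @param segment_lengths Segment lengths in bp, aligned to rows of `m`.
#' @param signed Use the signed-log transform (for delta matrices).
#' @param pseudocount Pseudo-count inside the log (default 0.01).
#' @return The transformed matrix tibble.
#' @export
transform_matrix <- function(m, segment_lengths, signed = FALSE,
                             pseudocount = 0.01) {
  out <- m
  num <- names(out) != "segment_id"
  mb <- segment_lengths / 1e6
  f <- if (signed) {
    function(v) sign(v) * log(abs(v) + pseudocount) / mb
  } else {
    function(v) log(v + pseudocount) / mb
  }
  out[num] <- lapply(out[num], f)
  out
}

#' Median per-bin aggregate of peak-level values
#'
#' Assigns each peak to the bin containing its midpoint and takes the median
#' value per bin; bins without peaks are missing.
#'
#' @param peaks Interval tibble with a `value` column.
#' @param genome Genome tibble.
#' @param bin_size Bin width in bp.
#' @return A bin-track tibble of medians.
#' @export
bin_median_aggregate <- function(peaks, genome, bin_size) {
  out <- bin_track(genome, bin_size)
  if (nrow(peaks) == 0) return(out)
  mid <- (peaks$start + peaks$end) %/% 2
  key <- paste(peaks$chrom, (mid %/% bin_size) * bin_size)
  key_out <- paste(out$chrom, out$start)
  idx <- match(key, key_out)
  agg <- tapply(peaks$value, idx, median)
  out$value[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Expression of the transcript with the nearest TSS to each peak
#'
#' Distance is from the peak midpoint to the TSS position (interval start);
#' ties break toward the lower coordinate.
#'
#' @param peaks Interval tibble.
#' @param tss TSS interval tibble with `name`.
#' @param expression Tibble `name`, `expression`.
#' @return `peaks` with columns `tss_name` and `expression` added.
#' @export
nearest_tss_value <- function(peaks, tss, expression) {
  peaks$tss_name <- NA_character_
  mid <- (peaks$start + peaks$end) %/% 2
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    tc <- tss[tss$chrom == ch, , drop = FALSE]
    if (nrow(tc) == 0) next
    tc <- tc[order(tc$start), ]
    for (k in pi) {
      d <- abs(tc$start - mid[k])
      peaks$tss_name[k] <- tc$name[which.min(d)]  # first min = lower coord
    }
  }
  peaks$expression <- expression$expression[match(peaks$tss_name,
                                                 expression$name)]
  peaks
}

#' Label genome bins overlapping initiation zones
#'
#' A bin is positive iff it shares at least 1 bp with any initiation-zone
#' interval.
#'
#' @param iz Interval tibble of initiation zones.
#' @param genome Genome tibble.
#' @param bin_size Bin width in bp.
#' @return A tibble of genome bins with a logical `iz` column.
#' @export
iz_bin_labels <- function(iz, genome, bin_size) {
  bins <- genome_bins(genome, bin_size)
  bins$iz <- overlaps_any(bins, iz)
  bins$bin <- NULL
  bins
}
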