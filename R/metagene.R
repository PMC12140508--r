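#' Reference-point signal matrix around anchor sites
#'
#' For each reference point (anchor = interval midpoint; minus-strand points
#' have their offsets flipped) and each offset bin of width `bin_size` in
#' `[-upstream, +downstream)`, the cell value is the mean of the track
#' values whose bins overlap the offset window. Cells without data are
#' missing unless `missing_as_zero`; rows that are entirely zero after that
#' substitution are dropped when `skip_zeros` (their count is recorded in
#' the `dropped_zero_rows` attribute). Points whose window leaves the
#' chromosome keep their row, with out-of-range cells treated as missing.
#'
#' @param track Bin-track tibble (any bin width).
#' @param points Interval tibble of reference points (optional `strand`).
#' @param bin_size Offset bin width in bp.
#' @param upstream,downstream Window extents in bp (multiples of
#'   `bin_size`).
#' @param missing_as_zero Substitute 0 for missing cells.
#' @param skip_zeros Drop all-zero rows.
#' @return A list of class `metagene_matrix`: `matrix` (points x offsets),
#'   `offsets` (bp of each column's window start), `points` (retained
#'   points), and the parameters.
#' @export
reference_point_matrix <- function(track, points, bin_size, upstream,
                                   downstream, missing_as_zero = FALSE,
                                   skip_zeros = FALSE) {
  stopifnot(bin_size > 0, upstream > 0, downstream > 0)
  if (upstream %% bin_size != 0 || downstream %% bin_size != 0) {
    abort("upstream and downstream must be multiples of bin_size")
  }
  offs <- seq(-upstream, downstream - bin_size, by = bin_size)
  centers <- (points$start + points$end) %/% 2
  track_bs <- track_bin_size(track)
  key_track <- paste(track$chrom, track$start)
  m <- matrix(NA_real_, nrow(points), length(offs))
  for (i in seq_len(nrow(points))) {
    w_start <- centers[i] + offs
    w_end <- w_start + bin_size
    # track bins overlapping [w_start, w_end)
    first_bin <- (w_start %/% track_bs) * track_bs
    m[i, ] <- vapply(seq_along(offs), function(j) {
      starts <- seq(first_bin[j], w_end[j] - 1, by = track_bs)
      idx <- match(paste(points$chrom[i], starts), key_track)
      v <- track$value[idx]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    if ("strand" %in% names(points) && !is.na(points[["strand"]][i]) &&
        points[["strand"]][i] == "-") {
      m[i, ] <- rev(m[i, ])
    }
  }
  if (missing_as_zero) m[is.na(m)] <- 0
  dropped <- 0L
  keep <- rep(TRUE, nrow(points))
  if (skip_zeros) {
    keep <- rowSums(m != 0, na.rm = TRUE) > 0
    dropped <- sum(!keep)
    m <- m[keep, , drop = FALSE]
  }
  structure(list(matrix = m, offsets = offs,
                 points = points[keep, , drop = FALSE],
                 bin_size = bin_size, upstream = upstream,
                 downstream = downstream,
                 missing_as_zero = missing_as_zero,
                 skip_zeros = skip_zeros,
                 dropped_zero_rows = dropped),
            class = "metagene_matrix")
}

#' Mean metagene profile of a reference-point matrix
#'
#' Column means over retained rows. Without `missing_as_zero`, offsets with
#' no data in any row stay missing rather than silently 0. Optional loess
#' smoothing is display-only.
#'
#' @param m A `metagene_matrix`.
#' @param smooth Loess span for display smoothing (`NULL` = none).
#' @return A tibble `offset`, `value` (and `smoothed` when requested).
#' @export
mean_profile <- function(m, smooth = NULL) {
  stopifnot(inherits(m, "metagene_matrix"))
  v <- colMeans(m$matrix, na.rm = TRUE)
  v[colSums(!is.na(m$matrix)) == 0] <- NA_real_
  out <- tibble::tibble(offset = m$offsets, value = v)
  if (!is.null(smooth)) {
    ok <- !is.na(out$value)
    fit <- loess(value ~ offset, data = out[ok, ], span = smooth, degree = 2)
    out$smoothed <- NA_real_
    out$smoothed[ok] <- predict(fit)
  }
  out
}

#' Per-stratum integration of feature, RT and RNA changes
#'
#' Ranks genome bins into strata of a stratifying statistic (ties broken by
#' genomic order) and summarizes every supplied value column per stratum
#' with its mean and median over jointly non-missing bins — the table behind
#' quartile heatmap readouts of coupled feature/RT/transcription changes.
#'
#' @param bins A tibble of aligned per-bin values: `chrom`, `start`, `end`
#'   plus numeric columns.
#' @param strat_statistic Name of the column to stratify on.
#' @param value_cols Character vector of columns to summarize (default all
#'   numeric except the statistic).
#' @param n_strata Number of strata (default 4, quartiles).
#' @return A tibble with one row per stratum x value column: `stratum`,
#'   `variable`, `mean`, `median`, `n_bins`.
#' @export
quartile_integration <- function(bins, strat_statistic, value_cols = NULL,
                                 n_strata = 4) {
  if (!strat_statistic %in% names(bins)) {
    abort(paste0("no column `", strat_statistic, "` in bins"))
  }
  if (is.null(value_cols)) {
    value_cols <- setdiff(names(bins)[vapply(bins, is.numeric, logical(1))],
                          c("start", "end", strat_statistic))
  }
  ok <- stats::complete.cases(bins[, c(strat_statistic, value_cols)])
  b <- bins[ok, , drop = FALSE]
  strat <- stratify(b, b[[strat_statistic]], n_strata)
  purrr::map_dfr(value_cols, function(vc) {
    dplyr::summarise(dplyr::group_by(strat, .data$stratum),
                     variable = vc,
                     mean = mean(.data[[vc]]),
                     median = median(.data[[vc]]),
                     n_bins = dplyr::n(),
                     .groups = "drop")
  })
}
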