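#' Parameters for circular binary segmentation
#'
#' Defaults follow the settings used for RT segmentation in this field:
#' 1000 permutations, an extremely conservative split significance level of
#' 1e-15, and "sdundo" pruning at 5 track standard deviations.
#'
#' @param nperm Number of permutations per split test (>= 100).
#' @param alpha Significance level to accept a changepoint (0 < alpha < 1).
#' @param undo_sd Changepoints whose flanking segment means are separated
#'   by fewer than `undo_sd` standard errors of their difference are
#'   pruned ("sdundo").
#' @param max_window Longest arc (in bins) scanned per segment; a documented
#'   speed cap.
#' @param seed Seed for the permutation streams.
#' @return A list of class `cbs_params`.
#' @export
cbs_params <- function(nperm = 1000, alpha = 1e-15, undo_sd = 5,
                       max_window = 5000, seed = 1) {
  if (nperm < 100) abort("cbs_params: nperm must be >= 100")
  if (alpha <= 0 || alpha >= 1) abort("cbs_params: alpha must be in (0, 1)")
  structure(list(nperm = nperm, alpha = alpha, undo_sd = undo_sd,
                 max_window = max_window, seed = seed),
            class = "cbs_params")
}

# Recursive CBS over one numeric vector; returns sorted changepoint
# boundaries (indices k meaning a boundary between x[k] and x[k+1]).
cbs_changepoints <- function(x, params) {
  n <- length(x)
  boundaries <- integer(0)
  recurse <- function(lo, hi) {
    len <- hi - lo + 1
    if (len < 3) return(invisible(NULL))
    seg <- x[lo:hi]
    st <- cbs_max_stat(seg, params$max_window)
    if (st[1] <= 0) return(invisible(NULL))
    p <- cbs_perm_pvalue(seg, st[1], params$nperm, params$alpha,
                         params$max_window)
    if (p > params$alpha) return(invisible(NULL))
    i <- st[2]; j <- st[3]           # arc (i, j] in 0-based local coords
    cuts <- integer(0)
    if (i > 0) cuts <- c(cuts, lo + i - 1)
    if (j < len) cuts <- c(cuts, lo + j - 1)
    if (!length(cuts)) return(invisible(NULL))
    boundaries <<- c(boundaries, cuts)
    edges <- sort(unique(c(lo - 1, cuts, hi)))
    for (k in seq_len(length(edges) - 1)) {
      recurse(edges[k] + 1, edges[k + 1])
    }
    invisible(NULL)
  }
  recurse(1, n)
  sort(unique(boundaries))
}

# sdundo pruning: repeatedly drop the changepoint whose flanking segment
# means are least separated, measured in standard errors of the mean
# difference (sd_track * sqrt(1/n1 + 1/n2)), while that standardized gap
# is below undo_sd.
sdundo_prune <- function(x, boundaries, undo_sd, sd_track) {
  repeat {
    if (!length(boundaries)) return(boundaries)
    edges <- c(0, boundaries, length(x))
    lens <- diff(edges)
    means <- vapply(seq_len(length(edges) - 1), function(k) {
      mean(x[(edges[k] + 1):edges[k + 1]])
    }, numeric(1))
    k <- length(means)
    z <- abs(diff(means)) /
      (sd_track * sqrt(1 / lens[-k] + 1 / lens[-1]))
    weakest <- which.min(z)
    if (z[weakest] >= undo_sd) return(boundaries)
    boundaries <- boundaries[-weakest]
  }
}

#' Segment a bin track by circular binary segmentation
#'
#' Re-implementation of circular binary segmentation restricted to linear
#' (non-wrapping) arcs per chromosome: recursively, the arc maximizing the
#' standardized mean-difference statistic is tested by permutation (values
#' shuffled within the segment) and the split is accepted when the
#' permutation p-value is at most `alpha`; accepted splits recurse into
#' their children. Afterward, "sdundo" pruning removes changepoints whose
#' flanking segment means are separated by fewer than `undo_sd` standard
#' errors of their mean difference, the track's residual sd being estimated
#' robustly as `mad(diff(values)) / sqrt(2)`.
#' Missing bins are excluded; segments tile the non-missing extent of each
#' chromosome.
#'
#' @param track Bin-track tibble.
#' @param params A [cbs_params()].
#' @return A segment tibble: `segment_id`, `chrom`, `start`, `end`,
#'   `n_bins`, `mean`.
#' @export
cbs_segment <- function(track, params = cbs_params()) {
  out <- list()
  for (ch in unique(track$chrom)) {
    sub <- track[track$chrom == ch & !is.na(track$value), , drop = FALSE]
    if (nrow(sub) == 0) next
    x <- sub$value
    sd_track <- mad(diff(x)) / sqrt(2)
    boundaries <- with_seed(child_seed(params$seed, paste("cbs", ch)),
                            cbs_changepoints(x, params))
    if (sd_track > 0) {
      boundaries <- sdundo_prune(x, boundaries, params$undo_sd, sd_track)
    }
    edges <- c(0, boundaries, length(x))
    segs <- purrr::map_dfr(seq_len(length(edges) - 1), function(k) {
      i1 <- edges[k] + 1; i2 <- edges[k + 1]
      tibble::tibble(chrom = ch,
                     start = sub$start[i1], end = sub$end[i2],
                     n_bins = i2 - i1 + 1,
                     mean = mean(x[i1:i2]))
    })
    out[[ch]] <- segs
  }
  res <- dplyr::bind_rows(out)
  if (is.null(res) || nrow(res) == 0) {
    return(tibble::tibble(segment_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_bins = integer(), mean = numeric()))
  }
  res$segment_id <- sprintf("seg%04d", seq_len(nrow(res)))
  res[, c("segment_id", "chrom", "start", "end", "n_bins", "mean")]
}

#' Refresh segment means from a bin track
#'
#' Mean over the non-missing bins whose midpoint falls inside each segment.
#'
#' @param track Bin-track tibble.
#' @param segments Segment tibble from [cbs_segment()].
#' @return `segments` with `mean` and `n_bins` recomputed against `track`.
#' @export
segment_means <- function(track, segments) {
  mid <- (track$start + track$end) / 2
  segments$mean <- NA_real_
  segments$n_bins <- 0L
  for (k in seq_len(nrow(segments))) {
    sel <- track$chrom == segments$chrom[k] &
      mid >= segments$start[k] & mid < segments$end[k] &
      !is.na(track$value)
    segments$n_bins[k] <- sum(sel)
    segments$mean[k] <- if (any(sel)) mean(track$value[sel]) else NA_real_
  }
  segments
}
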