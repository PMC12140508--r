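#' Define a genome as an ordered set of chromosomes
#'
#' A genome is the coordinate backbone every track and interval set in the
#' package refers to. Chromosome order is preserved everywhere downstream so
#' that tracks derived from the same genome are row-aligned.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer-ish vector of chromosome lengths in bp (all >= 1).
#' @return A tibble with columns `chrom` and `length`, one row per chromosome.
#' @examples
#' genome(c("chr1", "chr2"), c(5e6, 3e6))
#' @export
genome <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) {
    abort("chromosome names must be unique")
  }
  if (length(chrom) != length(length) || any(!is.finite(length)) || any(length < 1)) {
    abort("chromosome lengths must be finite, >= 1, one per chromosome")
  }
  tibble::tibble(chrom = chrom, length = length)
}

chrom_length <- function(genome, chrom) {
  genome$length[match(chrom, genome$chrom)]
}

#' Tile a genome into fixed-width bins
#'
#' Bins are 0-based half-open, non-overlapping, and tile each chromosome left
#' to right. The terminal bin of a chromosome may be truncated; it is kept and
#' can be identified by `end - start < bin_size`.
#'
#' @param genome A genome tibble from [genome()].
#' @param bin_size Bin width in bp (positive integer).
#' @return A tibble with columns `chrom`, `start`, `end` and `bin` (0-based
#'   index within chromosome), ordered by genome chromosome order then start.
#' @export
genome_bins <- function(genome, bin_size) {
  stopifnot(is.numeric(bin_size), bin_size >= 1)
  purrr::map2_dfr(genome$chrom, genome$length, function(ch, len) {
    starts <- seq(0, len - 1, by = bin_size)
    tibble::tibble(
      chrom = ch,
      start = starts,
      end = pmin(starts + bin_size, len),
      bin = seq_along(starts) - 1L
    )
  })
}

#' Create an empty bin track over a genome
#'
#' A bin track is a tibble of genome bins carrying one numeric `value` per
#' bin; `NA` marks missing bins (masked or no data).
#'
#' @inheritParams genome_bins
#' @param value Initial value for every bin (default `NA_real_`).
#' @return A bin-track tibble with columns `chrom`, `start`, `end`, `value`.
#' @export
bin_track <- function(genome, bin_size, value = NA_real_) {
  bins <- genome_bins(genome, bin_size)
  bins$bin <- NULL
  bins$value <- as.numeric(value)
  bins
}

track_bin_size <- function(track) {
  max(track$end - track$start)
}

assert_same_bins <- function(x, y) {
  if (nrow(x) != nrow(y) ||
      !identical(x$chrom, y$chrom) ||
      !identical(x$start, y$start)) {
    abort("tracks must share the same genome and binning")
  }
  invisible(TRUE)
}

validate_intervals <- function(x, genome = NULL) {
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(x))) {
    abort("interval table needs columns chrom, start, end")
  }
  bad <- which(!(x$start < x$end) | x$start < 0)
  if (length(bad)) {
    abort(paste0("invalid interval (need 0 <= start < end) at row ", bad[1]))
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(x$chrom), genome$chrom)
    if (length(unknown)) {
      abort(paste0("intervals on unknown chromosome(s): ",
                   paste(unknown, collapse = ", ")))
    }
    len <- chrom_length(genome, x$chrom)
    if (any(x$end > len)) {
      abort("interval end exceeds chromosome length")
    }
  }
  invisible(TRUE)
}

sort_intervals <- function(x, genome = NULL) {
  key <- if (is.null(genome)) x$chrom else
    factor(x$chrom, levels = genome$chrom)
  x[order(key, x$start, x$end), , drop = FALSE]
}
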