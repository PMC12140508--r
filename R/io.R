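#' Read a BED or SEACR-BED file into an interval tibble
#'
#' Coordinates are 0-based half-open (BED convention). The SEACR dialect
#' (6 columns: chrom, start, end, total signal, max signal, max-signal region)
#' maps its total-signal column to `score`.
#'
#' @param path Path to a tab-separated BED-like file without header.
#' @param format `"bed"` (3-6 columns: chrom, start, end, name, score,
#'   strand) or `"seacr"`.
#' @param genome Optional genome tibble; when given, intervals are validated
#'   against chromosome names and lengths.
#' @return A sorted interval tibble with columns `chrom`, `start`, `end` and,
#'   when present, `name`, `score`, `strand`.
#' @export
read_intervals <- function(path, format = c("bed", "seacr"), genome = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  min_cols <- if (format == "seacr") 6L else 3L
  bad <- which(nf < min_cols)
  if (length(bad)) {
    abort(paste0("malformed line ", bad[1], " in ", path,
                 ": expected >= ", min_cols, " tab-separated fields"))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  start <- suppressWarnings(as.numeric(col(2)))
  end <- suppressWarnings(as.numeric(col(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    abort(paste0("malformed line ", bad[1], ": non-numeric coordinates"))
  }
  bad <- which(end <= start | start < 0)
  if (length(bad)) {
    abort(paste0("malformed line ", bad[1], ": need 0 <= start < end"))
  }
  out <- tibble::tibble(chrom = col(1), start = start, end = end)
  if (format == "seacr") {
    out$score <- suppressWarnings(as.numeric(col(4)))
  } else {
    if (all(nf >= 4)) out$name <- col(4)
    if (all(nf >= 5)) out$score <- suppressWarnings(as.numeric(col(5)))
    if (all(nf >= 6)) {
      strand <- col(6)
      if (!all(strand %in% c("+", "-", "."))) {
        abort("strand column must be '+', '-' or '.'")
      }
      out$strand <- strand
    }
  }
  validate_intervals(out, genome)
  sort_intervals(out, genome)
}

#' Write an interval tibble as BED
#'
#' Emits as many of the optional BED columns (`name`, `score`, `strand`) as
#' the tibble carries, in that order, filling `name` with "." when `score` or
#' `strand` require it.
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_intervals <- function(x, path) {
  validate_intervals(x)
  cols <- list(x$chrom, format_coord(x$start), format_coord(x$end))
  has <- intersect(c("name", "score", "strand"), names(x))
  if (length(has)) {
    if ("name" %in% has || length(has)) {
      cols <- c(cols, list(if ("name" %in% names(x)) x$name else rep(".", nrow(x))))
    }
    if (any(c("score", "strand") %in% has)) {
      cols <- c(cols, list(if ("score" %in% names(x)) format_signal(x$score) else rep("0", nrow(x))))
    }
    if ("strand" %in% has) cols <- c(cols, list(x$strand))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

format_signal <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
}

#' Write a bin track as bedGraph
#'
#' One line per non-missing bin, four tab-separated columns, values at full
#' double precision so that a read-back reproduces them exactly.
#'
#' @param track Bin-track tibble (`chrom`, `start`, `end`, `value`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  keep <- !is.na(track$value)
  t2 <- track[keep, , drop = FALSE]
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(paste0("cannot open for writing: ", path))
  })
  on.exit(close(con))
  writeLines(paste(t2$chrom, format_coord(t2$start), format_coord(t2$end),
                   format_signal(t2$value), sep = "\t"), con)
  invisible(path)
}

#' Read a bedGraph file back into a bin track
#'
#' Bins absent from the file are returned as missing (`NA`).
#'
#' @param path bedGraph path.
#' @param genome Genome tibble the track is defined on.
#' @param bin_size Bin width in bp of the track grid.
#' @return A bin-track tibble covering the whole genome.
#' @export
read_bedgraph <- function(path, genome, bin_size) {
  x <- read_intervals(path, "bed", genome = genome)
  names(x)[names(x) == "name"] <- "value"
  x$value <- as.numeric(x$value)
  out <- bin_track(genome, bin_size)
  key_out <- paste(out$chrom, out$start)
  key_in <- paste(x$chrom, x$start)
  idx <- match(key_in, key_out)
  if (anyNA(idx)) abort("bedGraph lines do not align to the bin grid")
  out$value[idx] <- x$value
  out
}

#' Count fragments per genomic bin
#'
#' Each fragment is assigned to exactly one bin by its midpoint
#' `floor((start + end) / 2)`; a midpoint falling on a bin boundary belongs to
#' the right-hand bin (half-open rule). Counts are therefore conserved:
#' the per-bin values sum to the number of fragments.
#'
#' @param fragments Interval tibble of fragments.
#' @param genome Genome tibble.
#' @param bin_size Bin width in bp.
#' @return A bin-track tibble whose `value` is the fragment count (0 for
#'   empty bins).
#' @export
bin_fragments <- function(fragments, genome, bin_size) {
  validate_intervals(fragments, genome)
  out <- bin_track(genome, bin_size, value = 0)
  if (nrow(fragments) == 0) return(out)
  mid <- (fragments$start + fragments$end) %/% 2
  bin <- mid %/% bin_size
  key <- paste(fragments$chrom, bin * bin_size)
  key_out <- paste(out$chrom, out$start)
  idx <- match(key, key_out)
  if (anyNA(idx)) abort("fragment midpoint outside genome bins")
  tab <- tabulate(idx, nbins = nrow(out))
  out$value <- as.numeric(tab)
  out
}
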