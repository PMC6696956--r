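#' Coverage track
#'
#' Dense per-position sequencing depth over one replicon. Position `i` of
#' `depth` is genome position `i - 1` in 0-based coordinates (or bin
#' `i - 1` when `bin > 1`).
#'
#' @param chrom replicon name.
#' @param depth numeric vector of non-negative depths.
#' @param bin bin width in bp represented by each element (default 1).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(chrom, depth, bin = 1L) {
  if (!is.character(chrom) || length(chrom) != 1L) {
    stop2("chrom must be a single string")
  }
  if (!is.numeric(depth) || length(depth) == 0L) {
    stop2("depth must be a non-empty numeric vector")
  }
  if (anyNA(depth) || any(depth < 0)) stop2("depths must be non-negative")
  assert_scalar_number(bin, "bin", min = 1)
  structure(list(chrom = chrom, depth = as.numeric(depth),
                 length = length(depth), bin = as.integer(bin)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s: %s positions (bin %d bp), mean depth %.2f\n",
              x$chrom, format(x$length, big.mark = ","), x$bin,
              mean(x$depth)))
  invisible(x)
}

#' Read a bedGraph-style coverage file
#'
#' Four tab-separated columns (chrom, start, end, depth), 0-based half-open,
#' sorted and non-overlapping. The dense per-base track is reconstructed;
#' gaps between intervals are filled with depth 0.
#'
#' @param path path to the bedGraph file.
#' @param bin optional read-time binning width in bp; depths are averaged
#'   within bins (default 1 = per base).
#' @return A [coverage_track()].
#' @export
read_coverage <- function(path, bin = 1L) {
  if (!file.exists(path)) stop2("file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, col.names =
                            c("chrom", "start", "end", "depth"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  if (nrow(df) == 0L) stop2("empty coverage file: ", path)
  if (length(unique(df$chrom)) > 1L) {
    stop2("coverage file spans multiple replicons; one track per file")
  }
  if (any(df$depth < 0)) stop2("negative depth values")
  if (any(df$end <= df$start)) stop2("empty or inverted intervals")
  if (is.unsorted(df$start, strictly = TRUE)) {
    stop2("intervals must be sorted by start position")
  }
  if (nrow(df) > 1L && any(df$start[-1] < df$end[-nrow(df)])) {
    stop2("overlapping intervals")
  }
  depth <- numeric(max(df$end))
  for (i in seq_len(nrow(df))) {
    depth[(df$start[i] + 1):df$end[i]] <- df$depth[i]
  }
  if (bin > 1L) {
    grp <- ceiling(seq_along(depth) / bin)
    depth <- as.numeric(tapply(depth, grp, mean))
  }
  coverage_track(df$chrom[1], depth, bin = bin)
}

#' Write a coverage track as bedGraph
#'
#' Constant-depth runs are collapsed to single intervals; the round trip
#' through [read_coverage()] reproduces the dense track exactly (for
#' per-base tracks).
#'
#' @param track a [coverage_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$bin != 1L) stop2("only per-base tracks can be written")
  r <- rle(track$depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  lines <- sprintf("%s\t%s\t%s\t%s", track$chrom,
                   format(starts, scientific = FALSE, trim = TRUE),
                   format(ends, scientific = FALSE, trim = TRUE),
                   format(r$values, scientific = FALSE, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}
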