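#' Prophage region
#'
#' A chromosomal interval in 0-based half-open coordinates, optionally
#' carrying the attachment-site core sequence shared by its two flanks.
#'
#' @param chrom replicon name.
#' @param start 0-based start (inclusive).
#' @param end end (exclusive); must exceed `start`.
#' @param name region name (e.g. `"VNP1"`).
#' @param att_core optional DNA string: the att core present as a direct
#'   repeat at both region flanks.
#' @return An object of class `prophage_region`.
#' @export
prophage_region <- function(chrom, start, end, name = NA_character_,
                            att_core = NULL) {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom)) {
    stop2("chrom must be a non-empty string")
  }
  assert_scalar_number(start, "start", min = 0)
  assert_scalar_number(end, "end")
  if (start != floor(start) || end != floor(end)) {
    stop2("coordinates must be integers")
  }
  if (end <= start) {
    stop2("end (", end, ") must be > start (", start, ")")
  }
  if (!is.null(att_core)) assert_dna_string(att_core, "att_core")
  structure(list(chrom = chrom, start = as.numeric(start),
                 end = as.numeric(end), name = as.character(name),
                 att_core = att_core),
            class = "prophage_region")
}

#' @export
print.prophage_region <- function(x, ...) {
  cat(sprintf("<prophage_region> %s %s:%s-%s (%s bp)%s\n",
              ifelse(is.na(x$name), "", x$name), x$chrom,
              format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE),
              format(x$end - x$start, big.mark = ","),
              if (!is.null(x$att_core)) paste0(" core=", x$att_core) else ""))
  invisible(x)
}

#' Read prophage regions from a BED-style file
#'
#' Tab-separated, 3+ columns, 0-based half-open coordinates; an optional
#' 4th column is the region name. Lines failing the interval invariants
#' (`end > start`, integer coordinates) are an error.
#'
#' @param path path to the BED file.
#' @return A list of [prophage_region()] objects; empty list for an empty
#'   file.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop2("line ", i, ": fewer than 3 columns")
    if (!grepl("^[0-9]+$", f[2]) || !grepl("^[0-9]+$", f[3])) {
      stop2("line ", i, ": non-integer coordinates '", f[2], "', '", f[3], "'")
    }
    start <- as.numeric(f[2]); end <- as.numeric(f[3])
    if (end <= start) stop2("line ", i, ": end (", end, ") <= start (", start, ")")
    prophage_region(f[1], start, end,
                    name = if (length(f) >= 4L) f[4] else NA_character_)
  })
}

#' Write prophage regions to a BED-style file
#'
#' @param regions list of [prophage_region()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  if (inherits(regions, "prophage_region")) regions <- list(regions)
  lines <- vapply(regions, function(r) {
    base <- sprintf("%s\t%s\t%s", r$chrom,
                    format(r$start, scientific = FALSE),
                    format(r$end, scientific = FALSE))
    if (!is.na(r$name)) paste0(base, "\t", r$name) else base
  }, "")
  writeLines(lines, path)
  invisible(path)
}
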