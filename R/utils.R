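`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 allow_na = FALSE) {
  if (allow_na && length(x) == 1L && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop2(name, " must be a single non-missing number")
  }
  if (x < min || x > max) {
    stop2(name, " must be in [", min, ", ", max, "], got ", x)
  }
  invisible(x)
}

assert_dna_string <- function(x, name, allow_n = TRUE) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop2(name, " must be a non-empty DNA string")
  }
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- regexpr(pat, x)
  if (bad > 0L) {
    stop2(name, " contains illegal character '", substr(x, bad, bad),
          "' at position ", bad)
  }
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' Thin character-string wrapper around [Biostrings::reverseComplement()].
#'
#' @param x DNA string over `{A,C,G,T,N}`.
#' @return The reverse complement, as a character string.
#' @export
revcomp <- function(x) {
  assert_dna_string(x, "x")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Convert between printed and internal genome coordinates
#'
#' Genome papers print 1-based inclusive positions; internally this package
#' uses 0-based half-open intervals. The two converters are mutual inverses.
#'
#' @param start,end interval bounds in the source convention.
#' @return A list with `start` and `end` in the target convention.
#' @export
printed_to_internal <- function(start, end) {
  assert_scalar_number(start, "start", min = 1)
  assert_scalar_number(end, "end", min = start)
  list(start = start - 1, end = end)
}

#' @rdname printed_to_internal
#' @export
internal_to_printed <- function(start, end) {
  assert_scalar_number(start, "start", min = 0)
  if (end <= start) stop2("end must be > start for a non-empty interval")
  list(start = start + 1, end = end)
}

# stderr logging with levels; threshold via options(prophagekit.verbosity)
log_msg <- function(level = c("info", "warn", "debug"), ...) {
  level <- match.arg(level)
  threshold <- getOption("prophagekit.verbosity", "info")
  ranks <- c(warn = 1, info = 2, debug = 3)
  if (ranks[[level]] <= ranks[[threshold]]) {
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
  }
  invisible(NULL)
}
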