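#' Attachment-site set
#'
#' The quartet of att-site core sequences involved in site-specific
#' recombination of a temperate phage: `attL`/`attR` flank the integrated
#' prophage; excision reconstitutes `attB` on the chromosome and places
#' `attP` on the excised circle. All present sequences share one length
#' (the core length). A crossover position `k` is the number of leading
#' core positions contributed by the donor site (0-based half-open
#' slicing, `0 <= k <= core_length`).
#'
#' @param attL,attR hybrid site cores flanking the prophage.
#' @param attB,attP optional reconstituted bacterial / phage site cores.
#' @param crossover_interval optional integer pair `c(kmin, kmax)` of
#'   crossover positions consistent with the observed attP.
#' @return An object of class `att_site_set`.
#' @export
att_site_set <- function(attL, attR, attB = NULL, attP = NULL,
                         crossover_interval = NULL) {
  assert_dna_string(attL, "attL")
  assert_dna_string(attR, "attR")
  n <- nchar(attL)
  for (nm in c("attR", "attB", "attP")) {
    s <- switch(nm, attR = attR, attB = attB, attP = attP)
    if (!is.null(s) && nchar(s) != n) {
      stop2(nm, " length (", nchar(s), ") differs from attL length (", n, ")")
    }
  }
  if (!is.null(attB)) assert_dna_string(attB, "attB")
  if (!is.null(attP)) assert_dna_string(attP, "attP")
  if (!is.null(crossover_interval)) {
    stopifnot(length(crossover_interval) == 2L,
              crossover_interval[1] >= 0, crossover_interval[2] <= n,
              crossover_interval[1] <= crossover_interval[2])
  }
  structure(list(attL = attL, attR = attR, attB = attB, attP = attP,
                 core_length = n, crossover_interval = crossover_interval),
            class = "att_site_set")
}

#' @export
print.att_site_set <- function(x, ...) {
  cat("<att_site_set> core length", x$core_length, "bp\n")
  for (nm in c("attL", "attR", "attB", "attP")) {
    if (!is.null(x[[nm]])) cat(sprintf("  %s %s\n", nm, x[[nm]]))
  }
  if (!is.null(x$crossover_interval)) {
    cat(sprintf("  crossover k in [%d, %d]\n",
                x$crossover_interval[1], x$crossover_interval[2]))
  }
  invisible(x)
}

# All common substrings of exactly length len between a and b, with their
# occurrence positions (1-based). Used by the binary search in find_att_core.
common_substrings <- function(a, b, len) {
  na <- nchar(a); nb <- nchar(b)
  if (len > na || len > nb || len < 1L) return(character(0))
  ka <- substring(a, 1:(na - len + 1), len:na)
  kb <- substring(b, 1:(nb - len + 1), len:nb)
  intersect(unique(ka), unique(kb))
}

find_occurrences <- function(hay, needle) {
  m <- gregexpr(needle, hay, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Find the att core of a prophage region as a flanking direct repeat
#'
#' Searches for the longest exact direct repeat with one copy near the
#' region start and one near the region end: the attachment-site core that
#' site-specific recombination duplicates at the two prophage--host
#' junctions. Candidate copies are taken from windows of `window` bp on
#' either side of each region boundary; ties among equally long repeats are
#' broken by proximity of the copy ends to the region boundaries, then by
#' leftmost position.
#'
#' @param genome a [genome_record()] (or DNA string).
#' @param region a [prophage_region()] inside the genome.
#' @param window search window half-width around each boundary (bp).
#' @param min_len minimum acceptable core length (bp).
#' @return A list of class `att_core_hit`: `found` (logical); when found,
#'   `core`, `core_length`, `left_start`/`right_start` (0-based genomic
#'   starts of the two copies) and `att`, an [att_site_set()] with
#'   `attL = attR = core`. No repeat of at least `min_len` is reported as
#'   `found = FALSE`, not as an error.
#' @export
find_att_core <- function(genome, region, window = 1000, min_len = 10) {
  seq <- if (inherits(genome, "genome_record")) genome$sequence else genome
  assert_dna_string(seq, "genome")
  stopifnot(inherits(region, "prophage_region"))
  L <- nchar(seq)
  if (region$end > L) stop2("region extends beyond the genome")
  if (window < min_len) stop2("window must be >= min_len")

  wa <- c(max(0, region$start - window), min(L, region$start + window))
  wb <- c(max(0, region$end - window), min(L, region$end + window))
  a <- substr(seq, wa[1] + 1, wa[2])
  b <- substr(seq, wb[1] + 1, wb[2])

  no_hit <- structure(list(found = FALSE, core = NULL, core_length = 0L,
                           left_start = NA_integer_, right_start = NA_integer_,
                           att = NULL), class = "att_core_hit")

  # A valid repeat needs two distinct genomic occurrences; candidate pairs
  # with identical genomic positions (possible when the windows overlap)
  # are rejected below.
  valid_at <- function(len) {
    for (s in common_substrings(a, b, len)) {
      pa <- wa[1] + find_occurrences(a, s) - 1L  # 0-based genomic
      pb <- wb[1] + find_occurrences(b, s) - 1L
      if (any(outer(pa, pb, `!=`))) return(TRUE)
    }
    FALSE
  }
  if (!valid_at(min_len)) return(no_hit)

  lo <- min_len                       # longest len with a valid repeat
  hi <- min(nchar(a), nchar(b))
  while (lo < hi) {
    mid <- ceiling((lo + hi) / 2)
    if (valid_at(mid)) lo <- mid else hi <- mid - 1L
  }
  len <- lo

  best <- NULL
  for (s in sort(common_substrings(a, b, len))) {
    pa <- wa[1] + find_occurrences(a, s) - 1L
    pb <- wb[1] + find_occurrences(b, s) - 1L
    for (i in pa) for (j in pb) {
      if (i == j) next
      # left copy should start at the region start, right copy end at its end
      cost <- abs(i - region$start) + abs((j + len) - region$end)
      cand <- list(core = s, i = i, j = j, cost = cost)
      if (is.null(best) || cost < best$cost ||
          (cost == best$cost && (i < best$i ||
                                 (i == best$i && j < best$j)))) {
        best <- cand
      }
    }
  }
  structure(list(found = TRUE, core = best$core, core_length = len,
                 left_start = best$i, right_start = best$j,
                 att = att_site_set(best$core, best$core)),
            class = "att_core_hit")
}

#' @export
print.att_core_hit <- function(x, ...) {
  if (!x$found) cat("<att_core_hit> no core found\n")
  else cat(sprintf("<att_core_hit> %d bp core %s at %d / %d\n",
                   x$core_length, x$core, x$left_start, x$right_start))
  invisible(x)
}

#' Reconstruct attB and attP from attL and attR at crossover k
#'
#' A single crossover after `k` leading positions swaps the tails of the
#' two hybrid sites: `attB = attL[0:k] + attR[k:]` and
#' `attP = attR[0:k] + attL[k:]` (0-based half-open slices). For every
#' position i the unordered pair `{attB[i], attP[i]}` equals
#' `{attL[i], attR[i]}` — recombination rearranges, never invents, bases.
#'
#' @param attL,attR equal-length core sequences.
#' @param k crossover position, `0 <= k <= nchar(attL)`.
#' @return A list with `attB` and `attP`.
#' @export
recombine <- function(attL, attR, k) {
  assert_dna_string(attL, "attL")
  assert_dna_string(attR, "attR")
  n <- nchar(attL)
  if (nchar(attR) != n) stop2("attL and attR lengths differ")
  assert_scalar_number(k, "k", min = 0, max = n)
  if (k != floor(k)) stop2("k must be an integer")
  list(attB = paste0(substr(attL, 1, k), substr(attR, k + 1, n)),
       attP = paste0(substr(attR, 1, k), substr(attL, k + 1, n)))
}

#' Infer the crossover interval consistent with an observed attP
#'
#' Computes `{k : attR[0:k] + attL[k:] == attP}`. Under the
#' single-crossover model this set is always a contiguous interval
#' (the prefix condition is downward-closed in k, the suffix condition
#' upward-closed). An empty result means no single crossover explains the
#' observed attP.
#'
#' @param attL,attR,attP equal-length core sequences.
#' @return Integer vector `c(kmin, kmax)`, or `integer(0)` when no k works.
#' @export
infer_crossover_interval <- function(attL, attR, attP) {
  for (s in list(attL, attR, attP)) assert_dna_string(s, "att site")
  n <- nchar(attL)
  if (nchar(attR) != n || nchar(attP) != n) stop2("att site lengths differ")
  ok <- vapply(0:n, function(k) {
    paste0(substr(attR, 1, k), substr(attL, k + 1, n)) == attP
  }, logical(1))
  ks <- (0:n)[ok]
  if (length(ks) == 0L) return(integer(0))
  c(min(ks), max(ks))
}

#' Excise a prophage from a genome
#'
#' Models prophage excision by site-specific recombination between the
#' attL and attR cores at the region flanks: the host chromosome retains a
#' single reconstituted `attB` core at the junction, and the phage leaves
#' as a circle whose junction core is `attP`. The returned
#' `phage_circle$sequence` is the full excised interval (attL core,
#' internal phage sequence, attR core) as a linear string; on
#' circularisation the two terminal cores collapse into the single attP
#' junction. Hence the length bookkeeping
#' `nchar(host) + nchar(circle) = nchar(genome) + core_length`.
#'
#' @param genome a [genome_record()] or DNA string.
#' @param region the prophage interval, spanning from the start of the
#'   attL core to the end of the attR core (0-based half-open).
#' @param att an [att_site_set()] with `attL` and `attR`.
#' @param k crossover position (default: midpoint of the core).
#' @return A list with `host` (a `genome_record`), `circle` (class
#'   `phage_circle`: `sequence`, `core_length`, `attP`, `k`) and `att`,
#'   the input att set completed with `attB`/`attP`.
#' @export
excise <- function(genome, region, att, k = NULL) {
  rec <- if (inherits(genome, "genome_record")) genome else
    genome_record("genome", genome)
  seq <- rec$sequence
  stopifnot(inherits(region, "prophage_region"), inherits(att, "att_site_set"))
  n <- att$core_length
  k <- k %||% (n %/% 2)
  assert_scalar_number(k, "k", min = 0, max = n)
  left <- substr(seq, region$start + 1, region$start + n)
  right <- substr(seq, region$end - n + 1, region$end)
  if (left != att$attL) {
    stop2("attL core not found at region start (saw ", left, ")")
  }
  if (right != att$attR) {
    stop2("attR core not found at region end (saw ", right, ")")
  }
  rc <- recombine(att$attL, att$attR, k)
  host_seq <- paste0(substr(seq, 1, region$start), rc$attB,
                     substr(seq, region$end + 1, nchar(seq)))
  circle_seq <- substr(seq, region$start + 1, region$end)
  att_out <- att_site_set(att$attL, att$attR, attB = rc$attB, attP = rc$attP)
  list(host = genome_record(paste0(rec$id, "_excised"), host_seq,
                            rec$description),
       circle = structure(list(sequence = circle_seq, core_length = n,
                               attP = rc$attP, k = as.integer(k)),
                          class = "phage_circle"),
       att = att_out)
}

#' @export
print.phage_circle <- function(x, ...) {
  cat(sprintf("<phage_circle> %s bp (linearised excised interval), %d bp core, attP %s\n",
              format(nchar(x$sequence), big.mark = ","), x$core_length,
              x$attP))
  invisible(x)
}

#' Integrate a phage circle at an attB site
#'
#' Inverse of [excise()]: recombination between the chromosomal attB core
#' and the circle's attP junction re-creates attL and attR at the two new
#' junctions. The host sequence at `attB_position` must equal the attB
#' core implied by the circle's terminal cores and `k`; with identical
#' cores (and for any circle produced by [excise()] with the same `k`)
#' `integrate` is the exact inverse of `excise`.
#'
#' @param host_genome a [genome_record()] or DNA string carrying attB.
#' @param attB_position 0-based start of the attB core in the host.
#' @param phage_circle a `phage_circle` from [excise()] (or a list with
#'   `sequence` and `core_length`).
#' @param k crossover position (default: the circle's recorded `k`).
#' @return A `genome_record` with the prophage re-integrated.
#' @export
integrate_phage <- function(host_genome, attB_position, phage_circle,
                            k = NULL) {
  rec <- if (inherits(host_genome, "genome_record")) host_genome else
    genome_record("host", host_genome)
  seq <- rec$sequence
  n <- phage_circle$core_length
  k <- k %||% phage_circle$k %||% (n %/% 2)
  assert_scalar_number(k, "k", min = 0, max = n)
  circ <- phage_circle$sequence
  if (nchar(circ) < 2 * n) stop2("circle shorter than two core copies")
  attL_c <- substr(circ, 1, n)
  attR_c <- substr(circ, nchar(circ) - n + 1, nchar(circ))
  # the circle's circular junction core, reading across the linear ends
  attP <- paste0(substr(attR_c, 1, k), substr(attL_c, k + 1, n))
  attB_expected <- paste0(substr(attL_c, 1, k), substr(attR_c, k + 1, n))
  assert_scalar_number(attB_position, "attB_position", min = 0,
                       max = nchar(seq) - n)
  attB_host <- substr(seq, attB_position + 1, attB_position + n)
  if (attB_host != attB_expected) {
    stop2("attB core not found at position ", attB_position,
          " (expected ", attB_expected, ", saw ", attB_host, ")")
  }
  # attB x attP -> attL, attR; the circle interior is re-inserted between them
  attL_new <- paste0(substr(attB_host, 1, k), substr(attP, k + 1, n))
  attR_new <- paste0(substr(attP, 1, k), substr(attB_host, k + 1, n))
  inner <- substr(circ, n + 1, nchar(circ) - n)
  genome_record(sub("_excised$", "", rec$id),
                paste0(substr(seq, 1, attB_position), attL_new, inner,
                       attR_new,
                       substr(seq, attB_position + n + 1, nchar(seq))),
                rec$description)
}

#' Interval length under an explicit coordinate convention
#'
#' Printed genome coordinates are 1-based inclusive, for which the length
#' is `end - start + 1`; half-open (or "span") arithmetic gives
#' `end - start`. Published interval sizes mix both conventions, so the
#' convention is always an explicit argument here.
#'
#' @param start,end interval bounds, `end >= start`.
#' @param convention `"inclusive"` or `"end_minus_start"`.
#' @return Length in bp.
#' @export
region_length <- function(start, end,
                          convention = c("inclusive", "end_minus_start")) {
  convention <- match.arg(convention)
  assert_scalar_number(start, "start")
  assert_scalar_number(end, "end")
  if (end < start) stop2("end (", end, ") < start (", start, ")")
  if (convention == "inclusive") end - start + 1 else end - start
}
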