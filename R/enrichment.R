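#' Estimate background depth of a coverage track
#'
#' Robust background for supernatant sequencing: the median (default)
#' depth over all positions outside the excluded regions, which the
#' enriched prophage regions themselves are expected to be.
#'
#' @param track a [coverage_track()].
#' @param exclude_regions list of [prophage_region()]s to mask out.
#' @param stat `"median"` (robust, default) or `"mean"`.
#' @return Background depth (reads).
#' @export
estimate_background <- function(track, exclude_regions = list(),
                                stat = c("median", "mean")) {
  stopifnot(inherits(track, "coverage_track"))
  stat <- match.arg(stat)
  if (inherits(exclude_regions, "prophage_region")) {
    exclude_regions <- list(exclude_regions)
  }
  keep <- rep(TRUE, track$length)
  for (r in exclude_regions) {
    keep[max(1, r$start + 1):min(track$length, r$end)] <- FALSE
  }
  if (!any(keep)) stop2("all positions excluded; cannot estimate background")
  if (sum(!keep) / track$length >= 0.9) {
    stop2("excluded regions cover >= 90% of the track")
  }
  if (stat == "median") stats::median(track$depth[keep])
  else mean(track$depth[keep])
}

#' Fold enrichment of a region over background
#'
#' @param track a [coverage_track()].
#' @param region a [prophage_region()].
#' @param background positive background depth (see
#'   [estimate_background()]).
#' @return Mean in-region depth divided by background (dimensionless).
#' @export
fold_enrichment <- function(track, region, background) {
  stopifnot(inherits(track, "coverage_track"),
            inherits(region, "prophage_region"))
  assert_scalar_number(background, "background", min = 1e-12)
  if (region$end > track$length) stop2("region extends beyond the track")
  idx <- (region$start + 1):region$end
  if (length(idx) == 0L) stop2("zero-length region")
  mean(track$depth[idx]) / background
}

# centered running mean, odd window, truncated at the edges
smooth_depth <- function(depth, window = 501L) {
  if (window <= 1L) return(depth)
  if (window %% 2L == 0L) stop2("smoothing window must be odd")
  h <- (window - 1L) / 2L
  n <- length(depth)
  cs <- cumsum(c(0, depth))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect enriched segments de novo
#'
#' Localises induced-prophage blocks in a supernatant coverage track
#' without prior region annotation: after smoothing (centered running
#' mean), maximal runs of positions with depth at least
#' `min_fold * background` are extracted, runs separated by less than
#' `gap` bp are merged, and runs shorter than `min_len` are dropped.
#'
#' @param track a [coverage_track()] (per-base).
#' @param background background depth; estimated from the whole track
#'   (median) when `NULL`.
#' @param min_fold detection threshold, > 1 (default 3).
#' @param min_len minimum segment length in bp (default 5000).
#' @param window smoothing window, odd, in bp (default 501).
#' @param gap merge runs separated by less than this many bp (default
#'   1000).
#' @return A list of [prophage_region()]s (possibly empty).
#' @export
detect_enriched_segments <- function(track, background = NULL, min_fold = 3,
                                     min_len = 5000, window = 501L,
                                     gap = 1000L) {
  stopifnot(inherits(track, "coverage_track"))
  if (min_fold <= 1) stop2("min_fold must be > 1")
  if (min_len < 1) stop2("min_len must be >= 1")
  background <- background %||% estimate_background(track)
  sm <- smooth_depth(track$depth, window)
  above <- sm >= min_fold * background
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths            # 0-based
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(seg) == 0L) return(list())
  merged <- seg[1, , drop = FALSE]
  for (i in seq_len(nrow(seg))[-1]) {
    if (seg$start[i] - merged$end[nrow(merged)] < gap) {
      merged$end[nrow(merged)] <- seg$end[i]
    } else {
      merged <- rbind(merged, seg[i, ])
    }
  }
  merged <- merged[merged$end - merged$start >= min_len, , drop = FALSE]
  lapply(seq_len(nrow(merged)), function(i) {
    prophage_region(track$chrom, merged$start[i], merged$end[i],
                    name = paste0("segment_", i))
  })
}

# best two-segment piecewise-constant fit over x: the split s (1..n-1,
# meaning positions 1..s vs s+1..n) minimising total squared error.
step_fit_split <- function(x) {
  n <- length(x)
  if (n < 2L) return(list(split = NA_integer_, degenerate = TRUE))
  if (max(x) - min(x) < 1e-12) {
    return(list(split = NA_integer_, degenerate = TRUE))
  }
  cs <- cumsum(x)
  s <- seq_len(n - 1L)
  # SSE(s) = sum(x^2) - S1^2/s - S2^2/(n-s); minimise by maximising the gain
  gain <- cs[s]^2 / s + (cs[n] - cs[s])^2 / (n - s)
  list(split = which.max(gain), degenerate = FALSE)
}

#' Refine region boundaries by step fitting
#'
#' Each boundary is re-placed at the change point maximising the
#' two-segment piecewise-constant fit (equivalently minimising the total
#' squared error) of the raw depth within `search_window` bp of the
#' original boundary. A window with no step (constant signal) is flagged
#' degenerate and the boundary left unchanged.
#'
#' @param track a [coverage_track()] (per-base).
#' @param region a [prophage_region()] with approximate boundaries.
#' @param search_window half-width of the search window in bp.
#' @return A list: `start`, `end` (refined, 0-based half-open) and
#'   `degenerate` (logical pair, start/end).
#' @export
refine_boundaries <- function(track, region, search_window = 2000L) {
  stopifnot(inherits(track, "coverage_track"),
            inherits(region, "prophage_region"))
  refine_one <- function(boundary) {
    lo <- boundary - search_window
    hi <- boundary + search_window
    if (lo < 0 || hi > track$length) {
      stop2("search window extends beyond the track")
    }
    x <- track$depth[(lo + 1):hi]
    fit <- step_fit_split(x)
    if (fit$degenerate) list(pos = boundary, degenerate = TRUE)
    else list(pos = lo + fit$split, degenerate = FALSE)
  }
  s <- refine_one(region$start)
  e <- refine_one(region$end)
  list(start = s$pos, end = e$pos,
       degenerate = c(start = s$degenerate, end = e$degenerate))
}

#' Enrichment report for a region
#'
#' @param track a [coverage_track()].
#' @param region a [prophage_region()].
#' @param background background depth; estimated with the region excluded
#'   when `NULL`.
#' @param refine refine boundaries by step fitting first?
#' @return A list of class `enrichment_report`: `region`, `mean_depth`,
#'   `background`, `fold_enrichment`, `refined_start`, `refined_end`.
#' @export
enrichment_report <- function(track, region, background = NULL,
                              refine = FALSE) {
  background <- background %||%
    estimate_background(track, exclude_regions = list(region))
  refined <- if (refine) refine_boundaries(track, region) else
    list(start = region$start, end = region$end)
  reg <- prophage_region(region$chrom, refined$start, refined$end,
                         name = region$name, att_core = region$att_core)
  fold <- fold_enrichment(track, reg, background)
  structure(list(region = reg,
                 mean_depth = fold * background,
                 background = background,
                 fold_enrichment = fold,
                 refined_start = refined$start, refined_end = refined$end),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("<enrichment_report> %s [%s, %s): mean %.2f / background %.2f = %.2f-fold\n",
              x$region$name, format(x$refined_start, scientific = FALSE),
              format(x$refined_end, scientific = FALSE), x$mean_depth,
              x$background, x$fold_enrichment))
  invisible(x)
}

#' Ratio of enrichment between two prophages
#'
#' Phage DNA in the supernatant adds to, rather than replaces, the
#' residual host background, so the amount of released phage DNA is
#' proportional to the excess enrichment `fold - 1`; the default ratio is
#' `(fold_a - 1) / (fold_b - 1)`. Set `method = "fold"` for the plain
#' fold ratio.
#'
#' @param report_a,report_b [enrichment_report()]s (or bare fold values).
#' @param method `"excess"` (default) or `"fold"`.
#' @return The dimensionless ratio, or `NA` with a warning when the
#'   denominator's enrichment is not above background (undefined).
#' @export
enrichment_ratio <- function(report_a, report_b,
                             method = c("excess", "fold")) {
  method <- match.arg(method)
  fa <- if (inherits(report_a, "enrichment_report"))
    report_a$fold_enrichment else report_a
  fb <- if (inherits(report_b, "enrichment_report"))
    report_b$fold_enrichment else report_b
  if (fa <= 0 || fb <= 0) stop2("fold enrichments must be positive")
  if (method == "fold") return(fa / fb)
  if (fb <= 1) {
    warning("denominator fold <= 1: excess ratio undefined", call. = FALSE)
    return(NA_real_)
  }
  (fa - 1) / (fb - 1)
}
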