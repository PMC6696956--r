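#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(concentration) over a serial
#' dilution series, using every replicate point (not per-level means).
#' The amplification efficiency follows from the slope as
#' `E = 10^(-1/slope) - 1` (a slope of -3.32 cycles per decade is perfect
#' doubling, E = 1). Curves with `r2 <= r2_threshold` are returned as
#' rejected, carrying their values; a non-negative slope is an error.
#'
#' @param standards data frame with columns `known_conc` (ng/ul) and `ct`
#'   (cycles), or a [qpcr_plate()] whose standard wells are used.
#' @param r2_threshold acceptance bound on R^2 (default 0.95).
#' @return An object of class `standard_curve`: `slope`, `intercept`,
#'   `r2`, `efficiency`, `accepted`, `n_points`.
#' @export
fit_standard_curve <- function(standards, r2_threshold = 0.95) {
  if (inherits(standards, "qpcr_plate")) standards <- plate_standards(standards)
  stopifnot(all(c("known_conc", "ct") %in% names(standards)))
  df <- standards[!is.na(standards$ct), c("known_conc", "ct")]
  if (any(df$known_conc <= 0)) stop2("standard concentrations must be positive")
  if (length(unique(df$known_conc)) < 3L) {
    stop2("need at least 3 distinct standard concentrations")
  }
  fit <- stats::lm(ct ~ log10(known_conc), data = df)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop2("standard-curve slope must be negative, got ", slope)
  sst <- sum((df$ct - mean(df$ct))^2)
  r2 <- if (sst <= 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2,
                 efficiency = 10^(-1 / slope) - 1,
                 accepted = r2 > r2_threshold,
                 n_points = nrow(df)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> slope %.4f, intercept %.2f, R2 %.4f, efficiency %.1f%%%s\n",
              x$slope, x$intercept, x$r2, 100 * x$efficiency,
              if (x$accepted) "" else " [REJECTED]"))
  invisible(x)
}

#' Predicted Ct at a given concentration
#'
#' @param curve a [fit_standard_curve()] result.
#' @param conc concentration(s) in ng/ul.
#' @return Ct in cycles.
#' @export
curve_predict <- function(curve, conc) {
  stopifnot(inherits(curve, "standard_curve"))
  curve$intercept + curve$slope * log10(conc)
}

#' Convert Ct values to a DNA amount via a standard curve
#'
#' Each replicate Ct is inverted to the concentration scale
#' (`10^((ct - intercept)/slope)`) and replicates are averaged there
#' (equivalent to a geometric mean on the Ct scale). Missing Ct values
#' are the no-amplification sentinel and contribute amount 0; the count
#' of such wells is attached as attribute `n_no_amp`.
#'
#' @param ct numeric vector of replicate Ct values (NA = no
#'   amplification).
#' @param curve an accepted [fit_standard_curve()] result.
#' @return Amount in ng/ul (scalar), with attribute `n_no_amp`.
#' @export
quantify <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!curve$accepted) {
    stop2("standard curve rejected (R2 = ", signif(curve$r2, 4),
          "); refusing to quantify")
  }
  if (length(ct) == 0L) stop2("no Ct values")
  amounts <- ifelse(is.na(ct), 0, 10^((ct - curve$intercept) / curve$slope))
  structure(mean(amounts), n_no_amp = sum(is.na(ct)))
}

#' Normalize a DNA amount to the genomic reference
#'
#' `N(DNA_X) = amount_X / amount_reference`: dividing by the amount of a
#' single-copy genomic control gene (thymidine kinase) cancels
#' input-mass differences between samples, which is the purpose of
#' normalization.
#'
#' @param amount_target,amount_reference amounts in ng/ul;
#'   `amount_reference > 0`.
#' @return Dimensionless normalized amount N.
#' @export
normalize_amount <- function(amount_target, amount_reference) {
  if (any(amount_reference <= 0)) stop2("reference amount must be positive")
  if (any(amount_target < 0)) stop2("amounts must be non-negative")
  as.numeric(amount_target) / as.numeric(amount_reference)
}

#' Spontaneous-prophage-induction fraction
#'
#' `SPI fraction (%) = 100 * N(sample) / N(control)` where the control is
#' the fully induced (prophage-free) genotype whose attB junction is
#' present in every chromosome — by construction the 100% level. Values
#' above 100% are flagged (attribute `exceeds_control`), never clamped.
#'
#' @param n_sample,n_control normalized DNA amounts
#'   (see [normalize_amount()]); `n_control > 0`.
#' @return SPI fraction in percent.
#' @export
spi_fraction <- function(n_sample, n_control) {
  if (any(n_control <= 0)) stop2("control amount must be positive")
  if (any(n_sample < 0)) stop2("sample amount must be non-negative")
  out <- 100 * as.numeric(n_sample) / as.numeric(n_control)
  if (any(out > 100)) attr(out, "exceeds_control") <- TRUE
  out
}

#' Deletion-strain to wild-type ratio
#'
#' `ratio (%) = 100 * N(sample) / N(WT control)`, the competitive-growth
#' read-out with the wild-type DNA level taken as 100%.
#'
#' @inheritParams spi_fraction
#' @param n_wt normalized amount of the wild-type control.
#' @return Ratio in percent.
#' @export
strain_ratio <- function(n_sample, n_wt) {
  spi_fraction(n_sample, n_wt)
}

#' Phage-to-genome copy ratio
#'
#' Converts DNA amounts to molecule copy numbers via the amplicon's mass
#' (`copies = amount / (amplicon_len * mass_per_bp)`) and divides phage
#' circle copies by bacterial genome copies; the per-bp mass constant
#' cancels in the ratio.
#'
#' @param circle_amount,genome_amount amounts in ng/ul from circular-DNA
#'   and reference-gene targets.
#' @param circle_amplicon_len,ref_amplicon_len amplicon lengths in bp.
#' @return Copies of circular phage DNA per bacterial genome.
#' @export
phage_to_genome_ratio <- function(circle_amount, circle_amplicon_len,
                                  genome_amount, ref_amplicon_len) {
  assert_scalar_number(circle_amplicon_len, "circle_amplicon_len", min = 1)
  assert_scalar_number(ref_amplicon_len, "ref_amplicon_len", min = 1)
  if (any(circle_amount < 0) || any(genome_amount < 0)) {
    stop2("amounts must be non-negative")
  }
  genome_copies <- genome_amount / ref_amplicon_len
  if (any(genome_copies <= 0)) stop2("zero genome copies")
  (circle_amount / circle_amplicon_len) / genome_copies
}

#' Predict a PCR amplicon by exact primer matching
#'
#' Finds the unique product delimited by an exact match of the forward
#' primer and, downstream on the same strand, the reverse complement of
#' the reverse primer; both strands of the template are searched. The
#' product includes both primer sites.
#'
#' @param template a [genome_record()] or DNA string.
#' @param fwd_primer,rev_primer primer sequences (>= 15 nt), written 5'
#'   to 3'.
#' @param max_len maximum product length in bp (default 5000).
#' @return A list: `product` (sequence), `length` (bp), `start` (0-based
#'   on the matched strand) and `strand` (`"+"`/`"-"`). No product is an
#'   error, as is more than one (the ambiguity error lists the loci).
#' @export
predict_amplicon <- function(template, fwd_primer, rev_primer,
                             max_len = 5000L) {
  seq <- if (inherits(template, "genome_record")) template$sequence else
    template
  assert_dna_string(seq, "template")
  for (p in c(fwd_primer, rev_primer)) {
    assert_dna_string(p, "primer", allow_n = FALSE)
    if (nchar(p) < 15L) stop2("primers must be at least 15 nt")
  }
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    f_starts <- find_occurrences(s, toupper(fwd_primer))
    r_starts <- find_occurrences(s, revcomp(toupper(rev_primer)))
    for (f in f_starts) for (r in r_starts) {
      end <- r + nchar(rev_primer) - 1L
      len <- end - f + 1L
      if (r >= f && len <= max_len) {
        hits[[length(hits) + 1L]] <- list(
          product = substr(s, f, end), length = len,
          start = f - 1L, strand = strand)
      }
    }
  }
  if (length(hits) == 0L) stop2("no amplicon: primer sites not found")
  if (length(hits) > 1L) {
    loci <- vapply(hits, function(h)
      sprintf("%s:%d (%d bp)", h$strand, h$start, h$length), "")
    stop2("ambiguous amplification; products at: ",
          paste(loci, collapse = ", "))
  }
  hits[[1]]
}

#' Quantify every unknown well of a plate
#'
#' Fits the standard curve from the plate's standard wells (unless one is
#' supplied), inverts each (sample, target)'s replicate Cts to amounts,
#' and normalizes by that sample's `reference_tk` amount.
#'
#' @param plate a [qpcr_plate()].
#' @param curve optional pre-fitted [fit_standard_curve()] result.
#' @return A data frame with one row per (sample_id, target): `amount`
#'   (ng/ul) and `normalized` (N, `NA` where the sample lacks a reference
#'   target).
#' @export
quantify_plate <- function(plate, curve = NULL) {
  stopifnot(inherits(plate, "qpcr_plate"))
  curve <- curve %||% fit_standard_curve(plate)
  unk <- plate_unknowns(plate)
  if (nrow(unk) == 0L) stop2("plate has no unknown wells")
  key <- unique(unk[, c("sample_id", "target")])
  key$amount <- vapply(seq_len(nrow(key)), function(i) {
    cts <- unk$ct[unk$sample_id == key$sample_id[i] &
                  unk$target == key$target[i]]
    as.numeric(quantify(cts, curve))
  }, numeric(1))
  key$normalized <- NA_real_
  for (sid in unique(key$sample_id)) {
    ref <- key$amount[key$sample_id == sid & key$target == "reference_tk"]
    if (length(ref) == 1L && ref > 0) {
      rows <- key$sample_id == sid & key$target != "reference_tk"
      key$normalized[rows] <- normalize_amount(key$amount[rows], ref)
    }
  }
  rownames(key) <- NULL
  key
}
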