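#' Specify prophages to implant in a synthetic host genome
#'
#' Defaults emulate a mitomycin-C-induced culture of a host carrying two
#' prophages whose phage DNA release differs seven-fold: excess depth over
#' the supernatant background is `induced_fraction * burst_size` = 10x for
#' the first phage and 70x for the second (region means 11x and 71x
#' background).
#'
#' @param name,start,length,att_core,induced_fraction,burst_size vectors,
#'   one element per prophage: region name; 0-based start of the region
#'   (which spans attL core through attR core); interval length in bp
#'   including both core copies; att core sequence (>= 10 bp); induced
#'   fraction in `[0, 1]`; burst size (> 0).
#' @return A data frame, one row per prophage.
#' @export
prophage_spec <- function(name = c("VNP1", "VNP2"),
                          start = c(40000, 120000),
                          length = c(30000, 35000),
                          att_core = c("TAGATTTGTGTGGT",
                                       "CAGCCCACTTTTTTCTTCTTTGATTA"),
                          induced_fraction = c(0.1, 0.1),
                          burst_size = c(100, 700)) {
  data.frame(name = name, start = start, length = length,
             att_core = att_core, induced_fraction = induced_fraction,
             burst_size = burst_size, stringsAsFactors = FALSE)
}

random_dna <- function(n, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# If the bases at 0-based positions p1 and p2 are equal, resample the base
# at p2 so an implanted direct repeat cannot extend across them. Positions
# outside the sequence are ignored.
break_extension <- function(seq, p1, p2) {
  n <- nchar(seq)
  if (p1 < 0 || p2 < 0 || p1 >= n || p2 >= n) return(seq)
  b1 <- substr(seq, p1 + 1, p1 + 1)
  if (substr(seq, p2 + 1, p2 + 1) != b1) return(seq)
  repl <- sample(setdiff(c("A", "C", "G", "T"), b1), 1)
  paste0(substr(seq, 1, p2), repl, substr(seq, p2 + 2, n))
}

#' Generate a synthetic host genome with implanted prophages
#'
#' Background bases are i.i.d. at the requested GC content; each prophage
#' is implanted with an exact direct repeat of its att core at both region
#' flanks (the attL/attR cores left by integrase-mediated insertion). The
#' bases immediately outside each core copy are resampled where needed so
#' the implanted repeat is maximal — a repeat search recovers exactly the
#' implanted core, never a chance extension. The returned truth object
#' records everything downstream simulators need.
#'
#' @param length chromosome length in bp (default 200 kb, a desk-scale
#'   stand-in for a multi-Mb Vibrio chromosome).
#' @param regions_spec a [prophage_spec()] data frame; regions must be
#'   non-overlapping and keep >= 1 kb margins from the ends and each other.
#' @param gc background GC content in (0, 1).
#' @param seed integer seed.
#' @param background_depth,overdispersion,qpcr_noise_sd,spi_rate defaults
#'   recorded in the truth object for the downstream simulators:
#'   supernatant background depth (residual host gDNA), negative-binomial
#'   size parameter, qPCR cycle noise, and per-strain per-generation
#'   spontaneous-induction (lysis) probability.
#' @return A list of class `synthetic_truth`: `genome` ([genome_record()]),
#'   `regions` (list of [prophage_region()] with att cores),
#'   `induced_fraction`, `burst_size` (named vectors), plus the noise
#'   parameters above.
#' @export
generate_host_genome <- function(length = 200000,
                                 regions_spec = prophage_spec(),
                                 gc = 0.45, seed = 1L,
                                 background_depth = 10,
                                 overdispersion = 10,
                                 qpcr_noise_sd = 0.15,
                                 spi_rate = c(wt = 0.006, delta = 0)) {
  assert_scalar_number(gc, "gc", min = 1e-9, max = 1 - 1e-9)
  assert_scalar_number(length, "length", min = 1)
  rs <- regions_spec
  stopifnot(is.data.frame(rs), nrow(rs) >= 1L)
  if (any(nchar(rs$att_core) < 10L)) {
    stop2("att cores must be at least 10 bp")
  }
  if (any(rs$induced_fraction < 0 | rs$induced_fraction > 1)) {
    stop2("induced_fraction must be in [0, 1]")
  }
  if (any(rs$burst_size <= 0)) stop2("burst_size must be positive")
  rs <- rs[order(rs$start), , drop = FALSE]
  ends <- rs$start + rs$length
  margins <- c(rs$start, length) - c(0, ends)
  if (any(margins < 1000)) {
    stop2("regions must keep >= 1 kb margins from each other and the ends")
  }
  if (any(rs$length < 2 * nchar(rs$att_core) + 1)) {
    stop2("region shorter than its two att core copies")
  }

  set.seed(seed)
  pieces <- character(0)
  pos <- 0
  regions <- vector("list", nrow(rs))
  for (i in seq_len(nrow(rs))) {
    core <- rs$att_core[i]
    inner <- rs$length[i] - 2 * nchar(core)
    pieces <- c(pieces, random_dna(rs$start[i] - pos, gc),
                core, random_dna(inner, gc), core)
    pos <- rs$start[i] + rs$length[i]
    regions[[i]] <- prophage_region("chr1", rs$start[i], pos,
                                    name = rs$name[i], att_core = core)
  }
  pieces <- c(pieces, random_dna(length - pos, gc))
  seq <- paste(pieces, collapse = "")
  # make each implanted repeat maximal: the bases just outside the two
  # core copies must differ between copies, otherwise a repeat search
  # would (correctly) report a longer core than the one implanted
  for (i in seq_len(nrow(rs))) {
    cl <- nchar(rs$att_core[i])
    st <- rs$start[i]; en <- rs$start[i] + rs$length[i]
    seq <- break_extension(seq, st - 1, en - cl - 1)    # bases before copies
    seq <- break_extension(seq, st + cl, en)            # bases after copies
  }
  genome <- genome_record("chr1", seq,
                          "synthetic host chromosome")
  structure(list(genome = genome, regions = regions,
                 induced_fraction = stats::setNames(rs$induced_fraction, rs$name),
                 burst_size = stats::setNames(rs$burst_size, rs$name),
                 background_depth = background_depth,
                 overdispersion = overdispersion,
                 qpcr_noise_sd = qpcr_noise_sd,
                 spi_rate = spi_rate, gc = gc, seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %s bp genome, %d prophage(s)\n",
              format(nchar(x$genome$sequence), big.mark = ","),
              length(x$regions)))
  for (r in x$regions) {
    cat(sprintf("  %s [%d, %d) f=%.3g b=%.3g core=%s\n", r$name, r$start,
                r$end, x$induced_fraction[[r$name]],
                x$burst_size[[r$name]], r$att_core))
  }
  invisible(x)
}

#' Simulate supernatant sequencing coverage
#'
#' Depth at each base is negative-binomial with mean `background_depth`
#' outside the prophage regions (residual host gDNA in the supernatant)
#' and `background_depth * (1 + f_i * b_i)` inside region i, where `f_i`
#' is the induced fraction and `b_i` the burst size: induced cells each
#' release `b_i` phage genome copies on top of one chromosomal copy, so
#' the expected in-region/background depth ratio is `1 + f * b`.
#'
#' @param truth a `synthetic_truth` from [generate_host_genome()].
#' @param mean_depth background depth (default: the truth's value).
#' @param overdispersion negative-binomial size parameter (larger = closer
#'   to Poisson).
#' @param seed integer seed.
#' @return A [coverage_track()] over the truth genome.
#' @export
simulate_supernatant_coverage <- function(truth,
                                          mean_depth = truth$background_depth,
                                          overdispersion = truth$overdispersion,
                                          seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  assert_scalar_number(mean_depth, "mean_depth", min = 1e-9)
  assert_scalar_number(overdispersion, "overdispersion", min = 1e-9)
  L <- nchar(truth$genome$sequence)
  mu <- rep(mean_depth, L)
  for (r in truth$regions) {
    fb <- truth$induced_fraction[[r$name]] * truth$burst_size[[r$name]]
    mu[(r$start + 1):r$end] <- mean_depth * (1 + fb)
  }
  set.seed(seed)
  coverage_track(truth$genome$id,
                 stats::rnbinom(L, size = overdispersion, mu = mu))
}

qpcr_curve_ct <- function(amount, slope, intercept) {
  intercept + slope * log10(amount)
}

#' Simulate a qPCR plate with standards and unknowns
#'
#' Standards are 1:10 serial dilutions from 1 ng/ul (so `n_standards = 5`
#' ends at 1e-5 ng/ul), in technical duplicates. Unknown wells get
#' `Ct = intercept + slope * log10(true_amount) + Normal(0, noise_sd)`;
#' the true amount of each attB-junction target is
#' `spi_fraction * reference_amount` (an excised-genome junction is
#' present in exactly the induced fraction of chromosomes), and the
#' thymidine-kinase reference target measures `reference_amount` itself.
#' A zero true amount yields the no-amplification sentinel (`ct = NA`),
#' never an artificial Ct.
#'
#' @param truth a `synthetic_truth` (supplies default SPI fractions and
#'   noise).
#' @param curve_params list with `slope` (< 0, cycles per log10 ng/ul) and
#'   `intercept` (cycles at 1 ng/ul).
#' @param n_standards number of 1:10 dilution levels (>= 3).
#' @param spi_fractions named vector of true induced fractions per attB
#'   target sample (default: the truth's `induced_fraction`).
#' @param reference_amount DNA amount measured by the reference target
#'   (ng/ul).
#' @param noise_sd qPCR cycle noise (default: the truth's value).
#' @param include_control add a fully induced prophage-free control sample
#'   whose junction amount equals `reference_amount` (the 100% control).
#' @param seed integer seed.
#' @return A [qpcr_plate()].
#' @export
simulate_qpcr_plate <- function(truth,
                                curve_params = list(slope = -3.3219,
                                                    intercept = 20),
                                n_standards = 5L,
                                spi_fractions = truth$induced_fraction,
                                reference_amount = 0.1,
                                noise_sd = truth$qpcr_noise_sd,
                                include_control = TRUE,
                                seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (curve_params$slope >= 0) stop2("standard-curve slope must be negative")
  if (n_standards < 3L) stop2("need at least 3 standard dilutions")
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  set.seed(seed)
  rows <- list()
  add <- function(sample_id, target, amount, known = NA_real_) {
    for (rep in 1:2) {
      ct <- if (amount <= 0) NA_real_ else
        qpcr_curve_ct(amount, curve_params$slope, curve_params$intercept) +
        stats::rnorm(1, 0, noise_sd)
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = sample_id, target = target, ct = ct,
        known_conc = known, replicate = rep, stringsAsFactors = FALSE)
    }
  }
  for (conc in 10^-(seq_len(n_standards))) {
    add("standard", "standard", conc, known = conc)
  }
  targets <- paste0(tolower(names(spi_fractions)), "_attB")
  for (i in seq_along(spi_fractions)) {
    add("sample", targets[i], spi_fractions[[i]] * reference_amount)
  }
  add("sample", "reference_tk", reference_amount)
  if (include_control) {
    for (tg in targets) add("control", tg, reference_amount)
    add("control", "reference_tk", reference_amount)
  }
  qpcr_plate(do.call(rbind, rows))
}

#' Simulate a repetitive-batch competition with qPCR read-outs
#'
#' Runs the passage model of [simulate_passage()] and reports
#' strain-discriminating qPCR plates after the first and last cycles, as
#' in a competition experiment read out by deletion-junction qPCR: the
#' mixed culture's junction amount is proportional to the deletion-strain
#' fraction, and a pure deletion-strain control provides the 100% level.
#'
#' @param config a [passage_config()].
#' @param curve_params,noise_sd,reference_amount as in
#'   [simulate_qpcr_plate()].
#' @param seed integer seed (drives both trajectory and plate noise).
#' @return A list: `trajectory` (a `passage_trajectory`), `plate_cycle1`
#'   and `plate_cycle_final` ([qpcr_plate()]s).
#' @export
simulate_competition_experiment <- function(config = passage_config(),
                                            curve_params = list(slope = -3.3219,
                                                                intercept = 20),
                                            noise_sd = 0.15,
                                            reference_amount = 0.1,
                                            seed = 1L) {
  config$seed <- seed
  traj <- simulate_passage(config)
  strains <- attr(traj, "strains")
  delta <- strains[length(strains)]   # the deletion strain read out by qPCR
  make_plate <- function(cycle, plate_seed) {
    frac <- traj[traj$cycle == cycle, paste0("fraction_", delta)]
    set.seed(plate_seed)
    noisy_ct <- function(amount) {
      if (amount <= 0) return(NA_real_)
      qpcr_curve_ct(amount, curve_params$slope, curve_params$intercept) +
        stats::rnorm(1, 0, noise_sd)
    }
    rows <- list()
    add <- function(sample_id, target, amount, known = NA_real_) {
      for (rep in 1:2) {
        rows[[length(rows) + 1L]] <<- data.frame(
          sample_id = sample_id, target = target, ct = noisy_ct(amount),
          known_conc = known, replicate = rep, stringsAsFactors = FALSE)
      }
    }
    for (conc in 10^-(1:5)) add("standard", "standard", conc, known = conc)
    add("mix", "delta_junction", frac * reference_amount)
    add("mix", "reference_tk", reference_amount)
    add("control", "delta_junction", reference_amount)
    add("control", "reference_tk", reference_amount)
    qpcr_plate(do.call(rbind, rows))
  }
  list(trajectory = traj,
       plate_cycle1 = make_plate(1L, seed + 1000L),
       plate_cycle_final = make_plate(max(traj$cycle), seed + 2000L))
}
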