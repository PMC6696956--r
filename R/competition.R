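#' Number of generations in a batch culture
#'
#' From `OD_final / OD_start = 2^n`: `n = log2(OD_final / OD_start)`.
#' A full regrowth after a 1:200 dilution is log2(200) = 7.64
#' generations; twelve such cycles give about 90 generations.
#'
#' @param od_final,od_start optical densities (OD600), both positive,
#'   `od_final >= od_start`.
#' @return Number of generations n.
#' @export
generations <- function(od_final, od_start) {
  if (any(od_final <= 0) || any(od_start <= 0)) {
    stop2("OD values must be positive")
  }
  if (any(od_final < od_start)) stop2("od_final must be >= od_start")
  log2(od_final / od_start)
}

#' Cell dry weight from optical density
#'
#' `CDW [g/liter] = OD600 * 0.27`.
#'
#' @param od600 optical density (>= 0).
#' @return Cell dry weight in g/liter.
#' @export
od_to_cdw <- function(od600) {
  if (any(od600 < 0)) stop2("OD must be non-negative")
  od600 * 0.27
}

#' Configuration of a repetitive-batch competition
#'
#' Defaults follow the standard regime: 1:200 dilution twice a day, 12
#' cycles, two strains started 1:1, equal growth rates, and a per-
#' generation spontaneous-lysis (SPI) probability per strain.
#'
#' @param strains strain names; the last is treated as the deletion
#'   strain by read-out helpers.
#' @param fractions0 initial strain fractions (sum to 1).
#' @param spi_rate named per-strain per-generation lysis probability in
#'   `[0, 1)`.
#' @param growth_rate named per-strain growth rates (per hour); only
#'   their ratios matter and the default is equal rates.
#' @param dilution_factor transfer dilution (> 1, default 200).
#' @param cycles number of cultivation cycles (default 12).
#' @param od_start culture OD600 at inoculation (default 0.1).
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param bottleneck_cells number of cells transferred at each dilution
#'   (stochastic mode only).
#' @param seed integer seed (stochastic mode).
#' @return A list of class `passage_config`.
#' @export
passage_config <- function(strains = c("wt", "delta"),
                           fractions0 = c(0.5, 0.5),
                           spi_rate = c(wt = 0.006, delta = 0),
                           growth_rate = NULL,
                           dilution_factor = 200,
                           cycles = 12L,
                           od_start = 0.1,
                           mode = c("deterministic", "stochastic"),
                           bottleneck_cells = NULL,
                           seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(strains) >= 2L, length(fractions0) == length(strains))
  if (abs(sum(fractions0) - 1) > 1e-9) stop2("fractions0 must sum to 1")
  if (dilution_factor <= 1) stop2("dilution_factor must be > 1")
  if (cycles < 1L) stop2("cycles must be >= 1")
  spi <- stats::setNames(rep(0, length(strains)), strains)
  spi[names(spi_rate)] <- spi_rate
  if (any(spi < 0 | spi >= 1)) stop2("spi_rate must be in [0, 1)")
  gr <- growth_rate %||% stats::setNames(rep(1, length(strains)), strains)
  if (mode == "stochastic" && is.null(bottleneck_cells)) {
    stop2("bottleneck_cells is required in stochastic mode")
  }
  structure(list(strains = strains,
                 fractions0 = stats::setNames(fractions0, strains),
                 spi_rate = spi, growth_rate = gr,
                 dilution_factor = dilution_factor,
                 cycles = as.integer(cycles), od_start = od_start,
                 mode = mode, bottleneck_cells = bottleneck_cells,
                 seed = as.integer(seed)),
            class = "passage_config")
}

#' Simulate a repetitive-batch competition
#'
#' Minimal model of SPI-driven competition: in each generation a lysing
#' lineage loses its doubling, so strain i multiplies by
#' `2 * (1 - spi_rate_i) * g_i` per generation (with `g_i` the relative
#' growth-rate weight, 1 by default). Every cycle the culture regrows to
#' stationary phase — `log2(dilution_factor)` generations at full
#' regrowth — and is then diluted; deterministic dilution leaves
#' fractions unchanged, while stochastic mode draws binomial lysis per
#' generation and a multinomial sample of `bottleneck_cells` at each
#' transfer.
#'
#' @param config a [passage_config()].
#' @return A data frame of class `passage_trajectory` with one row per
#'   cycle: `cycle`, `fraction_<strain>` columns, `od_final`,
#'   `generations_cycle` and cumulative `generations_total`. The strain
#'   names are attached as attribute `strains`.
#' @export
simulate_passage <- function(config) {
  stopifnot(inherits(config, "passage_config"))
  g_target <- log2(config$dilution_factor)
  w <- config$growth_rate / max(config$growth_rate)
  mult <- 2 * (1 - config$spi_rate) * w     # per-generation multiplier

  if (config$mode == "deterministic") {
    sizes <- config$fractions0
    rows <- vector("list", config$cycles)
    total_gen <- 0
    for (cy in seq_len(config$cycles)) {
      sizes <- sizes * mult^g_target
      grown <- sum(sizes)
      od_final <- config$od_start * grown
      gen_cycle <- generations(od_final, config$od_start)
      total_gen <- total_gen + gen_cycle
      frac <- sizes / grown
      rows[[cy]] <- c(cycle = cy, stats::setNames(frac,
                        paste0("fraction_", config$strains)),
                      od_final = od_final, generations_cycle = gen_cycle,
                      generations_total = total_gen)
      sizes <- frac                         # dilution preserves fractions
    }
  } else {
    set.seed(config$seed)
    counts <- as.numeric(stats::rmultinom(1, config$bottleneck_cells,
                                          config$fractions0)[, 1])
    names(counts) <- config$strains
    start_total <- sum(counts)
    rows <- vector("list", config$cycles)
    total_gen <- 0
    for (cy in seq_len(config$cycles)) {
      g_left <- g_target
      while (g_left > 1e-9) {
        step <- min(1, g_left)
        # lysis first (a lysing cell skips its doubling), then division;
        # a partial generation divides a Binomial(2^step - 1) subset
        lysed <- stats::rbinom(length(counts), counts,
                               pmin(1, config$spi_rate * step))
        alive <- counts - lysed
        if (step >= 1) {
          counts <- 2 * alive
        } else {
          counts <- alive + stats::rbinom(length(counts), alive,
                                          2^step - 1)
        }
        names(counts) <- config$strains
        g_left <- g_left - step
      }
      grown_total <- sum(counts)
      od_final <- config$od_start * grown_total / start_total
      gen_cycle <- generations(max(od_final, config$od_start),
                               config$od_start)
      total_gen <- total_gen + gen_cycle
      frac <- counts / grown_total
      rows[[cy]] <- c(cycle = cy, stats::setNames(frac,
                        paste0("fraction_", config$strains)),
                      od_final = od_final, generations_cycle = gen_cycle,
                      generations_total = total_gen)
      counts <- as.numeric(stats::rmultinom(1, config$bottleneck_cells,
                                            frac)[, 1])
      names(counts) <- config$strains
      start_total <- sum(counts)
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "strains") <- config$strains
  attr(out, "config") <- config
  class(out) <- c("passage_trajectory", "data.frame")
  out
}

#' Estimate the selection coefficient from ratio read-outs
#'
#' Inverse of the deterministic passage model: with ratio R = deletion
#' strain : wild type, `R_final = R_initial * (1 - s)^(-n)` after n
#' generations, so `s = 1 - (R_initial / R_final)^(1/n)`. Applied to a
#' trajectory simulated at a given SPI rate this recovers the rate
#' exactly (deterministic mode) or in expectation (stochastic mode).
#'
#' @param ratio_initial,ratio_final strain ratios (> 0).
#' @param n_generations number of elapsed generations (> 0).
#' @return Selection coefficient s (per generation).
#' @export
estimate_selection <- function(ratio_initial, ratio_final, n_generations) {
  if (any(ratio_initial <= 0) || any(ratio_final <= 0)) {
    stop2("ratios must be positive")
  }
  if (any(n_generations <= 0)) stop2("n_generations must be positive")
  1 - (ratio_initial / ratio_final)^(1 / n_generations)
}
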