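test_that("generated genomes implant maximal att repeats at region flanks", {
  truth <- generate_host_genome(
    length = 50000,
    regions_spec = prophage_spec(name = "VNP1", start = 20000, length = 5000,
                                 att_core = VNP1_CORE,
                                 induced_fraction = 0.1, burst_size = 100),
    seed = 5)
  occ <- as.integer(gregexpr(VNP1_CORE, truth$genome$sequence,
                             fixed = TRUE)[[1]]) - 1L
  expect_equal(occ, c(20000L, 25000L - 14L))
  expect_equal(nchar(truth$genome$sequence), 50000)

  # the repeat is maximal: the flanking bases differ between copies
  s <- truth$genome$sequence
  expect_false(substr(s, 20000, 20000) == substr(s, 24986, 24986))
  expect_false(substr(s, 20015, 20015) == substr(s, 25001, 25001))
})

test_that("genome generation is deterministic given the seed", {
  a <- generate_host_genome(length = 30000, seed = 42,
                            regions_spec = prophage_spec(
                              name = "p", start = 10000, length = 5000,
                              att_core = VNP1_CORE,
                              induced_fraction = 0.1, burst_size = 10))
  b <- generate_host_genome(length = 30000, seed = 42,
                            regions_spec = prophage_spec(
                              name = "p", start = 10000, length = 5000,
                              att_core = VNP1_CORE,
                              induced_fraction = 0.1, burst_size = 10))
  expect_identical(a$genome$sequence, b$genome$sequence)
})

test_that("background GC content matches the request within binomial error", {
  truth <- generate_host_genome(length = 100000, gc = 0.45, seed = 8,
                                regions_spec = prophage_spec(
                                  name = "p", start = 45000, length = 5000,
                                  att_core = VNP1_CORE,
                                  induced_fraction = 0, burst_size = 1))
  chars <- strsplit(truth$genome$sequence, "")[[1]]
  gc_obs <- mean(chars %in% c("G", "C"))
  # binomial SE at n = 1e5 is ~0.0016; 0.01 is > 6 SE
  expect_lt(abs(gc_obs - 0.45), 0.01)
})

test_that("generator rejects invalid prophage specifications", {
  expect_error(generate_host_genome(
    length = 20000, regions_spec = prophage_spec(
      name = c("a", "b"), start = c(2000, 6000), length = c(5000, 5000),
      att_core = c(VNP1_CORE, VNP1_CORE),
      induced_fraction = c(0, 0), burst_size = c(1, 1))), "margin")
  expect_error(generate_host_genome(
    length = 20000, regions_spec = prophage_spec(
      name = "a", start = 5000, length = 5000, att_core = "ACGTACGT",
      induced_fraction = 0, burst_size = 1)), "10 bp")
})

test_that("uninduced prophages leave coverage flat at background", {
  truth <- small_truth(seed = 2)
  truth$induced_fraction[] <- 0
  cov <- simulate_supernatant_coverage(truth, seed = 3)
  bg <- truth$background_depth
  expect_lt(abs(mean(cov$depth) - bg) / bg, 0.05)
  for (r in truth$regions) {
    expect_lt(abs(mean(cov$depth[(r$start + 1):r$end]) - bg) / bg, 0.1)
  }
})

test_that("in-region coverage matches the closed form background*(1+f*b)", {
  truth <- small_truth(seed = 4)
  n_seeds <- 50
  means <- matrix(NA_real_, n_seeds, 2)
  for (s in seq_len(n_seeds)) {
    cov <- simulate_supernatant_coverage(truth, seed = s)
    for (j in 1:2) {
      r <- truth$regions[[j]]
      means[s, j] <- mean(cov$depth[(r$start + 1):r$end])
    }
  }
  for (j in 1:2) {
    r <- truth$regions[[j]]
    fb <- truth$induced_fraction[[r$name]] * truth$burst_size[[r$name]]
    expected <- truth$background_depth * (1 + fb)
    se <- sd(means[, j]) / sqrt(n_seeds)
    expect_lt(abs(mean(means[, j]) - expected), 3 * se + 1e-9)
  }
})

test_that("the configured burst asymmetry yields a ~7x enrichment ratio", {
  truth <- small_truth(seed = 6)
  ratios <- vapply(1:25, function(s) {
    cov <- simulate_supernatant_coverage(truth, seed = s)
    bg <- estimate_background(cov, truth$regions)
    f1 <- fold_enrichment(cov, truth$regions[[1]], bg)
    f2 <- fold_enrichment(cov, truth$regions[[2]], bg)
    enrichment_ratio(f2, f1)
  }, numeric(1))
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 7), max(3 * se, 0.2))
})

test_that("noise-free qPCR plates satisfy the exact curve relations", {
  truth <- small_truth(seed = 1)
  # fully induced sample: its attB amount equals the reference amount
  plate <- simulate_qpcr_plate(truth, spi_fractions = c(VNP1 = 1, VNP2 = 1),
                               noise_sd = 0, seed = 1)
  unk <- plate_unknowns(plate)
  ct_attB <- unk$ct[unk$sample_id == "sample" & unk$target == "vnp1_attB"]
  ct_ref <- unk$ct[unk$sample_id == "sample" & unk$target == "reference_tk"]
  expect_equal(ct_attB, ct_ref)

  # five 1:10 dilutions from 1 ng/ul end at 1e-5 ng/ul
  std <- plate_standards(plate)
  expect_equal(min(std$known_conc), 1e-5)
  expect_equal(sort(unique(std$known_conc)), 10^-(5:1))

  # noise-free Ct spacing per 10x dilution step equals the slope magnitude
  cts <- tapply(std$ct, std$known_conc, unique)  # ordered by rising conc
  expect_equal(as.numeric(diff(cts)), rep(-3.3219, 4))
})

test_that("zero true amount yields the no-amplification sentinel", {
  truth <- small_truth(seed = 1)
  plate <- simulate_qpcr_plate(truth, spi_fractions = c(VNP1 = 0, VNP2 = 0.5),
                               noise_sd = 0, seed = 1)
  unk <- plate_unknowns(plate)
  expect_true(all(is.na(
    unk$ct[unk$sample_id == "sample" & unk$target == "vnp1_attB"])))
  expect_true(all(!is.na(
    unk$ct[unk$sample_id == "sample" & unk$target == "vnp2_attB"])))
})

test_that("competition simulator is symmetric, deterministic and calibrated", {
  # equal strains, zero SPI, zero noise: the final read-out is 50:50
  cfg <- passage_config(spi_rate = c(wt = 0, delta = 0))
  out <- simulate_competition_experiment(cfg, noise_sd = 0, seed = 1)
  q <- quantify_plate(out$plate_cycle_final)
  frac <- q$normalized[q$sample_id == "mix" & q$target == "delta_junction"] /
    q$normalized[q$sample_id == "control" & q$target == "delta_junction"]
  expect_equal(frac, 0.5, tolerance = 1e-6)

  # fixed seed reproduces the plates exactly
  out2 <- simulate_competition_experiment(cfg, noise_sd = 0, seed = 1)
  expect_identical(out$plate_cycle_final$ct, out2$plate_cycle_final$ct)

  # noisy read-out recovers the true final fraction without bias
  cfg2 <- passage_config()
  truth_frac <- simulate_passage(cfg2)$fraction_delta[12]
  est <- vapply(1:100, function(s) {
    o <- simulate_competition_experiment(cfg2, noise_sd = 0.15, seed = s)
    qq <- quantify_plate(o$plate_cycle_final)
    qq$normalized[qq$sample_id == "mix" & qq$target == "delta_junction"] /
      qq$normalized[qq$sample_id == "control" & qq$target == "delta_junction"]
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth_frac), 3 * se + 0.002)
})
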