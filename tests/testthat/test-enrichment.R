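uniform_track <- function(depth = 10, n = 1000) {
  coverage_track("chr1", rep(depth, n))
}

test_that("background estimation is the median outside excluded regions", {
  expect_equal(estimate_background(uniform_track()), 10)

  # 70x plateau, excluded: background untouched by the enriched region
  depth <- rep(10, 10000); depth[4001:6000] <- 700
  tr <- coverage_track("chr1", depth)
  reg <- prophage_region("chr1", 4000, 6000)
  expect_equal(estimate_background(tr, list(reg)), 10)

  # agreement with a sort-based median oracle on random tracks
  set.seed(12)
  for (trial in 1:20) {
    x <- rnbinom(5000, size = 10, mu = runif(1, 5, 50))
    tr <- coverage_track("chr1", x)
    expect_equal(estimate_background(tr), median_oracle(x))
  }

  expect_error(estimate_background(tr, list(prophage_region("chr1", 0, 5000))),
               "excluded")
})

test_that("fold enrichment is in-region mean over background", {
  tr <- uniform_track(10, 1000)
  expect_equal(fold_enrichment(tr, prophage_region("chr1", 100, 900), 10), 1)

  depth <- rep(10, 1000); depth[201:400] <- 70
  tr2 <- coverage_track("chr1", depth)
  expect_equal(fold_enrichment(tr2, prophage_region("chr1", 200, 400), 10), 7)
  expect_error(fold_enrichment(tr2, prophage_region("chr1", 200, 400), 0),
               "background")
})

test_that("recovered fold matches 1 + f*b on simulated coverage", {
  truth <- small_truth(seed = 9)
  folds <- vapply(1:50, function(s) {
    cov <- simulate_supernatant_coverage(truth, seed = s)
    # mean-based background for the unbiased closed-form comparison (the
    # median of discrete counts sits slightly below the mean)
    bg <- estimate_background(cov, truth$regions, stat = "mean")
    fold_enrichment(cov, truth$regions[[1]], bg)
  }, numeric(1))
  expected <- 1 + truth$induced_fraction[["VNP1"]] * truth$burst_size[["VNP1"]]
  se <- sd(folds) / sqrt(length(folds))
  expect_lt(abs(mean(folds) - expected), 3 * se + 1e-9)
})

test_that("segment detection finds implanted plateaus and nothing else", {
  expect_equal(detect_enriched_segments(uniform_track(10, 20000)), list())

  truth <- small_truth(seed = 10)
  cov <- simulate_supernatant_coverage(truth, seed = 11)
  segs <- detect_enriched_segments(cov)
  expect_length(segs, 2)
  for (j in 1:2) {
    r <- truth$regions[[j]]; s <- segs[[j]]
    ov <- max(0, min(r$end, s$end) - max(r$start, s$start))
    expect_gte(ov / (r$end - r$start), 0.95)
    expect_gte(ov / (s$end - s$start), 0.95)
  }

  # plateau shorter than min_len is ignored
  depth <- rep(10, 30000); depth[10001:12000] <- 100
  tr <- coverage_track("chr1", depth)
  expect_equal(detect_enriched_segments(tr, min_len = 5000), list())
  expect_length(detect_enriched_segments(tr, min_len = 1000), 1)
})

test_that("detection statistics are invariant to depth rescaling", {
  truth <- small_truth(seed = 13)
  cov <- simulate_supernatant_coverage(truth, seed = 13)
  scaled <- coverage_track(cov$chrom, cov$depth * 17.3)
  bg <- estimate_background(cov, truth$regions)
  bg_s <- estimate_background(scaled, truth$regions)
  r <- truth$regions[[1]]
  expect_equal(fold_enrichment(scaled, r, bg_s), fold_enrichment(cov, r, bg))
  segs <- detect_enriched_segments(cov)
  segs_s <- detect_enriched_segments(scaled)
  expect_equal(lapply(segs_s, `[`, c("start", "end")),
               lapply(segs, `[`, c("start", "end")))
})

test_that("boundary refinement is exact on noise-free steps", {
  depth <- rep(10, 20000)
  depth[8001:13000] <- 70                  # region [8000, 13000)
  tr <- coverage_track("chr1", depth)
  # start from deliberately wrong boundaries
  reg <- prophage_region("chr1", 8600, 12500)
  ref <- refine_boundaries(tr, reg, search_window = 1000)
  expect_equal(ref$start, 8000)
  expect_equal(ref$end, 13000)
  expect_false(any(ref$degenerate))
})

test_that("flat windows are flagged degenerate and left unchanged", {
  tr <- uniform_track(10, 10000)
  reg <- prophage_region("chr1", 3000, 7000)
  ref <- refine_boundaries(tr, reg, search_window = 500)
  expect_true(all(ref$degenerate))
  expect_equal(ref$start, 3000)
  expect_equal(ref$end, 7000)
})

test_that("step-fit split agrees with a naive SSE scan under noise", {
  set.seed(14)
  errs <- numeric(50)
  for (trial in 1:50) {
    n <- 3000
    true_split <- 1000
    x <- c(rnbinom(true_split, size = 10, mu = 10),
           rnbinom(n - true_split, size = 10, mu = 70))
    tr <- coverage_track("chr1", x)
    reg <- prophage_region("chr1", true_split, 2400)
    ref <- refine_boundaries(tr, reg, search_window = 500)
    errs[trial] <- abs(ref$start - true_split)
    if (trial <= 10) {
      # cross-check the fast split against the brute-force scan
      win <- x[(true_split - 500 + 1):(true_split + 500)]
      expect_equal(ref$start, true_split - 500 + stepfit_oracle(win))
    }
  }
  expect_lte(median(errs), 50)
})

test_that("enrichment ratio uses excess enrichment by default", {
  expect_equal(enrichment_ratio(71, 11), 7)
  expect_equal(enrichment_ratio(71, 11, method = "fold"), 71 / 11)
  expect_equal(enrichment_ratio(5, 5), 1)
  expect_warning(out <- enrichment_ratio(5, 1), "undefined")
  expect_true(is.na(out))
})

test_that("enrichment reports assemble region statistics coherently", {
  depth <- rep(10, 20000); depth[8001:13000] <- 70
  tr <- coverage_track("chr1", depth)
  rep1 <- enrichment_report(tr, prophage_region("chr1", 8300, 12800, "p"),
                            refine = TRUE)
  expect_equal(rep1$refined_start, 8000)
  expect_equal(rep1$refined_end, 13000)
  expect_equal(rep1$fold_enrichment, 7)
  expect_equal(rep1$mean_depth / rep1$background, rep1$fold_enrichment)
})
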