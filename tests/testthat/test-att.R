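test_that("recombine reconstructs the observed VNP2 attP at k = 23", {
  rc <- recombine(VNP2_ATTL, VNP2_ATTR, 23)
  expect_equal(rc$attP, VNP2_ATTP)
  # attB is the complementary hybrid: attL head, attR tail
  expect_equal(rc$attB, paste0(substr(VNP2_ATTL, 1, 23),
                               substr(VNP2_ATTR, 24, 26)))
})

test_that("recombine is the identity on identical sites, for every k", {
  s <- "ACGTACGTAA"
  for (k in 0:10) {
    rc <- recombine(s, s, k)
    expect_equal(rc$attB, s)
    expect_equal(rc$attP, s)
  }
  expect_error(recombine("ACGT", "ACGTA", 2), "length")
  expect_error(recombine("ACGT", "ACGT", 5), "k")
})

test_that("recombination conserves the per-position base multiset", {
  set.seed(11)
  column_pairs <- function(x, y) {
    cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
    paste(pmin(cx, cy), pmax(cx, cy))
  }
  for (trial in 1:25) {
    n <- sample(8:30, 1)
    attL <- rand_dna(n); attR <- rand_dna(n)
    parents <- column_pairs(attL, attR)
    for (k in 0:n) {
      rc <- recombine(attL, attR, k)
      expect_equal(column_pairs(rc$attB, rc$attP), parents)
    }
  }
})

test_that("crossover interval for the printed VNP2 sites matches brute force", {
  oracle_ks <- crossover_oracle(VNP2_ATTL, VNP2_ATTR, VNP2_ATTP)
  expect_equal(range(oracle_ks), c(12, 23))
  expect_equal(infer_crossover_interval(VNP2_ATTL, VNP2_ATTR, VNP2_ATTP),
               c(12L, 23L))
})

test_that("crossover interval handles degenerate and impossible cases", {
  s <- "ACGTACGT"
  expect_equal(infer_crossover_interval(s, s, s), c(0L, 8L))
  # attP base present in neither parent at position 1
  expect_equal(infer_crossover_interval("AACGT", "ACCGT", "TACGT"),
               integer(0))
})

test_that("inferred crossover interval always contains the generating k", {
  set.seed(21)
  for (trial in 1:40) {
    n <- sample(10:30, 1)
    attL <- rand_dna(n); attR <- rand_dna(n)
    k <- sample(0:n, 1)
    rc <- recombine(attL, attR, k)
    iv <- infer_crossover_interval(attL, attR, rc$attP)
    expect_true(length(iv) == 2 && iv[1] <= k && k <= iv[2])
    expect_equal(iv, range(crossover_oracle(attL, attR, rc$attP)))
  }
})

test_that("find_att_core recovers an implanted 14-bp core", {
  truth <- generate_host_genome(
    length = 50000,
    regions_spec = prophage_spec(name = "VNP1", start = 20000, length = 5000,
                                 att_core = VNP1_CORE,
                                 induced_fraction = 0.1, burst_size = 100),
    seed = 5)
  # the 14-mer occurs exactly twice, at the two region flanks
  occ <- gregexpr(VNP1_CORE, truth$genome$sequence, fixed = TRUE)[[1]]
  expect_equal(as.integer(occ) - 1L, c(20000L, 25000L - 14L))

  hit <- find_att_core(truth$genome, truth$regions[[1]])
  expect_true(hit$found)
  expect_equal(hit$core, VNP1_CORE)
  expect_equal(hit$core_length, 14L)
  expect_equal(hit$left_start, 20000L)
  expect_equal(hit$right_start, 25000L - 14L)
})

test_that("find_att_core reports absence of a flanking repeat, not an error", {
  set.seed(31)
  g <- genome_record("chr", rand_dna(6000))
  r <- prophage_region("chr", 2000, 4000)
  hit <- find_att_core(g, r, window = 500, min_len = 12)
  # a chance 12-mer repeat between two 1-kb windows is vanishingly unlikely
  expect_false(hit$found)
  expect_null(hit$core)
})

test_that("find_att_core agrees with the longest-common-substring oracle", {
  set.seed(41)
  for (trial in 1:60) {
    core_len <- sample(10:24, 1)
    core <- rand_dna(core_len)
    left <- rand_dna(300); right <- rand_dna(300)
    inner <- rand_dna(sample(400:800, 1))
    seq <- paste0(left, core, inner, core, right)
    start <- 300
    end <- 300 + 2 * core_len + nchar(inner)
    g <- genome_record("chr", seq)
    r <- prophage_region("chr", start, end)
    hit <- find_att_core(g, r, window = 150, min_len = 8)
    wa <- substr(seq, start - 150 + 1, start + 150)
    wb <- substr(seq, end - 150 + 1, end + 150)
    oracle <- lcs_oracle(wa, wb)
    expect_true(hit$found)
    expect_equal(hit$core_length, oracle$length)
    # the returned core must itself be a common substring of both windows
    # of the oracle's maximal length (ties are broken by boundary
    # proximity, so the witness string may legitimately differ)
    expect_true(grepl(hit$core, wa, fixed = TRUE))
    expect_true(grepl(hit$core, wb, fixed = TRUE))
    expect_gte(hit$core_length, core_len)
  }
})

test_that("excision leaves one attB core and conserves length bookkeeping", {
  truth <- small_truth(seed = 3)
  r <- truth$regions[[1]]
  att <- att_site_set(VNP1_CORE, VNP1_CORE)
  ex <- excise(truth$genome, r, att)

  host <- ex$host$sequence
  expect_equal(length(gregexpr(VNP1_CORE, host, fixed = TRUE)[[1]]), 1L)
  expect_equal(nchar(host) + nchar(ex$circle$sequence),
               nchar(truth$genome$sequence) + att$core_length)
  # identical cores: the circle is the prophage interval itself
  expect_equal(ex$circle$sequence,
               substr(truth$genome$sequence, r$start + 1, r$end))
  expect_equal(ex$att$attB, VNP1_CORE)
  expect_equal(ex$circle$attP, VNP1_CORE)

  bad_att <- att_site_set("AAAAAAAAAAAAAA", "AAAAAAAAAAAAAA")
  expect_error(excise(truth$genome, r, bad_att), "not found")
})

test_that("length conservation holds across random excisions", {
  set.seed(51)
  for (trial in 1:30) {
    core_len <- sample(10:26, 1)
    core <- rand_dna(core_len)
    inner <- rand_dna(sample(50:400, 1))
    left <- rand_dna(100); right <- rand_dna(100)
    g <- genome_record("g", paste0(left, core, inner, core, right))
    r <- prophage_region("g", 100, 100 + 2 * core_len + nchar(inner))
    k <- sample(0:core_len, 1)
    ex <- excise(g, r, att_site_set(core, core), k = k)
    expect_equal(nchar(ex$host$sequence) + nchar(ex$circle$sequence),
                 nchar(g$sequence) + core_len)
  }
})

test_that("integration inverts excision exactly, identical or impaired cores", {
  # identical cores
  truth <- small_truth(seed = 7)
  r <- truth$regions[[2]]
  ex <- excise(truth$genome, r, att_site_set(VNP2_ATTL, VNP2_ATTL))
  back <- integrate_phage(ex$host, r$start, ex$circle)
  expect_equal(back$sequence, truth$genome$sequence)

  # VNP2-style impaired cores: implant attL and attR, excise at k = 23
  left <- rand_dna(200); inner <- rand_dna(500); right <- rand_dna(200)
  g <- genome_record("g", paste0(left, VNP2_ATTL, inner, VNP2_ATTR, right))
  r2 <- prophage_region("g", 200, 200 + 26 + 500 + 26)
  ex2 <- excise(g, r2, att_site_set(VNP2_ATTL, VNP2_ATTR), k = 23)
  expect_equal(ex2$att$attP, VNP2_ATTP)
  host <- ex2$host$sequence
  # junction in the host is the reconstituted attB
  expect_equal(substr(host, 201, 226), ex2$att$attB)
  back2 <- integrate_phage(ex2$host, 200, ex2$circle)
  expect_equal(back2$sequence, g$sequence)
  # both junction sites of the re-integrated genome conserve the
  # per-position multiset of the original attL/attR columns
  reL <- substr(back2$sequence, 201, 226)
  reR <- substr(back2$sequence, 201 + 500 + 26, 226 + 500 + 26)
  for (i in 1:26) {
    expect_setequal(c(substr(reL, i, i), substr(reR, i, i)),
                    c(substr(VNP2_ATTL, i, i), substr(VNP2_ATTR, i, i)))
  }

  expect_error(integrate_phage(ex2$host, 5, ex2$circle), "attB")
})

test_that("region_length reports printed interval sizes per convention", {
  expect_equal(region_length(935757, 971809, "inclusive"), 36053)
  expect_equal(region_length(935757, 971809, "end_minus_start"), 36052)
  expect_equal(region_length(1496626, 1535809, "end_minus_start"), 39183)
  expect_equal(region_length(10, 10, "end_minus_start"), 0)
  expect_error(region_length(20, 10), "<")
})
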