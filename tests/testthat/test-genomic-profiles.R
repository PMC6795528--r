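# genomic_profiles: data model, MAD/noise metrics, segmentation, binning,
# and the TSV/SEG I/O boundary.

test_that("genome model and bin grid enforce their invariants", {
  expect_error(genome_model(c("1", "1"), c(1e6, 2e6)), "unique")
  expect_error(genome_model("1", -5), "positive")
  gm <- default_genome()
  expect_identical(gm$chrom, as.character(1:22))
  expect_true(all(c("X", "Y") %in% default_genome(include_sex = TRUE)$chrom))

  grid <- bin_grid(tiny_genome(), 1e5)
  expect_equal(nrow(grid), 500 + 400)
  # half-open, non-overlapping, tiling in order
  by_chr <- split(grid, grid$chrom)
  for (g in by_chr) {
    expect_true(all(g$end > g$start))
    expect_equal(g$start[-1], g$end[-nrow(g)])
  }
  expect_equal(by_chr[["1"]]$end[nrow(by_chr[["1"]])], 5e7)
})

test_that("compute_mad matches hand computations", {
  expect_equal(compute_mad(make_profile(rep(0, 10))), 0)
  expect_equal(compute_mad(make_profile(c(1, 2, 3, 4, 5))), 1)
  # median 0, absolute deviations {0,0,0,10}, median of those 0
  expect_equal(compute_mad(make_profile(c(0, 0, 0, 10))), 0)
})

test_that("probe_profile rejects or cleans bad input", {
  expect_error(make_profile(numeric(0)), "empty profile")
  expect_message(
    p <- probe_profile("s", data.frame(chrom = "1",
                                       start = c(0, 1e4, 2e4),
                                       end = c(1e4, 2e4, 3e4),
                                       log2ratio = c(0.1, NaN, 0.3)),
                       genome = tiny_genome()),
    "dropped 1")
  expect_equal(nrow(p$probes), 2)
  # probes come back sorted by (chromosome, start)
  shuffled <- data.frame(chrom = c("2", "1", "1"),
                         start = c(0, 2e4, 0), end = c(1e4, 3e4, 1e4),
                         log2ratio = 1:3)
  p2 <- probe_profile("s", shuffled, genome = tiny_genome())
  expect_equal(p2$probes$chrom, c("1", "1", "2"))
  expect_equal(p2$probes$start, c(0, 2e4, 0))
})

test_that("estimate_noise recovers the probe sd and ignores structure", {
  expect_equal(estimate_noise(make_profile(rep(0.3, 100))), 0)
  # exact step, one breakpoint: all differences zero except one
  expect_equal(estimate_noise(make_profile(c(rep(0, 50), rep(1, 50)))), 0)
  # Monte-Carlo oracle: i.i.d. Gaussian probes, sd 0.1
  set.seed(42)
  p <- make_profile(list(`1` = rnorm(5e4, 0, 0.1)), spacing = 1e3)
  expect_equal(estimate_noise(p), 0.1, tolerance = 0.05)
  expect_error(estimate_noise(make_profile(0.5)), "at least 2 probes")
})

test_that("noise estimate is invariant to shifts and segment structure", {
  set.seed(7)
  base <- rnorm(2000, 0, 0.08)
  p0 <- make_profile(list(`1` = base), spacing = 2e4)
  n0 <- estimate_noise(p0)
  # constant shift
  expect_equal(estimate_noise(make_profile(list(`1` = base + 3),
                                           spacing = 2e4)), n0)
  # true segment structure with <= 1 breakpoint per 10 probes. At the
  # limit, 10% of first differences are contaminated by breakpoints,
  # inflating the median by ~13% in theory; 20% bounds the drift.
  for (k in c(5, 50, 200)) {
    bp <- sort(sample(1999, k))
    levels <- cumsum(c(0, sample(c(-0.5, 0.5), k, replace = TRUE)))
    seg_means <- rep(levels, diff(c(0, bp, 2000)))
    pn <- make_profile(list(`1` = base + seg_means), spacing = 2e4)
    expect_lt(abs(estimate_noise(pn) - n0), 0.2 * n0)
  }
})

test_that("segmentation handles constant, noiseless and noisy steps", {
  # constant profile on two chromosomes: one segment each
  p <- make_profile(list(`1` = rep(0.25, 100), `2` = rep(0.25, 80)))
  s <- segment_profile(p)
  expect_equal(nrow(s$segments), 2)
  expect_equal(s$segments$mean, c(0.25, 0.25))
  expect_equal(s$segments$num_probes, c(100L, 80L))

  # noiseless step 0 -> 1 at probe 500 of 1000
  p <- make_profile(list(`1` = c(rep(0, 500), rep(1, 500))))
  s <- segment_profile(p)
  expect_equal(nrow(s$segments), 2)
  expect_equal(s$segments$num_probes, c(500L, 500L))
  expect_equal(s$segments$mean, c(0, 1))

  # noisy step: breakpoint within +/- 2 probes, means within 0.02
  set.seed(11)
  for (i in 1:5) {
    x <- c(rnorm(500, 0, 0.05), rnorm(500, 1, 0.05))
    s <- segment_profile(make_profile(list(`1` = x)))
    expect_equal(nrow(s$segments), 2)
    expect_lte(abs(s$segments$num_probes[1] - 500), 2)
    expect_equal(s$segments$mean, c(0, 1), tolerance = 0.02)
  }

  expect_error(segment_profile(p, min_probes = 0), "min_probes")
})

test_that("segmentation conserves means and is idempotent on its output", {
  set.seed(3)
  x <- c(rnorm(300, 0, 0.05), rnorm(200, 0.8, 0.05), rnorm(300, -0.4, 0.05))
  p <- make_profile(list(`1` = x))
  s <- segment_profile(p)
  # sum over segments of (probe count x mean) == sum of probe log2ratios
  expect_equal(sum(s$segments$num_probes * s$segments$mean), sum(x))
  # rebuild the noiseless piecewise-constant reconstruction and re-segment
  recon <- rep(s$segments$mean, s$segments$num_probes)
  s2 <- segment_profile(make_profile(list(`1` = recon)))
  expect_equal(s2$segments$start, s$segments$start)
  expect_equal(s2$segments$end, s$segments$end)
  expect_equal(s2$segments$mean, s$segments$mean)
})

test_that("project_to_bins weights overlaps and flags uncovered bins", {
  gm <- tiny_genome()
  grid <- bin_grid(gm, 1e5)
  # one whole-chromosome segment, mean 0.3; chromosome 2 uncovered
  s <- segmented_profile("s", data.frame(chrom = "1", start = 0, end = 5e7,
                                         num_probes = 100L, mean = 0.3),
                         noise = 0.05, mad = 0.05, genome = gm)
  v <- project_to_bins(s, grid)
  expect_equal(v[grid$chrom == "1"], rep(0.3, 500))
  expect_true(all(is.na(v[grid$chrom == "2"])))
  # two segments meeting mid-bin with equal overlap -> weighted mean 0.5
  s2 <- segmented_profile("s", data.frame(chrom = "1",
                                          start = c(0, 1.5e5),
                                          end = c(1.5e5, 5e7),
                                          num_probes = c(3L, 997L),
                                          mean = c(0, 1)),
                          noise = 0.05, mad = 0.05, genome = gm)
  v2 <- project_to_bins(s2, grid)
  expect_equal(v2[1:3], c(0, 0.5, 1))
  # mismatched genome errors
  grid_other <- bin_grid(genome_model("1", 1e7), 1e5)
  expect_error(project_to_bins(s, grid_other), "genome")
})

test_that("binning a globally shifted profile shifts every bin by +c", {
  set.seed(5)
  cfg <- tiny_config()
  pair <- simulate_profile_pair(cfg, "non-clonal", seed = 9)
  s <- segment_profile(pair$profile_a)
  grid <- bin_grid(tiny_genome(), 1e5)
  v <- project_to_bins(s, grid)
  s_shift <- s
  s_shift$segments$mean <- s$segments$mean + 0.7
  v_shift <- project_to_bins(s_shift, grid)
  expect_equal(v_shift, v + 0.7)
})

test_that("probe TSV and SEG round-trip through the I/O boundary", {
  p <- make_profile(list(`1` = c(0.1, 0.2, -0.3), `2` = c(0.5, 0.4)))
  tsv <- tempfile(fileext = ".tsv")
  write_probe_tsv(p, tsv)
  expect_message(p2 <- read_probe_tsv(tsv, sample_id = "s1",
                                      genome = tiny_genome()),
                 "read 5 probe records")
  expect_equal(p2$probes, p$probes)

  s <- segment_profile(make_profile(list(`1` = c(rep(0, 50), rep(1, 50)))))
  seg <- tempfile(fileext = ".seg")
  write_seg(s, seg)
  # SEG is 1-based closed on disk
  raw <- read.table(seg, header = TRUE, sep = "\t")
  expect_equal(raw$loc.start, c(1, 50 * 5e4 + 1))
  expect_message(back <- read_seg(seg, genome = tiny_genome()), "1 samples")
  expect_equal(back[[1]]$segments$start, s$segments$start)
  expect_equal(back[[1]]$segments$end, s$segments$end)
  expect_equal(back[[1]]$segments$mean, s$segments$mean)

  expect_error(suppressMessages(read_probe_tsv(seg)), "malformed")
})
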