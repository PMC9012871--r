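test_that("fixed-width tiling covers each chromosome exactly", {
  sc <- build_fixed_bins(genome_layout("chr1", 1e6), 5e5)
  expect_equal(sc$bins$start, c(0, 5e5))
  expect_equal(sc$bins$end, c(5e5, 1e6))

  sc <- build_fixed_bins(genome_layout("chr1", 1234567), 5e5)
  expect_equal(nrow(sc$bins), 3)
  expect_equal(sc$bins$start[3], 1e6)
  expect_equal(sc$bins$end[3], 1234567)
  expect_identical(sc$scheme_kind, "fixed_width")

  # tiling property over a multi-chromosome layout
  sc <- build_fixed_bins(tiny_layout(), 123457)
  for (ch in sc$layout$chrom) {
    b <- sc$bins[sc$bins$chrom == ch, ]
    expect_equal(b$start[1], 0)
    expect_equal(b$end[nrow(b)], sc$layout$length[sc$layout$chrom == ch])
    if (nrow(b) > 1) expect_equal(b$start[-1], b$end[-nrow(b)])
  }
})

test_that("fixed-width binning validates input", {
  expect_error(build_fixed_bins(genome_layout("chr1", 1e6), 0),
               "positive")
  expect_error(genome_layout(character(0), numeric(0)), "empty")
  expect_error(genome_layout(c("a", "a"), c(1, 2)), "duplicate")
})

test_that("equal-mappable binning balances uniform tracks exactly", {
  layout <- genome_layout("chr1", 1e6)
  sc <- build_adaptive_bins(layout, uniform_track(layout), 10)
  expect_equal(nrow(sc$bins), 10)
  expect_equal(sc$bins$mappable_bases, rep(1e5, 10))
  expect_identical(sc$scheme_kind, "equal_mappable")

  # CV of mappable bases <= 1% on a uniform multi-chromosome genome
  # (bin count chosen so chromosomes hold enough bins that the
  # per-chromosome apportionment rounding stays below 1%)
  layout <- tiny_layout()
  sc <- build_adaptive_bins(layout, uniform_track(layout), 241)
  expect_equal(nrow(sc$bins), 241)
  mb <- sc$bins$mappable_bases
  expect_lt(stats::sd(mb) / mean(mb), 0.01)
  # total usable bases conserved
  expect_equal(sum(mb), sum(layout$length))
})

test_that("boundaries concentrate where the genome is mappable", {
  layout <- genome_layout("chr1", 1e6)
  mp <- data.frame(chrom = "chr1", start = c(0, 5e5), end = c(5e5, 1e6),
                   value = c(1, 0))
  sc <- build_adaptive_bins(layout, mp, 5)
  # all internal boundaries inside the first (mappable) half
  expect_true(all(sc$bins$start[-1] <= 5e5))
  expect_equal(sc$bins$mappable_bases, rep(1e5, 5), tolerance = 1e-6)
})

test_that("adaptive boundaries match a per-base cumulative-sum oracle", {
  # 10 kb toy genome, 100-base track intervals with mixed mappability
  set.seed(42)
  layout <- genome_layout("toy", 1e4)
  vals <- sample(c(0, 0.5, 1), 100, replace = TRUE)
  mp <- data.frame(chrom = "toy", start = seq(0, 9900, 100),
                   end = seq(100, 1e4, 100), value = vals)
  n <- 8
  sc <- build_adaptive_bins(layout, mp, n)

  # oracle: per-base scan for the smallest position with cum >= target
  perbase <- rep(vals, each = 100)
  cum <- cumsum(perbase)
  total <- sum(perbase)
  oracle <- vapply(seq_len(n - 1), function(k) {
    which(cum >= total * k / n)[1]   # position in bases (1-based end)
  }, 0)
  expect_equal(sc$bins$start[-1], as.numeric(oracle))
})

test_that("equal-mappable errors are informative", {
  layout <- genome_layout("chr1", 100)
  expect_error(build_adaptive_bins(layout, uniform_track(layout), 1000),
               "exceeds total usable bases")
  mp <- uniform_track(layout, 0)
  expect_error(build_adaptive_bins(layout, mp, 5), "no usable bases")
})

test_that("annotate_bins computes GC and flags uncovered bins", {
  layout <- genome_layout("chr1", 1000)
  sc <- build_fixed_bins(layout, 100)
  # per-10-base GC intervals emulating ACGTACGTAA repeats: gc 0.4
  gc10 <- data.frame(chrom = "chr1", start = seq(0, 990, 10),
                     end = seq(10, 1000, 10), value = 0.4)
  sc1 <- annotate_bins(sc, gc10, uniform_track(layout, 1))
  expect_equal(sc1$bins$gc, rep(0.4, 10))
  expect_false(any(sc1$bins$masked))

  # all-GC and all-AT extremes
  gcx <- data.frame(chrom = "chr1", start = c(0, 500), end = c(500, 1000),
                    value = c(1, 0))
  sc2 <- annotate_bins(sc, gcx, uniform_track(layout, 1))
  expect_equal(sc2$bins$gc[1:5], rep(1, 5))
  expect_equal(sc2$bins$gc[6:10], rep(0, 5))

  # bin with no GC coverage (all-N) is masked
  gcpart <- data.frame(chrom = "chr1", start = 0, end = 900, value = 0.5)
  sc3 <- annotate_bins(sc, gcpart, uniform_track(layout, 1))
  expect_true(sc3$bins$masked[10])
  expect_false(any(sc3$bins$masked[1:9]))
})

test_that("mask_bins matches a brute-force filter", {
  sc <- tiny_scheme(1e5)
  set.seed(7)
  sc$bins$mappable_bases <- round(stats::runif(nrow(sc$bins), 0.5, 1) *
                                    (sc$bins$end - sc$bins$start))
  expect_false(any(mask_bins(sc, 0)$bins$masked))
  m9 <- mask_bins(sc, 0.9)$bins$masked
  oracle <- sc$bins$mappable_bases / (sc$bins$end - sc$bins$start) < 0.9
  expect_equal(m9, oracle)
  # threshold 1 masks a bin missing a single base
  sc$bins$mappable_bases[1] <- sc$bins$end[1] - sc$bins$start[1] - 1
  expect_true(mask_bins(sc, 1)$bins$masked[1])
})

test_that("bins round-trip through BED", {
  sc <- mask_bins(tiny_scheme(123457), 0.9)
  path <- tempfile(fileext = ".bed")
  write_bins_bed(sc, path)
  back <- read_bins_bed(path)
  expect_identical(back$scheme_kind, sc$scheme_kind)
  expect_equal(back$bins$start, sc$bins$start)
  expect_equal(back$bins$end, sc$bins$end)
  expect_equal(back$bins$gc, sc$bins$gc, tolerance = 1e-5)
  expect_equal(back$bins$masked, sc$bins$masked)
  expect_equal(back$layout$length, sc$layout$length)
})

test_that("layout and track files round-trip", {
  layout <- tiny_layout()
  p <- tempfile()
  write_layout_tsv(layout, p)
  expect_equal(read_layout_tsv(p), layout)

  tr <- data.frame(chrom = "chrA", start = c(0, 100), end = c(100, 250),
                   value = c(0.5, 1))
  p2 <- tempfile(fileext = ".bedgraph")
  write_track(tr, p2)
  expect_equal(read_track(p2), tr)

  # fixed-step wiggle is accepted
  wig <- tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chrA start=1 step=100 span=100",
               "0.1", "0.7", "0.3"), wig)
  tw <- read_track(wig)
  expect_equal(tw$start, c(0, 100, 200))
  expect_equal(tw$value, c(0.1, 0.7, 0.3))
})
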