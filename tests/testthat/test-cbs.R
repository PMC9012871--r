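test_that("a constant profile yields one segment per chromosome", {
  chrom <- rep(c("chr1", "chr2"), each = 40)
  np <- fake_profile(rep(0, 80), chrom)
  sc <- fake_scheme(80, chrom)
  ss <- segment_cbs(np, sc, n_perm = 200, seed = 1)
  expect_equal(nrow(ss$segments), 2)
  expect_equal(ss$segments$n_bins, c(40, 40))
  expect_equal(ss$segments$mean_log2, c(0, 0))
})

test_that("a noiseless step is split exactly at the changepoint", {
  x <- c(rep(0, 50), rep(1, 50))
  np <- fake_profile(x)
  sc <- fake_scheme(100)
  ss <- segment_cbs(np, sc, n_perm = 500, seed = 2)
  expect_equal(nrow(ss$segments), 2)
  expect_equal(ss$segments$n_bins, c(50, 50))
  expect_equal(ss$segments$mean_log2, c(0, 1))
})

test_that("the first split matches an exhaustive best-arc oracle", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(10:30, 1)
    x <- stats::rnorm(n, sd = 0.1) +
      c(rep(0, floor(n / 3)), rep(0.5, n - floor(n / 3)))
    got <- cfCNA:::.cbs_max_t(x)
    # oracle: direct two-sample t over every arc
    best <- -Inf; bi <- bj <- NA
    for (i in 0:(n - 1)) for (j in (i + 1):n) {
      if (i == 0 && j == n) next
      inside <- x[(i + 1):j]; outside <- x[-((i + 1):j)]
      m1 <- mean(inside); m2 <- mean(outside)
      ssw <- sum((inside - m1)^2) + sum((outside - m2)^2)
      s2 <- ssw / (n - 2)
      tval <- abs(m1 - m2) / sqrt(s2 * (1 / length(inside) +
                                          1 / length(outside)))
      if (tval > best) { best <- tval; bi <- i; bj <- j }
    }
    expect_equal(got$t, best, tolerance = 1e-9)
    # an arc and its complement define the same split: compare the cut
    # sets (internal boundaries), not the arc labels
    cuts <- function(i, j) setdiff(c(i, j), c(0, n))
    expect_setequal(cuts(got$i, got$j), cuts(bi, bj))
  }
})

test_that("segment means conserve the profile mean", {
  set.seed(9)
  chrom <- rep(c("chr1", "chr2"), each = 60)
  x <- stats::rnorm(120, sd = 0.06) +
    rep(c(0, 0.5, 0, -0.4), each = 30)
  np <- fake_profile(x, chrom)
  sc <- fake_scheme(120, chrom)
  ss <- segment_cbs(np, sc, n_perm = 300, seed = 3)
  s <- ss$segments
  expect_equal(sum(s$mean_log2 * s$n_bins) / sum(s$n_bins), mean(x),
               tolerance = 1e-12)
  expect_equal(sum(s$n_bins), 120)   # covers all valid bins
})

test_that("copy states follow the thresholds", {
  s <- data.frame(chrom = "chr1", start = c(0, 10, 20) * 1000,
                  end = c(10, 20, 30) * 1000, n_bins = 10,
                  mean_log2 = c(0, 0.25, -0.5), copy_state = "neutral",
                  stringsAsFactors = FALSE)
  ss <- segment_set("s", "cbs_arm", s)
  out <- assign_copy_states(ss, 0.2, -0.2)$segments$copy_state
  expect_equal(out, c("neutral", "gain", "loss"))
  expect_error(assign_copy_states(ss, -0.1, -0.2), "loss_threshold")

  # elementwise oracle on a random set
  set.seed(4)
  m <- stats::runif(50, -0.6, 0.6)
  s2 <- data.frame(chrom = "chr1", start = (0:49) * 1000,
                   end = (1:50) * 1000, n_bins = 1, mean_log2 = m,
                   copy_state = "neutral", stringsAsFactors = FALSE)
  got <- assign_copy_states(segment_set("s", "cbs_arm", s2))
  oracle <- ifelse(m >= 0.2, "gain", ifelse(m <= -0.2, "loss", "neutral"))
  expect_equal(got$segments$copy_state, oracle)
})

test_that("merging adjacent same-state segments is idempotent", {
  s <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                  start = c(0, 10, 20, 0) * 1000,
                  end = c(10, 20, 30, 10) * 1000,
                  n_bins = c(10, 10, 10, 10),
                  mean_log2 = c(0.01, -0.01, 0.5, 0.0),
                  copy_state = c("neutral", "neutral", "gain", "neutral"),
                  stringsAsFactors = FALSE)
  ss <- segment_set("s", "cbs_arm", s)
  m1 <- merge_adjacent_same_state(ss)
  expect_equal(nrow(m1$segments), 3)
  expect_equal(m1$segments$n_bins[1], 20)
  expect_equal(m1$segments$mean_log2[1], 0)   # weighted mean
  m2 <- merge_adjacent_same_state(m1)
  expect_identical(m1$segments, m2$segments)

  # alternating states stay untouched
  alt <- s
  alt$copy_state <- c("gain", "loss", "gain", "loss")
  ma <- merge_adjacent_same_state(segment_set("s", "cbs_arm", alt))
  expect_equal(nrow(ma$segments), 4)
})

test_that("more segments never increase the median within-segment SD", {
  set.seed(12)
  x <- stats::rnorm(150, sd = 0.06) + rep(c(0, 0.4, -0.3), each = 50)
  np <- fake_profile(x)
  sc <- fake_scheme(150)
  fine <- summarize_segments(np, segment_cbs(np, sc, n_perm = 300, seed = 6))
  single <- segment_set("s", "cbs_arm", data.frame(
    chrom = "chr1", start = 0, end = 150000, n_bins = 150,
    mean_log2 = mean(x), copy_state = "neutral",
    bin_from = 1, bin_to = 150, stringsAsFactors = FALSE))
  coarse <- summarize_segments(np, single)
  expect_lte(stats::median(fine$within_segment_sds),
             stats::median(coarse$within_segment_sds))
})

test_that("SEG output round-trips with 1-based inclusive coordinates", {
  s <- data.frame(chrom = "chr1", start = c(0, 20000), end = c(20000, 50000),
                  n_bins = c(20, 30), mean_log2 = c(0.1, -0.2),
                  copy_state = c("neutral", "loss"), stringsAsFactors = FALSE)
  ss <- segment_set("dog1", "cbs_arm", s)
  p <- tempfile(fileext = ".seg")
  write_seg(ss, p)
  txt <- utils::read.table(p, header = TRUE, sep = "\t")
  expect_equal(txt$loc.start, c(1, 20001))
  expect_equal(txt$loc.end, c(20000, 50000))
  back <- read_seg(p)
  expect_equal(back$dog1$segments$start, s$start)
  expect_equal(back$dog1$segments$end, s$end)
  expect_equal(back$dog1$segments$copy_state, s$copy_state)
})
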